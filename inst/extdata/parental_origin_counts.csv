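category,count
AA,255
RA,358
AR,34
RR,204
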