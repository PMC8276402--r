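sample,catches,no_tissue,non_target,within_year_recaptures
adults_2006,86,0,1,0
adults_2007,37,3,0,0
adults_2008,89,7,1,2
adults_2009,82,1,0,0
adults_2010,28,1,2,0
adults_2011,73,3,4,2
adults_2012,56,0,1,2
adults_2013,41,2,0,0
adults_2014,60,1,0,1
adults_2015,99,0,2,1
adults_2016,89,2,0,1
smolts_2017,965,20,94,0
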