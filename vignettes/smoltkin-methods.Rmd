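---
title: "Methods: kinship, effective size and resident contribution in a partially migratory population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship, effective size and resident contribution in a partially migratory population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoltkin)
library(dplyr)
```

## The monitoring problem

Many salmonid populations are partially migratory: some individuals smolt
and go to sea (anadromy), others complete their life cycle in freshwater
(residency, including precociously mature male parr). Where a river is
fitted with full up- and downstream traps, every ascending anadromous
spawner and every descending smolt can be sampled and genotyped, but the
resident fish in the river cannot. `smoltkin` implements the genetic
analysis chain for such a design:

1. collapse repeat captures of the same fish by multilocus genotype
   matching (PIT tags are lost, especially by spawning females);
2. per-sample diversity statistics and Hardy–Weinberg exact tests;
3. effective population size by the linkage-disequilibrium (LD) method;
4. full-sib/half-sib reconstruction and parentage assignment from
   microsatellite genotypes;
5. a Mantel permutation test for association between kinship and
   migration timing;
6. inference of the resident contribution to the smolt run from
   parentage gaps: because *all* anadromous spawners are in the candidate
   pool, a smolt whose mother or father cannot be found among them must
   have had a resident parent.

A forward pedigree simulator generates ground-truthed synthetic datasets
with the same structure, so every stage is validated against known truth.

## Data model

Genotypes live in a long tibble (`id`, `locus`, `a1`, `a2`) with unordered
integer allele pairs and `NA` for missing calls; a call with one readable
allele is treated as fully missing because the likelihood models require
complete diploid calls. Capture metadata is one row per capture event
(`id`, `capture_date`, `trap`, `sex`, `stage`). Dates are ISO 8601;
day-of-year and `floor(doy/7)` week indices are used for timing distances
— integer arithmetic, no locale- or ISO-week dependence.

## Identity matching

`find_matches()` links two records when they mismatch at no more than
`max_mismatch` (default 1) of their mutually non-missing loci, requiring
at least `min_shared_loci` (default 10 of 18) comparable loci; clusters
are connected components, so A–B and B–C can chain with A and C two
mismatches apart — the standard behaviour of "matches" tools, accepted for
order-independence. With 18 loci of heterozygosity ≈ 0.8 the probability
that two distinct individuals match at 17+ loci is astronomically small
(≪ 10⁻¹⁰), so false links are not a practical concern at these sample
sizes. Recapture clusters double as technical replicates:
`estimate_error_rates()` turns their discordances into per-allele miscall
and allelic-dropout estimates.

## Diversity statistics

Per locus: observed heterozygosity; unbiased expected heterozygosity
`2n/(2n−1)·(1−Σp²)`; `F_IS = 1 − H_O/H_E`. Rarefied allelic richness uses
the hypergeometric closed form `Σᵢ[1 − C(N−Nᵢ,g)/C(N,g)]`, rarefying to
the smallest per-sample gene-copy count by default. Sample means of
H<sub>O</sub>, H<sub>E</sub> and F<sub>IS</sub> are unweighted means over
loci; the ± intervals are percentile bootstraps over loci (the natural
resampling unit when the quantity reported is a cross-locus mean; whether
to bootstrap loci or individuals was an open choice and is documented
here).

The Hardy–Weinberg exact test uses the conditional distribution of
genotype arrays given allele counts. For two alleles and moderate n the
Levene distribution is enumerated exactly. Otherwise a Markov chain walks
over ordered allele assignments by swapping one allele between two random
individuals; because the number of ordered states representing an array
{n_c} is `n!/Πn_c!·2^h`, the uniform walk visits arrays exactly with
their conditional probabilities and no Metropolis correction is needed.
The p-value is the probability mass of arrays no more probable than the
observed one; the default chain (10⁴ burn-in, 1000 batches × 10⁴ steps)
reports a batch-means Monte Carlo SE. The chain statistic is re-synced
from the count table at every batch boundary so probability ties at the
observed level are compared exactly. The enumeration path doubles as the
independent oracle for the chain in the test suite; simulated null data
put the empirical size at ≈ 0.05. Benjamini–Hochberg step-up FDR
correction (`fdr_bh()`) counts deviations per sample.

## LD effective population size

For each locus pair and each retained allele pair (frequency ≥ `pcrit`,
default 0.05), Burrows' composite disequilibrium is computed from
unphased dosages `x, y ∈ {0,1,2}`:

Δ̂ = n/(n−1) · (Σxy/2n − 2p̂q̂),  r² = Δ̂² / [(p̂(1−p̂)+D̂_A)(q̂(1−q̂)+D̂_B)]

where `D̂_A = P̂_AA − p̂²` is the within-locus Hardy–Weinberg departure.
The departure terms in the denominator are what make the composite
correlation reach 1 under perfect homozygote coupling without phase
information. For biallelic loci only one allele enters (the other is its
mirror). Pooling weights each allele comparison by the number of
individuals complete at both loci. The sampling expectation
`E[r²] = 1/S + 3.19/S²` (S ≥ 30; `0.0018 + 0.907/S + 4.44/S²` below) is
subtracted at the harmonic-mean sample size S, and
`Ne = (1/3 + √(1/9 − 2.76·r²_drift)) / (2·r²_drift)` for random mating
(monogamy constants available). Non-positive drift signal maps to an
infinite estimate, which is reported as such, not clipped.

**Confidence interval.** A delete-one-*locus* jackknife (not locus-pair:
pairs sharing a locus are positively correlated, and deleting single
pairs was measured to undercover badly — 67% at nominal 95% in the
recovery experiment below) gives a variance for pooled r², converted to
effective degrees of freedom `n′ = 2r̂⁴/Var` and a chi-square interval on
r², then mapped through the monotone Ne transform. In the validation
experiment (ideal Wright–Fisher population, true Ne = 50, S = 50, 18 loci
× 10 alleles, 200 replicates) the median point estimate lands within a
few percent of truth and the interval covers ≈ 90%.

Loci known to sit near targets of selection (e.g. immune-linked markers)
can be excluded from Ne estimation via `exclude_loci` while remaining in
sibship reconstruction — configuration, not code. A mixed-age spawner
sample estimates something between N_e and N_b (the effective number of
breeders); a single smolt cohort sits closer to N_b. That caveat affects
interpretation, not computation.

## Kinship inference

The engine is a pairwise-likelihood core with consensus reconstruction —
deliberately simpler than full-pedigree simulated-annealing samplers, and
the package's central documented simplification. Relationship categories
are parameterised by IBD coefficients (k₀,k₁,k₂): unrelated (1,0,0),
half-sib (½,½,0), full-sib (¼,½,¼), parent–offspring (0,1,0). Per locus,

P(g₁,g₂ | category) = Σₘ kₘ · P(g₁,g₂ | m alleles IBD),

with observed genotypes tied to true genotypes by a one-parameter
per-allele miscall model (correct with probability 1−ε, otherwise uniform
on the locus registry; ε defaults to 0.01, and the dropout rate estimated
from recaptures can be folded into a composite ε — a single-parameter
likelihood kept deliberately simple). All quantities are precomputed as
per-locus lookup tables over unordered genotype pairs
(`M J M'` products of the emission matrix and the IBD-conditional joint),
verified in the tests against exhaustive enumeration over parental
genotypes and Mendelian transmissions.

`classify_dyads()` reports per-pair category log-likelihoods and retains
the best non-unrelated category at a log-likelihood-ratio threshold
(default 3). Within a single smolt cohort the parent–offspring category
is impossible on age grounds and can be excluded via `categories=` —
capture metadata resolving what genotypes alone cannot. Genotype-
identical pairs are flagged ambiguous (twin / duplicate / parent–offspring
cannot be separated). Pairwise argmax classification at 18 microsatellite
loci correctly labels roughly 9 in 10 true full-sib pairs (the rest
mostly drift to half-sib) — the well-known accuracy gap of pairwise
methods that motivates the partition step.

`reconstruct_sibships()` runs a randomized greedy agglomeration: merge
clusters whenever the summed full-sib-vs-unrelated LLR across the merged
pairs improves, in an order randomized per run, followed by a local
search that moves single individuals between families while the same
objective improves (repairing early lock-ins). Half-sib links between
families are added on the analogous half-sib criterion. Three runs with
different seeds are reconciled by keeping only co-memberships and
half-sib pairs present in every run; the intersection of equivalence
relations is itself one, so the consensus is a valid partition. In
validation (20 families of 5, 18 loci), the consensus partition recovers
essentially 100% of true full-sib dyads with ~0 co-membership error.

`assign_parentage()` scores each offspring against sex-matched candidates
by parent–offspring LOD (log₁₀ L(PO)/L(unrelated)), requiring LOD ≥
`min_lod` (default 5), at most `max_mendel_mismatch` (default 1)
allele-sharing exclusions, and at least 10 comparable loci; an assigned
mother–father pair must additionally be trio-consistent at all but one
locus, else the lower-LOD parent is dropped. With complete candidate
pools and no genotyping error, over 99% of parent slots are filled, all
correctly; the handful of misses are true parents whose LOD genuinely
falls below the false-assignment threshold — the designed
precision-over-recall trade-off. Candidate pools are windowed by the
caller on ascent year (smolt age bounds determine which spawning years
are possible). Allele frequencies for all likelihoods come from the full
collapsed dataset and are not updated during inference.

## Kinship and migration timing

Dyads are coded 1 (unrelated), 0.75 (half-sib), 0.5 (full-sib);
individuals without any sib in the sample are dropped so the test is not
dominated by structurally unrelated rows. The timing matrix is |Δdate| in
days for smolts (a compact run) and in week indices for adults (a
months-long run). `mantel_test()` correlates lower triangles, permutes
rows/columns of one matrix jointly (compiled loop), and reports the
add-one estimator `p = (#{r_perm ≥ r_obs}+1)/(n_perm+1)` — upper-tailed
by default because the working hypothesis (kin migrate together) implies
a positive correlation of the two distances; a two-tailed flag exists.
For n ≤ 7 an exact path enumerates all n! orderings; the sampled p agrees
with it to Monte Carlo error. A percentile bootstrap over individuals
(resampled pairs of one individual with itself discarded) accompanies r
but is never used for significance. Empirical size over 500 null cohorts
is ≈ 0.04–0.05, and mean observed r rises monotonically with the
between-family timing variance.

Parent–offspring dyads inside one sample are coded 1 (unrelated): only
sib relationships enter the kinship matrix.

## Resident contribution

`classify_parental_origin()` converts unassigned parent slots into
resident parents and tallies AA / RA / AR / RR (father × mother,
A = anadromous, R = resident), with Wilson 95% intervals on the
percentages and, per parental sex, a two-sided binomial test of
anadromous vs resident contribution against 1:1. By construction
`%(≥1 resident) = RA + AR + RR` and the anadromous-mother share of mixed
matings is `RA/(RA+AR)`. Mature male parr and adult resident trout
cannot be distinguished by this design and share the single "resident"
label. `validate_final_year_parents()` implements the internal
consistency check available in the last monitored year: a parent of the
final smolt cohort seen ascending only in the final adult year (too late
to have produced that cohort) must also have ascended earlier, or it is
flagged.

`census_trend()` is ordinary least squares of counts on year (delegated
to `lm`); `sex_ratio_test()` reports both a summed per-year 1:1
goodness-of-fit chi-square (df = years) and the year × sex heterogeneity
chi-square (df = years − 1) — published analyses are sometimes ambiguous
about which of the two they used, so both are always printed and `mode`
only picks the headline.

## The simulator and what it does (not) emulate

`sim_config()` defaults describe the monitored system the package is
aimed at: 11 ascent years with 25–96 anadromous spawners each
(female-biased ≈ 1.5:1), an unsampled resident pool with strongly
male-biased contribution (mother resident with probability 0.28, father
0.66), 317 mating-pair draws with zero-truncated negative-binomial
offspring counts (NB mean 0.95, dispersion 0.3, giving a truncated mean
of ≈ 2.7 sampled offspring per family — overdispersed, so family sizes
range from 1 into the dozens and the cohort lands near 851 smolts), smolt ages 2–4 (the upper
tail of natural age distributions is cut to keep pedigrees shallow —
configurable), family-correlated outmigration dates (family mean SD 8 d,
within-family SD 4 d around a May 1 midpoint; adults around mid-August
with SD 25 d), re-ascent probability 0.16 per year, and genotyping noise
ε = 0.01, dropout 0.01, missing 0.002 at 18 loci × 10 founder alleles
(Dirichlet concentration 3 → effective richness ≈ 8). Date SDs, resident
pool sizes and the NB dispersion are not observable in trap data and were
fixed once at field-plausible values. Offspring-centric parent draws with
replacement produce polygamy of both sexes and half-sib structure without
extra parameters; a family's offspring share one spawning year and smolt
age, and identical parent pairs drawn twice merge into one full-sib
family.

Deliberately not modelled: mutation and coalescent history (founders are
drawn from Dirichlet frequencies), inbreeding loops (parents are drawn
without shared-ancestry tracking), environmental covariates, growth and
survival. Passing tests therefore demonstrate correctness of the
inference machinery under Mendelian inheritance with realistic noise and
family structure — not robustness to population structure, null alleles
or inbreeding, which real datasets may add.

## Numerical and design choices

* Half-missing Genepop calls → fully missing; 2- and 3-digit allele
  encodings auto-detected; Pop blocks concatenated (one river population;
  grouping comes from metadata).
* Seeds: a single master seed is hashed into per-stage seeds
  (`derive_seed`), so `run_pipeline()` is bit-reproducible end to end and
  all run seeds are recorded in the manifest.
* Greedy merges accept any positive-gain merge in randomized scan order
  (not max-gain): run-to-run variability is what gives the consensus its
  meaning.
* Ties in parentage LOD resolve to the first candidate; with continuous
  LODs this is measure-zero.
* `Ne = ∞` is propagated as `Inf`, ordered as maximal, and rendered as
  `∞` in printed output.
* Problem sizes in the validation suite — e.g. 20×5 families for sibship
  recovery, 200 Wright–Fisher replicates for Ne, 500 null cohorts for the
  Mantel size check, 10⁴ null replicates for the Hardy–Weinberg size
  check — were chosen to make the Monte Carlo error small relative to
  each tolerance.

## Worked example

```{r example, eval = FALSE}
pop <- simulate_population(sim_config(), seed = 1)
pipe <- run_pipeline(pop$genotypes, pop$meta, smolt_year = 2017,
                     candidate_window_start = 2010, final_year = 2016,
                     seed = 1)
glance(pipe$contribution$summary)
pipe$mantel |> dplyr::filter(sample == "smolts")
autoplot(pipe$contribution$summary)
```

## Known limitations

* The pairwise-likelihood engine is weaker than full-likelihood pedigree
  samplers for single-dyad classification (≈ 10% full-sib/half-sib
  confusion at 18 loci); the consensus partition closes most of that gap
  for family reconstruction, which is what downstream stages consume.
* Dropout is folded into the miscall rate rather than modelled as a
  distinct process in the likelihoods.
* The LD-Ne estimate inherits the method's sensitivity to small samples;
  with ~25 individuals the interval can span from double digits to
  infinity, and the point estimate should not be read alone.
* Sex is consumed as a data field (genetic sexing upstream of this
  package); misassigned sexes propagate into parentage pools.
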