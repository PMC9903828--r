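---
title: "Methods: simulating purging and measuring mutational load in bottlenecked bird populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating purging and measuring mutational load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kakapopg)
```

# Scope

`kakapopg` addresses a question typical of conservation genomics: when a
population has been small and inbred for a long time (the Stewart Island
kākāpō are the motivating case), has inbreeding *purged* recessive
deleterious variation, or has drift *accumulated* it? The package provides
two complementary toolsets:

* an individual-based, age-structured, non-Wright-Fisher forward simulator
  of deleterious-mutation dynamics under contrasting demographic scenarios,
  and
* the empirical statistics used to detect purging in resequencing data:
  GERP-weighted relative mutational load, impact-category variant counts,
  the R~xy~ derived-allele frequency ratio, windowed nucleotide diversity, a
  pairwise genotype distance with neighbor-joining trees, PLINK-style runs
  of homozygosity (F~ROH~), and a loss-of-function inside/outside-ROH
  contrast.

A synthetic-data generator with planted truth ties the two together so that
every statistic is testable at desk scale without access-controlled data.

# The forward simulator

## Model

One simulation step is one year. Each individual carries two haplotypes
over a genic genome (by default 3,291 genes of 1.5 kb on 23 chromosomes,
4,936,500 bp in total). Within a step the population reproduces, ages one
year, and undergoes viability selection:

* **Reproduction.** Every mature female (maturity drawn uniformly from
  7–11 years; males 5–7) nests and pairs with one mature male. Pairing
  preference grows with male experience, `min(age - maturity + 1, 6)`, and
  by default each male sires at most one clutch per year. Clutch size is
  `round(Normal(3, 1.5))`, truncated at zero; offspring are male with
  probability 2/3. Each offspring receives one recombined gamete per
  parent: haplotypes switch between adjacent genes with probability
  `1 - exp(-r * gap)` (r = 1e-9 per bp across the physical inter-gene gap,
  no recombination within genes, free assortment across chromosomes), plus
  `Poisson(mu * L)` new mutations per gamete (mu = 1.33e-8 per bp per
  generation).
* **Mutation effects.** New mutations are neutral or deleterious at ratio
  1:2.31. Deleterious selection coefficients are gamma-distributed with
  mean −0.024 and sd 0.14 (shape ≈ 0.0294, scale ≈ 0.8167), negated; no cap
  is applied at draw time, so the sampler's moments match the configured
  distribution, and draws below −1 are simply lethal when exposed (the
  fitness factors 1+s and 1+hs are clamped at zero). The dominance
  coefficient h ∈ {0, 0.25, 0.5} is fixed per run.
* **Survival.** Fitness `w = prod (1+s)^hom (1+hs)^het` is computed once at
  birth. Each year an individual survives with probability
  `base(age) * min(1, K/N) * w`, with first-year baseline 0.33, adult
  baseline 0.975 and a hard maximum age of 90. Fixed mutations are removed
  from haplotypes periodically; their selection coefficients accumulate in
  a population-level fixed-load term so every individual's additive load is
  unchanged by the bookkeeping (this invariant is tested exactly).

Additive genetic load is reported as a positive magnitude,
`sum |s| (hom) + sum h |s| (het) + fixed load`; the underlying coefficients
are negative and the sign convention is cosmetic.

## Emergent quantities and calibration

Generation time is *not* an input. The field-observation-backed
life-history inputs (maturity ages, clutch distribution, sex ratio,
age-increasing male pairing success, census = 2.8 × target N~e~) leave free
the mortality schedule, the exact shape of the pairing-preference function,
and per-year mating exclusivity. Two facts shaped the calibration:

* Under density regulation the population equilibrates at lifetime
  replacement (R0 = 1), which makes the realized survival rates nearly
  independent of their baselines — what matters is the *juvenile-to-adult
  ratio* of the schedule. Lower relative first-year survival forces a
  higher equilibrium adult survival and therefore older parents.
* Unlimited yearly polygyny with an uncapped linear age preference
  concentrates paternity in a few old males, inflating reproductive
  variance and depressing N~e~ well below census/2.8.

With yearly pairing, the experience cap at 6 years, first-year survival
0.33 and adult survival 0.975, the realized generation time is ≈ 16 years
(the parental-age dispersion is wider than in episodic-breeding schemes)
and the census-to-effective-size ratio, estimated from the per-generation
rate of heterozygosity loss in neutral runs, is ≈ 2.7–2.9, consistent with
the 2.8 design factor. All of these knobs remain exposed in
`life_history_params()`.

## Scenarios, burn-in and desk scale

Four demographic scenarios span 25,000 years at full scale: Stable
(N~e~ 10,000, weak-drift control), Mainland (decline to 6,000),
StewartIsland (decline to 1,000) and Extreme (decline to 100). All start
from the Stable level; declines interpolate exponentially over the first
20% of the scenario steps (5,000 of 25,000 in the full design — the
fraction, not the absolute length, is preserved when runs are shortened)
and stay constant thereafter. Census carrying capacity is 2.8 × N~e~.

Burn-in follows the standard rescaling trick for slowly coalescing models:
a scaled phase at N/10 with mutation and recombination rates and selection
coefficients ×10, then the scaling is removed (coefficients divided back,
fitness recomputed) and the population grows to and equilibrates at the
full K. Equilibrium is declared when the trailing-window linear trend of
nucleotide diversity is statistically indistinguishable from zero
(two-sided slope t-test, alpha = 0.05); a run that has not reached
stationarity carries an explicit flag. Tree-sequence-based coalescence
checking is out of scope; the diversity-trend test is the in-package
stationarity criterion.

The desk-scale divisor divides all carrying capacities and the gene count
while scaling the per-bp mutation rate up, so the expected mutation input
per gamete per generation is preserved. The default divisor of 20 keeps a
Stable population at census ≈ 1,400 and a full scenario run in tens of
seconds. Problem sizes used by the bundled analyses: generation-time runs
at K = 500 for 2,000 recorded steps (3 seeds); neutral-decay runs at
K = 560 for 1,500 steps with 600 seeded neutral sites; scenario contrasts
with 10 replicates per scenario, 2,500 scenario steps, scaled burn-in of
600 steps plus 150 equilibration steps. These sizes were chosen so the
purging contrast is unambiguous while a full analysis completes on a
laptop CPU.

## What desk scale does and does not show

At divisor 20 the StewartIsland scenario has N~e~ ≈ 50: drift is stronger
relative to selection than at full scale (N~e~s crosses 1 at |s| ≈ 0.02
instead of 0.001), so per-class outcomes are compressed toward the drift
limit. The qualitative ordering the full-scale design predicts — fewer
segregating deleterious alleles in StewartIsland than Mainland, higher
additive load under Extreme decline — is robust at desk scale and is what
the acceptance checks assert; absolute load values are not comparable to
full-scale runs.

# Empirical statistics

## Data model and polarization

All statistics run on a complete (no missing genotypes) matrix of
derived-allele dosages. VCF input is parsed with `vcfR`; only biallelic
SNPs are kept. Polarization replaces ALT-dosage with derived-allele dosage
using an outgroup ancestral call (the kea, for kākāpō): sites with the
ancestral allele equal to ALT are complemented (0 ↔ 2), sites with unknown
or mismatching ancestral calls are dropped and tallied — no fallback
guessing. Masks arrive as BED (0-based half-open) and are converted at the
boundary; internal coordinates are 1-based. Completeness filtering and
masking are idempotent and commute, which the test suite checks on random
fixtures.

## Relative mutational load

Per individual: the sum over sites with GERP score > 2 of
(dosage × GERP), divided by the individual's total derived-allele count
over *all* sites. Heterozygous sites contribute one allele, homozygous
two, regardless of dominance. The denominator deliberately includes every
derived allele, including those at sites of intermediate constraint
(1 ≤ GERP ≤ 2); restricting the denominator instead would scale all
individuals nearly equally and not change population contrasts. The
statistic scales linearly with the score scale (tested), so score
recalibration does not reorder individuals.

## R~xy~

For a variant category C,
`R_xy = sum_i f_x(1-f_y) / sum_i f_y(1-f_x)` over eligible sites, with
frequencies taken as derived-allele counts over called alleles. The
eligibility sentence in the underlying method ("at least one out of all
alleles is derived in both populations") is ambiguous; the default reads
it literally as d_x ≥ 1 AND d_y ≥ 1, with `eligibility = "union"`
available for the pooled reading. Uncertainty comes from a delete-one-block
jackknife over consecutive blocks of 1,000 eligible sites (the trailing
block is kept when at least half-size, else merged) with a normal 95% CI
(±1.96 SE). Two caveats are worth knowing: with few blocks the normal CI
under-covers slightly, and conditioning on realized eligibility biases the
estimand away from the true-frequency functional when samples are small
and variants common — the synthetic-data recovery tests quantify both.
R~xy~ < 1 here means a deficit of that category in population x (the
island population in the kākāpō reading); the identity
R~xy~(x,y) × R~xy~(y,x) = 1 holds exactly.

## Distance matrix and trees

Per pair and site: d = 0 for same-allele homozygotes, 0.5 if either
genotype is heterozygous, 1 for opposite homozygotes. D~ij~ is the mean
over compared sites (the "region length" normalizer is taken as the number
of sites, keeping D in [0, 1]; physical-bp normalization is available).
Neighbor joining is delegated to `ape::nj`; the test suite verifies exact
inversion of an additive 4-taxon matrix and recovery of planted population
structure.

## Diversity and heterozygosity

Windowed π sums the unbiased per-site estimator `2 f (1-f) n/(n-1)` over
10-kb tiles and divides by the window length; empty interior windows are
reported with zero sites. Individual heterozygosity is heterozygous sites
per covered kb, where the covered span is the per-chromosome range of
analyzed sites.

## Runs of homozygosity

`detect_roh()` re-implements the PLINK `--homozyg` window rule with the
parameters used for kākāpō (window 100 SNPs, ≤1 heterozygote per window,
5% window-hit threshold; segments require ≥25 SNPs, ≥100 kb, ≤50 kb/SNP
density, ≤1,000 kb gaps, ≤750 heterozygotes), plus a stricter
sensitivity-check preset (`roh_params_strict()`). Three conventions are
pinned down explicitly because the upstream description leaves them open:
only windows fully inside a chromosome count; candidate stretches are
split at gaps *before* the SNP-count/length filters; and segment bounds
are the first and last SNP coordinates. The detector is tested for
equality against a brute-force implementation of the window rule on
fixtures up to a few thousand SNPs, and for monotonicity (tightening the
window heterozygote allowance never lengthens total ROH). F~ROH~ divides
ROH length at thresholds (≥100 kb, ≥2 Mb) by a genome length that defaults
to the covered span, since synthetic and simulated data have no assembly
constant.

The LoF contrast asks whether HIGH-impact variants are depleted inside ROH
(where recessives have been exposed to selection): per individual, the
rate of LoF carrier sites inside ROH is normalized by homozygous
synonymous sites inside ROH, the same outside, and a paired two-sided
t-test compares the normalized rates. Individuals with a zero synonymous
denominator are excluded and reported.

# The synthetic-data generator

`synth_spec()`/`synth_generate()` emulate the statistical structure the
empirical analyses assume: two populations, complete biallelic genotypes,
Beta-distributed derived-allele frequencies (default Beta(0.8, 2.5)),
SnpEff-style impact categories, GERP scores with a configurable
super-threshold fraction, and optional long forced-homozygous tracts in
population 1. A per-category deficit factor δ downscales population-x
frequencies so the planted truth R~xy~ ≈ δ < 1 — the purging signature.
Ancestral alleles equal the reference except for a configurable flipped
fraction that exercises polarization. Generation is a pure function of the
spec (fixed seed ⇒ byte-identical files; tested), and `truth_check()`
reports frequency agreement, R~xy~ CI coverage of the planted value, and
bp-level ROH recall/precision.

What the generator does *not* emulate: linkage disequilibrium outside the
planted tracts, site-frequency-spectrum shape from any real demography,
sequencing error, or missingness beyond what the completeness filter
removes. Passing recovery tests therefore demonstrate estimator
correctness, not robustness to real-data artifacts.

# Numerical choices and degenerate inputs

* All randomness flows through R's global RNG; every driver takes a seed,
  and replicate r of a multi-replicate run uses seed + r.
* The haplotype store is a dense 0/1 integer matrix (mutations × 2
  columns per individual); reads and writes go through in-environment
  assignment so sub-assignments never copy the matrix.
* R~xy~ with a zero denominator returns an explicit "undefined" status;
  fewer than two jackknife blocks yields a point estimate with a "no_ci"
  flag. Individuals with zero derived alleles get `NA` relative load.
  Chromosomes with fewer SNPs than one ROH window produce no calls and a
  warning. An empty post-filter matrix is a warning from
  `filter_complete()` but a hard error in the pipeline, where silence
  would hide a configuration mistake.
* Welch t-tests on degenerate inputs (constant groups) report p = 1 when
  the means are equal and `NA` otherwise rather than erroring.
* Extinct scenario replicates are flagged, their trajectories kept, and
  they are excluded from load summaries with a warning.

# Known limitations

* The simulator's parental-age standard deviation (≈ 8 years) is wider
  than an episodic, synchronized-breeding model would give; only the mean
  generation time was calibrated.
* Population-level fitness acts on survival only; fecundity selection is
  not modeled.
* The R~xy~ jackknife assumes eligible sites are exchangeable in genome
  order; strong local LD structure (absent in the generator) would make
  1,000-site blocks optimistic on real data.
* The decline trajectories are a smooth exponential stand-in for glacial
  demographic reconstructions; breakpoint-level realism is out of scope.
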