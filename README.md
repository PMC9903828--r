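# kakapopg

Mutational load, purging and inbreeding genomics for bottlenecked bird
populations.

## The problem

Small, long-isolated populations — the Stewart Island kākāpō (*Strigops
habroptilus*) being the archetype — can follow two opposite genetic
trajectories: drift can let deleterious mutations accumulate, or inbreeding
can expose recessive deleterious alleles as homozygotes and let selection
*purge* them. Distinguishing the two requires both sides of the argument:

* **Forward simulation.** An individual-based, age-structured,
  non-Wright-Fisher simulator with kākāpō life history (female maturity
  7–11 y, male 5–7 y, clutches `round(N(3, 1.5))`, 2:1 male-biased
  offspring sex ratio, age-weighted male pairing, census = 2.8 × target
  N<sub>e</sub>). Genomes are 3,291 genes × 1.5 kb (4,936,500 bp) on 23
  chromosomes, mutated at μ = 1.33 × 10⁻⁸ /bp/generation with
  deleterious:neutral mutations at 2.31:1 and gamma-distributed selection
  coefficients (mean −0.024, sd 0.14; dominance h ∈ {0, 0.25, 0.5} per
  run). Generation time is *emergent* (≈ 16 y). Four demographic scenarios
  (Stable N<sub>e</sub> 10,000; Mainland 6,000; StewartIsland 1,000;
  Extreme 100) span 25,000 years, shrunk to desk scale by a divisor that
  preserves the per-gamete mutation input.

* **Empirical statistics** for resequencing data:
  - GERP-weighted relative load per individual:
    Σ<sub>GERP>2</sub>(dosage × GERP) / Σ(dosage over all sites);
  - SnpEff impact-category counts split by het/hom with Welch tests;
  - R<sub>xy</sub> = Σf<sub>x</sub>(1−f<sub>y</sub>) /
    Σf<sub>y</sub>(1−f<sub>x</sub>) with a 1,000-site block jackknife
    (R<sub>xy</sub> < 1 ⇒ deficit of the category in population x);
  - windowed nucleotide diversity (10 kb) and per-kb heterozygosity;
  - the pairwise genotype distance D<sub>ij</sub> (0 / 0.5 / 1 per site)
    with neighbor-joining trees;
  - PLINK-style runs of homozygosity (100-SNP windows, ≤1 het/window, 5%
    threshold, ≥25 SNPs, ≥100 kb, ≤50 kb/SNP, ≤1,000 kb gaps) and
    F<sub>ROH</sub>;
  - loss-of-function rates inside vs outside ROH, normalized by homozygous
    synonymous rates, with a paired t-test.

A synthetic-data generator plants known truth (frequency spectra, category
deficits, homozygous tracts) so every estimator is testable without the
access-controlled kākāpō data.

## Worked example

Generate a synthetic two-population dataset with a planted
loss-of-function deficit in the island population (the purging signature),
planted homozygous tracts, and some sites needing polarization; then run
the full empirical pipeline:

```r
library(kakapopg)
spec <- synth_spec(n_sites = 20000, n_ind = c(12, 12),
                   deficit = c(LOW = 1, MODERATE = 1, HIGH = 0.5, MODIFIER = 1),
                   roh_fraction = 0.2, roh_tract_mean = 2e6,
                   flip_fraction = 0.1, seed = 42)
ds  <- synth_generate(spec, dir = "synth")
res <- pipeline_empirical(ds$files$vcf, ds$files$pop_map,
                          ds$files$annotation, out_dir = "results",
                          pops = c("island", "mainland"), block = 250,
                          seed = 42)
res$rxy
#>   category  estimate          se     ci_lo     ci_hi n_sites n_blocks status
#> 1      LOW 1.0153849 0.010958883 0.9939055 1.0368643    4636       19     ok
#> 2 MODERATE 1.0033463 0.010019081 0.9837089 1.0229837    2374        9     ok
#> 3     HIGH 0.3969624 0.003813752 0.3894875 0.4044374     645        3     ok
```

The planted HIGH deficit (factor 0.5) is recovered — R<sub>xy</sub> ≈ 0.40
with a CI excluding 1 — while the untouched categories sit at 1. The same
run reports per-individual load and F<sub>ROH</sub>:

```r
head(res$load[, c("sample_id", "population", "load", "n_derived")], 4)
#>   sample_id population      load n_derived
#> 1 island_01     island 1.0281251      9497
#> 2 island_02     island 1.0115217      9519
#> 3 island_03     island 1.0358157      9517
#> 4 island_04     island 0.9880564      9629
```

Island individuals carry the planted homozygosity
(mean F<sub>ROH</sub>(≥100 kb) ≈ 0.31 vs 0.00 on the mainland), and the
LoF-in/out-of-ROH paired test on this fixture is decisive
(p ≈ 3.4 × 10⁻¹³).

On the simulation side:

```r
build_architecture()
#> genome_architecture: 3291 genes x 1500 bp = 4,936,500 bp on 23 chromosomes
#>   mu = 1.33e-08 /bp/gen (0.0657 new mutations per gamete), r = 1e-09 /bp between genes

pipeline_simulate("sim_out", scenarios = c("StewartIsland", "Mainland"),
                  replicates = 10, scale = 20, h = 0, seed = 1)
```

writes per-replicate trajectories (step, N, π, mean load), per-individual
load tables and a Welch-test comparison table; with h = 0 the island
scenario ends with significantly fewer deleterious alleles per individual
than the mainland scenario — purging, not accumulation.

A thin command-line wrapper is installed at
`inst/scripts/kakapopg.R` (`simulate`, `empirical`, `synth` subcommands).
The methods vignette (`vignettes/kakapopg-methods.Rmd`) documents the
model, its assumptions, calibration and limitations.

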