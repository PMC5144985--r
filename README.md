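# ionqtl

Multi-environment QTL mapping and QTL-by-environment interaction (QEI)
analysis for seed ionomics in recombinant inbred line (RIL) populations.

## The problem

The concentrations of mineral nutrients and trace elements in a seed (its
*ionome*) are shaped jointly by the plant's genotype and by the field it
grew in.  In a biparental RIL population grown in many environments, the
interesting questions are quantitative: how heritable is each element
within and across environments, where are the quantitative trait loci
(QTL), and which loci change their effect with the environment (QEI)?
Answering them from single-seed ICP-MS measurements takes a chain of
statistical steps, each with sharp edges: analytical outliers, seed-size
confounding, unbalanced line x environment designs, genome-wide multiple
testing, and interaction tests that must be calibrated by permutation.

`ionqtl` implements that chain end to end for unbalanced multi-environment
RIL designs, together with a synthetic-data generator that emulates the
statistical structure of such studies, so the whole pipeline is testable
without any external data.

## What it computes

**Single-seed normalization.**  Raw per-seed concentrations are screened
for analytical outliers by a grouped robust score: within each
(line, environment) group, `score = |x - median| / MAD`, and values with
score > 6.2 are set missing (groups with MAD = 0 or fewer than 3 seeds are
left alone).  Retained seeds are then normalized by taking residuals of
the per-element least-squares model

    raw ~ intercept + seed weight + analytical run (factor)

The residual — the *estimated concentration difference from the mean*
(ECDM) — removes the seed-size confound (small seeds otherwise show
inflated apparent concentrations) and run-to-run batch shifts.  Line x
trait matrices are means of retained ECDMs per environment.

**Heritability.**  Across environments, broad-sense H² comes from an
unbalanced type-II two-way ANOVA (two sequential fits, `~ line + env` and
`~ env + line`; each term's adjusted mean square is read from the fit
where it enters second).  Variance components are recovered from the
expected mean squares, `VG = (MS_line - MS_res) / c_g`, negative estimates
clipped to zero, and `H² = VG / (VG + VE + Vres)`.  Within an environment,
lines with two or more replicate rows enter a one-way ANOVA and
`H² = VG / (VG + Vres)`.

**QTL mapping.**  Single-marker regression gives
`LOD = (n/2) log10(RSS0 / RSS1)` at every marker; genome-wide significance
is the 95th percentile of the maximum LOD over (by default) 1000
trait-shuffling permutations.  Multi-QTL models are built by forward/
backward stepwise search over purely additive marker models scored by the
penalized LOD (model LOD minus the permutation penalty per locus, at most
10 loci), refined by iterative per-locus rescans in random order, and
merged across environments by single-linkage clustering with a 5 cM
window.

**QEI.**  Two complementary tests:

1. *Location covariates.*  Years within a location are pooled and, at
   each marker, the full model `y ~ g + location + g:location` is compared
   with the additive model `y ~ g + location`; the difference of their LOD
   scores isolates the genotype-by-location component.  Significance comes
   from permutations of the same three-step procedure (fit both models,
   subtract), shuffling within location strata.
2. *Trait differences.*  For two years at one location, per-line trait
   differences are mapped with the same stepwise machinery; loci with
   year-dependent effects survive the subtraction, shared effects cancel.

## Worked example

Simulate two New York growouts sharing 200 RILs, with a constant-effect
Mo locus and a Ni locus whose effect reverses sign between years, then run
the pipeline:

```r
library(ionqtl)

sc <- sim_scenario(
  n_lines = 200, map = make_map(5, 21, 100),
  environments = list(
    list(env_id = "NY05", line_subset_size = 180, n_reps = 3),
    list(env_id = "NY12", line_subset_size = 150, n_reps = 1)),
  traits = c("Mo", "Ni"),
  qtl_effects = list(
    list(trait = "Mo", chr = 1, pos_cM = 60, effect = 1.5),
    list(trait = "Ni", chr = 4, pos_cM = 40,
         effect = c(NY05 = 1, NY12 = -1))),
  env_main_effects = c(NY05 = 0, NY12 = 0.8),
  residual_sd = 1, rng_seed = 2025)
crosses <- simulate_crosses(sc)

marker_lod_scan(crosses$NY05, "Mo")
#> LOD genome scan for 'Mo' (105 markers, 5 chromosomes, n = 180)
#>   max LOD 30.63 at c1_m13 (chr 1, 60.0 cM)

thr <- permutation_threshold(crosses$NY05, "Mo", n_perm = 1000,
                             alpha = 0.05, seed = 1)
#> threshold: 2.46
refine_positions(crosses$NY05,
                 stepwise_qtl(crosses$NY05, "Mo",
                              penalty = as.numeric(thr)),
                 seed = 1)
#> Stepwise QTL model for 'Mo' (NY05): 1 loci, model LOD 30.63,
#>   penalty 2.46, pLOD 28.18
#>   marker chr pos effect lod_drop
#> 1 c1_m13   1  60   1.33     30.6
```

The scan finds the planted Mo locus at its true position (chr 1, 60 cM)
with an estimated A-minus-B effect of 1.33 (truth 1.5), far above the
genome-wide threshold.  The sign-reversing Ni locus is invisible to
across-environment heritability but lights up the interaction test:

```r
h2_across_env(lapply(crosses, `[[`, "traits"), "Ni")
#> Broad-sense heritability: Ni (across environments)
#>   H2 = 0.000  (VG = 0, VE = 0.1742, Vres = 1.088, n = 330)

st <- stack_locations(crosses, list(NY05 = "NY05", NY12 = "NY12"))
qei_covariate_test(st, "Ni", n_perm = 1000, alpha = 0.05, seed = 2)
#> QTL-by-location interaction scan for 'Ni'
#>   threshold (alpha = 0.05): 2.61; 18 significant marker(s)
#>    marker chr pos delta_lod
#> 6   c4_m9   4  40     25.14
#> ...
```

The interaction LOD peaks at 25.14 exactly at the planted locus
(chr 4, 40 cM), while the line main effect — and hence across-environment
H² — is near zero because the +1/-1 effects cancel.  This is the
signature that motivates both QEI procedures.

A thin command-line wrapper over the same functions ships in
`inst/cli/ionqtl.R` (`simulate`, `normalize`, `herit`, `scan`,
`stepwise`, `merge`, `qei-covariate`, `qei-diff`).

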