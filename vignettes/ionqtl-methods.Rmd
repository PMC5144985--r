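---
title: "Methods: multi-environment ionome QTL and QEI analysis"
author: "ionqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment ionome QTL and QEI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionqtl)
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limits.

## 1. The design being modeled

The target design is a biparental recombinant inbred line (RIL)
population — homozygous at essentially every locus, so genotypes are
two-state — phenotyped for ~20 elemental concentrations in seed tissue
across roughly ten environments.  The design is heavily unbalanced:
each environment grows a different, overlapping subset of lines (on the
order of 80-260 of ~230), and only a few environments have replicate
rows.  All mapping works from a genetic map in centimorgans; scans are
at markers only, because maps of intermated RIL populations are dense
enough (thousands of markers) that pseudomarker imputation buys little
and costs the clean least-squares formulation.

## 2. Single-seed normalization

**Outlier flagging.**  Per element, within each (line, environment)
group, the score is $|x - \mathrm{med}|/\mathrm{MAD}$ and values scoring
strictly above the threshold are set missing.  The default threshold is
6.2, the convention for single-seed ionomics panels.  Two deliberate
choices:

* The MAD is used *raw* (no 1.4826 normal-consistency constant), the
  more conservative reading of the 6.2 convention; a `consistency`
  switch restores the scaled version, in which case the same numeric
  threshold flags roughly 1.48x more aggressively.
* Flagging is defined as a **single pass**.  Re-scoring after removal
  would shrink the MAD and could cascade; the contract is one pass on
  the raw data, which is idempotent by construction and is what the
  tests assert.

Groups with MAD = 0 or fewer than 3 seeds are left unflagged — a robust
scale estimated from one or two points, or a degenerate zero scale, is
not evidence.

**ECDM.**  Dividing concentration by seed weight biases small seeds
upward whenever there is any weight-independent signal component
(contamination, detection-limit effects).  Instead each element is fit
per environment by least squares as

$$\mathrm{raw} = \beta_0 + \beta_1\,\mathrm{weight} +
  \beta_2\,\mathrm{run} + e,$$

with the analytical run as a categorical factor, and the residual $e$ —
the estimated concentration difference from the mean (ECDM) — is the
normalized trait.  If every seed had exactly the concentration its
weight predicts, all residuals would be zero; a seed richer or poorer
than the population shows a signed ECDM.  Flagged seeds are excluded
from the fit (flagging precedes normalization) and get missing ECDM.
Degenerate designs degrade gracefully with a logged notice: a single run
level drops the run factor, constant weight drops the weight term.

The fit is per environment by default (runs are nested within shipping
batches in practice); a pooled fit is a switch.  Line values are means
of retained ECDMs; a line with no retained seeds is missing, never zero.
Replicate-row means are kept separately because within-environment
heritability needs them.

## 3. Heritability

Across environments the layout is a two-way crossed design with no
interaction term, badly unbalanced, so sums of squares depend on fit
order.  The type-II resolution fits both orders —
`trait ~ line + env` and `trait ~ env + line` — and reads each term's
sum of squares from the fit where it enters **second** (adjusted for the
other).  From the adjusted mean squares, variance components come from
the expected-mean-square relations

$$\hat V_G = \frac{MS_\mathrm{line} - MS_\mathrm{res}}{c_g},\qquad
  c_g = \frac{N - \sum_i n_i^2/N}{\mathrm{df}_\mathrm{line}},$$

(and symmetrically for environment), with negative estimates clipped to
zero and logged.  $H^2 = \hat V_G/(\hat V_G + \hat V_E + \hat
V_\mathrm{res})$.  The component step matters: the raw mean-square ratio
is not a variance fraction (its expectation involves the replication
factors), and under a simulated 1:1:2 split of genetic : environmental :
residual variance only the component estimator returns ~0.25.  Because
"the genetic variance" is sometimes read as the adjusted MS or SS
itself, both alternative ratios are carried in the result object
(`ms_ratio`, `ss_ratio`) for comparison.

Within an environment, lines with at least two replicate rows enter a
one-way ANOVA; $H^2 = \hat V_G/(\hat V_G + MS_\mathrm{res})$ with the
same EMS recovery.  With zero replicate noise this is exactly 1.  If all
surviving values are identical there is no variance to partition and the
estimate is reported missing rather than invented.

A signature worth noting: a locus whose effect reverses sign between
environments produces high within-environment H² but near-zero
across-environment H², because the line main effect cancels.  The
generator reproduces this pattern and the tests assert it.

## 4. Genome scans, thresholds, stepwise selection

At marker $j$ the LOD is $\tfrac{n_j}{2}\log_{10}(RSS_0/RSS_1)$ with
both residual sums of squares computed **on the same line subset**
(lines missing the genotype at $j$ are dropped from both models, keeping
the statistic a valid likelihood ratio; nothing is imputed).  The scan
engine is vectorized over phenotype columns, so a full permutation null
(shuffle traits across lines, rescan, record the genome-wide maximum) is
one matrix pass; the default is the conventional 1000 permutations and
the 95th percentile.

Stepwise multi-QTL selection is purely additive: forward steps scan with
the current loci as covariates and add the marker maximizing the joint
model LOD while the penalized LOD ($\mathrm{LOD} - \mathrm{penalty}
\times k$, penalty = the permutation threshold) increases and $k < 10$;
backward elimination then removes any locus whose removal increases the
penalized LOD; the best model visited wins.  Interaction penalties are
zero and interaction terms never enter.  Ties in the forward scan break
to the lowest chromosome, then lowest position, making runs
reproducible.  Position refinement rescans each locus's chromosome in
seeded-random order with the other loci as covariates, relocating to the
maximum; the model LOD cannot decrease, and passes stop at convergence
or 10 iterations.

Loci from different environments within 5 cM (single linkage, so chains
merge) are reported as one locus.

## 5. The two QEI tests

**Location covariates.**  Years are pooled by location; each line
contributes one observation per year with its (identical) genotypes.
At each marker the full model $y \sim g + \mathrm{loc} + g{:}\mathrm{loc}$
and the additive model $y \sim g + \mathrm{loc}$ are fit by least
squares, each scored as a LOD against the shared null
$y \sim \mathrm{loc}$, and the difference $\Delta\mathrm{LOD} =
\mathrm{LOD}_\mathrm{full} - \mathrm{LOD}_\mathrm{add} \ge 0$ isolates
the interaction.  Markers where some location lacks both genotype
classes are skipped (logged), since the interaction is inestimable
there.

The permutation null repeats the full three-step procedure.  The
stratification is a genuine design choice: an unstratified shuffle would
destroy location main effects and inflate the null, so permutations
shuffle the line-to-genotype pairing **within each location**.
(Implementation note: permuting trait values within a location stratum
is distributionally identical to permuting which line's genotypes they
attach to, and lets all permutations share one vectorized pass.)  The
scheme is calibrated: under a constant-effect null the exceedance rate
of the threshold sits at the nominal alpha within binomial error — the
acceptance suite measures it.

**Trait differences.**  For two years at one location, common lines'
per-year trait values are subtracted and the differences mapped with
the standard stepwise-plus-permutation machinery.  A locus with equal
effects in both years cancels (detections at ~alpha); a year-specific
locus survives.  Differences are taken on line means, never seed-level
data, and at least 3 common lines are required.

## 6. The synthetic-data generator

The generator is first-class, tested code; its defaults encode the
study conditions the pipeline targets.

* **Genotypes**: each line an independent two-state Markov chain per
  chromosome; switch probability between adjacent markers is the
  Haldane fraction $r = \tfrac12(1 - e^{-2d/100})$ of their map
  distance.  Map distances are treated as realized RIL distances — maps
  of intermated populations already include the intermating expansion,
  so no extra transform is applied.
* **Traits**: $y = \mu + \sum_k a_{k e} s_{ik} + E_e + \varepsilon$,
  genotypes coded $s = \pm\tfrac12$ so a stated effect *is* the A-vs-B
  mean difference; effects may differ by environment (that is what QEI
  is); QTL act at the marker nearest their stated position (ties to the
  lower position).  Residual SD defaults to 1 so effects read in SD
  units.
* **Seeds**: weight ~ truncated normal (default 250 +/- 50 mg); raw
  concentration = weight x trait value + a weight-independent
  contamination term + a run-batch offset + measurement noise; runs are
  assigned round-robin in blocks of consecutive seeds (default block
  96), mimicking autosampler batching.  A fraction of (seed, element)
  values receives an injected outlier of 15 group-MADs.  The injection
  size is set so the flagging rule's recovery guarantee survives the
  worst realistic case — two same-direction outliers landing in one
  small group roughly double the post-injection MAD, which halves the
  score; 15 MADs keeps flagged scores above 6.2 with margin, 12 does
  not.
* **Reproducibility**: every operation seeds its own stream, with
  per-environment sub-streams at fixed offsets, so partial reruns are
  bit-identical.
* **The default scenario** mirrors the target design: 233 founder
  lines; 10 environments with subset sizes 82-233 and replicate rows in
  three of them; 20 elements; a strong Mo locus on chromosome 1 present
  in 9 environments, a Cd locus on chromosome 2, a location-dependent
  Ni locus early on chromosome 9, and a modest Zn locus; contamination,
  4 run batches, 0.5% outliers.  Marker density defaults to 60 per
  chromosome — mapping is marker-based, so density affects resolution,
  not validity, and the tests' conclusions.

What the generator does **not** emulate: linkage disequilibrium decay
beyond the Markov chain (no interference, no segregation distortion),
pedigree-accurate intermating, multi-allelic markers, correlated
elements (each trait draws independent residuals), within-run drift
(runs enter only as additive offsets, exactly the term the ECDM model
fits), and soil/weather covariates.  Passing tests therefore show the
*statistical machinery* is correct and calibrated under the stated
model; they do not certify behavior under real-data pathologies such as
drift within runs or trait-trait correlation.

## 7. Numerical choices

* Perfect fits: $RSS_1$ is floored at $10^{-12} \times RSS_0$, capping
  the LOD rather than emitting infinities (logged).
* Zero-variance traits scan to an all-zero profile with a warning;
  zero-variance difference traits yield an empty QTL model.
* Monomorphic markers (within the analysis subset) get LOD 0 — the
  marker model equals the null; markers with fewer than 3 informative
  lines are reported missing.
* $\Delta$LOD is mathematically $\ge 0$ (nested models); tests allow
  $-10^{-9}$ of roundoff.
* Negative variance components are clipped at zero before ratios, and
  every clip, cap, dropped term and skipped marker goes through one
  logging channel with stable prefixes (`clipped-variance`,
  `capped-lod`, `drop-term`, `skipped-marker`).
* Empirical thresholds use the default continuous sample quantile; at
  the default 1000 permutations the choice of quantile type moves the
  threshold by far less than permutation noise.

## 8. Problem sizes used by the test and acceptance runs

The statistical checks run at the sizes their claims need and no more:
calibration of genome-wide false positives uses 200 pure-noise scans
(20 traits x 10 environments) at 100 lines x 300 markers with 200
permutations each; QEI type-I uses 100 two-location datasets (200 lines
per location); power and recovery checks use 20-25 replicates; the
equal-effect selectivity *rate* uses 100 replicates because a rate near
0.05 is unresolvable from 25.  The vectorized engines make all of this
a matter of seconds, so the same sizes are used in
`scripts/acceptance.R`.

## 9. Known limitations

* Marker regression shifts reported positions slightly relative to
  imputation-based interval mapping near gaps in the map; on dense maps
  the difference is within a marker spacing.
* The stacked QEI model is fixed-effects: lines appearing in both years
  of a location contribute two independent observations, with no
  within-line correlation modeling.
* Heritability uses the two-term ANOVA the design supports — no
  line-by-environment variance component, no REML.
* The ECDM model corrects between-run offsets only; within-run drift
  must be handled upstream (control solutions), and is out of scope
  here.
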