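---
title: "Methods: nutritional geometry of rumen macronutrient balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutritional geometry of rumen macronutrient balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenbalance)
```

## The problem this package addresses

Wild northern browsers such as moose face winter foodscapes in which the
available plants differ widely in their balance of protein, nonstructural
carbohydrates (TNC), and cell-wall carbohydrates. Proportions-based
nutritional geometry asks whether animals regulate the *composition* of
what ends up in the rumen — a similar protein:TNC balance across animals
eating very different plant combinations is the signature of active
macronutrient balancing. `rumenbalance` implements that analysis as a
tested pipeline: derivation of macronutrient profiles from proximate
chemistry, right-angle mixture triangle (RMT) geometry, the associated
statistics, a foodscape module for the plant side, a seeded synthetic-data
generator, and a simplified latent-variable calibration stage for
near-infrared (NIR) spectra.

## The macronutrient derivation ladder

Proximate analysis reports, per sample and as % of dry matter (dm): ash,
Kjeldahl (total) N, N bound in acid-detergent fiber (ADF-N),
neutral-detergent fiber (NDF), acid-detergent fiber (ADF), and lignin.
The derived quantities are definitions, not tunables:

* crude protein $= 6.25 \times \mathrm{N}$ (proteins average ~16% N);
* available protein $\mathrm{AP} = 6.25\,(\mathrm{N} - \mathrm{ADF\!-\!N})$
  — fiber-bound N is treated as nutritionally unavailable. For rumen
  material the available pool includes microbial N, hence the notation
  AP~R~;
* hemicellulose $= \mathrm{NDF} - \mathrm{ADF}$ and cellulose
  $= \mathrm{ADF} - \mathrm{lignin}$ (the detergent ladder);
* for rumen samples the quickly digestible pool cannot be measured
  reliably (unknown residence time), so it is estimated by compositional
  closure: $\mathrm{TNC2{+}lipids} = 100 - (\mathrm{NDF} + \mathrm{AP} +
  \mathrm{ash})$;
* for plants, sugars and starch are measured enzymatically and summed
  (TNC1), and lipids are kept separate;
* microbial N $= 1.1 \times$ the purine marker (g yeast-RNA equivalents
  per 100 g dm).

Closure is an algebraic identity of the derivation:
$\mathrm{AP} + \mathrm{cellulose} + \mathrm{hemicellulose} +
\mathrm{lignin} + \mathrm{ash} + \mathrm{TNC2{+}lipids} = 100$ holds
exactly for every accepted rumen record, and the test suite asserts it to
$10^{-9}$.

Derived values that fall slightly negative (input rounding) are clipped to
zero within a tolerance of 0.5 percentage points and logged; anything
beyond that rejects the record with a named reason. Rejection rather than
silent propagation was chosen because a closure deficit larger than
rounding indicates an inconsistent record, and proportions-based analyses
propagate any such error into every other constituent.

## RMT geometry

An RMT represents a three-component mixture in the plane: x = % highly
digestible macronutrients (TNC2+lipids, or TNC1+lipids for plants), y =
% available protein, and the implicit axis i = 100 − x − y carries fiber
(cellulose + hemicellulose). Components are expressed as percentages of
the *macronutrient* total (ap + fiber + tnc); lignin and ash are excluded
from the denominator. The projection is scale invariant, and x + y + i =
100 always — both are tested properties.

```{r rmt}
rmt_points(data.frame(ap = 25, fiber = 30, tnc2_lipids = 45))
```

Nutritional spaces are convex hulls of RMT point clouds in (x, y).
Vertices are returned counter-clockwise from the lexicographically
smallest vertex (deterministic output), area by the shoelace formula.
Degenerate inputs (fewer than three distinct non-collinear points) yield
area 0 rather than an error, because a browser restricted to one or two
foods genuinely has a degenerate mixing space.

## Statistics

All tests are two-sided at $\alpha = .05$. The isometry test standardizes
both variables (so slope 1 means the two components scale in exact
proportion) and fits ordinary least squares; on standardized data the
slope equals the Pearson correlation, asserted to $10^{-12}$ in the
tests. OLS rather than standardized-major-axis regression is used because
the analysis this package implements treats the relationship as a plain
linear regression; SMA would be the choice if measurement error in x were
the focus.

The balance-ratio model regresses AP:(TNC+lipids) on % fiber. With
diet-type labels a full-interaction linear model (raw scale by default)
gives a slope per type and t-tests of interaction contrasts; a
quasi-binomial GLM on the ratio rescaled into (0, 1) by 1.02 times its
observed maximum (logit link, Pearson dispersion) is available as a
robustness check for the bounded scale. The two variants are required by
the tests to give similar results on the synthetic default. The 1.02
ceiling factor is arbitrary but innocuous: it only needs to keep the
rescaled ratios strictly inside the unit interval.

Subpopulation analyses aggregate per-sample ratios as the mean ratio per
management unit (not the ratio of means; the latter is available as a
sensitivity variant) and regress mean calf body mass on it, with df =
n − 2. Calf body mass is used because it indexes subpopulation condition
while avoiding age and harvest-bias effects.

## The foodscape module

The packaged plant table stores the printed winter composition of the 12
dominant food plants verbatim at one decimal. Its fiber sub-fractions do
not always re-add to the printed NDF (up to ~3 percentage points); the
fixture makes no attempt to reconcile this, and a checksum test guards
the values.

The plant PCA uses the correlation matrix (constituents have
heterogeneous scales). The default constituent set is a genuine design
decision: the source describes a seven-constituent list in its methods
but a six-constituent loading plot in its results. Recomputing both from
the packaged table gives PC1+PC2 = 69.8% of variance for the
six-constituent set (lignin, cellulose, hemicellulose, AP, TNC1, dNDF)
and 64.9% for seven (adding lipids); only the former matches the
published "70%", so six is the default and `plant_pca_constituents(7)`
selects the variant. Loadings follow a deterministic sign convention
(largest-|loading| entry per component positive).

Only the TNC anchors of the three root crops are published for the
supplementary feeds; the remaining feed values are synthetic stand-ins at
feed-table magnitudes, shipped in a fixture whose name marks it
synthetic, and overridable by a user CSV. The feed comparison PCA is
therefore illustrative, not a reference result.

## The synthetic-data generator

The generator exists so that every stage is testable without any
download. It emulates, at the study's conditions:

* n = 481 samples, 30 management units across areas A–G with at least 5
  samples each, diet-type allocation 16:8:6
  (broadleaf : shrub-and-sugar : conifer);
* the published 7×7 constituent correlation matrix;
* diet-type contrasts: lignin 16/18/16 % dm and microbial N
  0.71/0.92/0.70 % dm (broadleaf/shrub-and-sugar/conifer);
* the age-sex mix (52% calves, 14% yearlings, 20% adult females, 14%
  adult males, sexes split as observed);
* a 70:30 early:late sampling-date split, inverted in area A, spanning
  13 October to 22 February so the 23-October design filter is
  exercised;
* calf dressed body mass ~N(65, 8²) kg, independent of the balance ratio
  under the default null, with an optional injected subpopulation-level
  slope for known-truth recovery tests.

Three design points deserve explanation.

**Closure by subtraction, not renormalization.** TNC2+lipids *is defined*
by subtraction, so the generator draws only the six measured constituents
from a Gaussian with the printed 6×6 correlation block and computes
TNC2+lipids as 100 minus the closure sum. Closure then holds exactly by
construction. The TNC2 correlation row is induced rather than free: the
marginal dispersions were calibrated (a one-time analytic fit) so the
induced row matches the printed one to within 0.026. Renormalizing a full
7-dimensional draw instead distorts the printed correlations by up to
0.07 — outside the generator's ±0.05 contract.

**Diet types by latent-score thresholding.** Additive per-type shifts in
lignin and microbial N cannot coexist with the printed pooled
correlations: removing the between-type shift covariance from the target
leaves a within-type lignin–AP correlation above 1. Instead, the
shrub-and-sugar type is assigned to the upper tail of a latent score
aligned with the lignin/microbial-N axes (direction and noise admixture
solved in closed form from the requested contrasts and the tail
expectation of the normal), and the remaining samples split between
broadleaf and conifer at random. The printed type means emerge while the
pooled correlation structure is untouched.

**The observed RMT envelope is a diagnostic, not a default filter.**
Rejection-filtering to the observed range box distorts the target
correlations by up to 0.26, so `range_box_filter` is off by default; the
default marginals place ~99% of generated points inside the box anyway.

What the generator does *not* emulate: the exact marginal distributions
(a clipped Gaussian copula makes no compositional-distribution claim),
the RMT-plane correlation of protein with TNC (the pipeline recovers
~0.75 on synthetic data, not the published 0.84 — the generator targets
%-of-dm correlations, and the projection to macronutrient proportions
shifts them), any within-winter time trend, spatial autocorrelation, or
measurement error structure beyond i.i.d. noise. Passing tests therefore
show that the *machinery* reproduces known truth injected at the study's
effect sizes, not that synthetic data are distributionally
indistinguishable from field data. Known-truth slope recovery
consequently uses a direct bivariate simulator (`gen_balance_pairs`) at
the published effect sizes (0.84 and −0.97) rather than the full
generator.

## The NIR calibration stage

Real instruments scan 780–2,498 nm at 0.5 nm; the synthetic stage uses
the same range at 4 nm (431 points), which preserves the linear-mixture
structure that matters for the calibration contract at a fraction of the
cost. Spectra are linear mixtures of one fixed non-negative component
spectrum per constituent plus a smooth baseline and Gaussian noise.

Representative-subset selection reduces spectra to three PCA score
dimensions and ranks by Mahalanobis distance from the center, taking
extremes first and filling the rest stratified across distance ranks —
duplicated spectra are deferred so each distinct spectrum is taken before
any repeat. Calibration is partial least squares with the component count
chosen by k-fold cross-validation minimizing RMSEP; the component count
is capped at the numerical rank of the centered training matrix
(singular values above $10^{-7}$ relative), which keeps noiseless
low-rank spectra exactly recoverable without running PLS past the
identifiable subspace. Orthogonal-signal-correction variants
re-partition the same subspace for interpretability; they do not change
the prediction contract tested here. The published calibration statistics
themselves require the original spectra, which are not deposited, so this
module's acceptance is property-based: exact recovery at zero noise and
held-out $R^2 \ge 0.9$ at instrument-like noise.

## Problem sizes and numerical choices

The test suite runs the generator at n = 10,000 for correlation-fidelity
checks (sampling noise ~0.01 leaves clear margin inside the ±0.05
contract), n = 481 for pipeline-level checks (the field sample size), 20
seeds for slope recovery, and 1,000 replicates for the size of the
slope-vs-one test; calibration checks use 120 spectra. The whole suite
completes in well under a minute.

Other numerical conventions: the printed correlation matrix is very
slightly indefinite (smallest eigenvalue ≈ −3×10⁻⁴, a rounding artifact)
and is repaired by eigenvalue clipping before factorization; hull
vertices are ordered deterministically; PCA signs follow the
largest-loading convention; constant columns in correlation matrices are
flagged rather than silently NaN; a perfect-fit regression reports
`t_vs_one = 0` instead of 0/0; all generator draws go through an
RNG-preserving seed wrapper so the caller's random stream is undisturbed.

## Known limitations

* The balance between protein and TNC in RMT coordinates is flatter in
  synthetic data than published (see above); analyses of the *pipeline's
  statistical machinery* are unaffected, but synthetic runs should not be
  read as replications of the field coefficients.
* The quasi-binomial rescaling ceiling, the ADF-N split of total N (80%
  available by default), and the body-mass means for non-calf classes are
  plausible conventions, not measured quantities.
* The supplementary-feed fixture is mostly synthetic (see above).
* Printed per-type microbial-N means and the printed "49% of available N"
  summary are mutually inconsistent under AP levels compatible with the
  published RMT ranges; the generator follows the per-type means, so its
  microbial share of available N comes out near 35%, and the pipeline
  reports whatever it computes.
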