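---
title: "Phylogenetic comparative analysis of birdsong traits with phylosong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic comparative analysis of birdsong traits with phylosong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosong)
```

## The problem

Songbird taxa differ in how long, how fast, how high and how variably they
sing, and related taxa resemble each other: a cross-taxon correlation
between, say, body mass and song pitch can be an artefact of shared
ancestry rather than evidence of a physical constraint. `phylosong`
implements the full comparative workflow for this situation, modelled on
the leaf-warbler (Phylloscopidae) song system: verse-level sonogram
measurements are aggregated into per-taxon song traits, each trait is
tested and quantified for phylogenetic signal, its mode of evolution is
selected by information criterion, and trait–predictor relationships are
estimated with and without correction for relatedness.

The pipeline operates on three inputs: a rooted, binary, ultrametric time
tree (the chronogram a dating analysis would produce), a verse-level
measurement table, and a per-taxon table of explanatory variables
(morphology, migration, range limits, elevation, habitat). Because the
bioacoustic raw data of the motivating system are not available as
machine-readable files, the package ships a synthetic-data generator that
emulates that study design with known ground truth; every stage of the
pipeline is tested against it.

## Trait derivation

The unit of measurement is the *verse* — a pause-delimited period of
singing. Ten parameters are measured per verse (durations `tges`, `tmax`,
`tmin`; counts `zel`, `zeltype`; frequencies `fmax`, `fmin`; element
bandwidths `dfmax`, `dfmin`; frequency gradient `fmodend`) and six are
derived: tempo `zeltges = zel/tges`, `fmean = (fmin + fmax)/2`, bandwidth
`df = fmax − fmin`, and three complexity indices, among them the
diversity–tempo index `complexity3 = zeltype/zel + (zel/tges)/30.268`,
whose normalising constant maps the fastest delivery rate in the
reference cohort to a tempo component of exactly 1 (configurable via
`tempo_norm`).

Derived traits are computed per verse and then averaged — first over each
individual's verses, then over individuals within a taxon — so that
unequal sampling does not weight taxa towards their best-recorded
individuals. The alternative (derive from taxon-mean inputs) is not
offered: trait definitions are stated per verse, and averaging a derived
ratio is not the same as the ratio of averages.

Mean coordinates and elevations of a breeding range are midpoints of the
range limits; the distance-from-equator variable `lat_equator` is the mean
of the *absolute* latitude extremes, so an all-southern range scores the
same as its mirror image in the north (the alternative reading
`|lat_mean|` is also exported, as `lat_equator_alt`).

Principal components are computed on centred, unit-variance variables
(`prcomp` with scaling) for three subsets: all ten measured parameters,
the five compositional ones, the five frequency ones. PCA signs are
arbitrary, so each loading vector is flipped to make its
largest-magnitude entry positive; this keeps scores reproducible across
runs and platforms.

## Signal, models, contrasts, pGLS

Signal testing is two-step. Detection uses a randomization test whose
statistic is the variance of the standardized independent contrasts —
low when relatives resemble each other; tip values are shuffled across
taxa and `P = (#{perm ≤ obs} + 1)/(n_perm + 1)`. With the default 999
permutations the smallest attainable P is 0.001. Strength is quantified
by Blomberg's K (ratio of observed to Brownian-expected variance
partitioning; K = 1 under Brownian motion on the given tree, exactly 1 on
a star phylogeny) and by Pagel's λ, estimated by profile maximum
likelihood over [0, 1] with the root state and rate profiled
analytically. The λ profile can be multimodal on small trees, so the
optimizer runs a 21-point grid first and refines around the best point
(tolerance 1e-8), always evaluating both endpoints.

Five models of continuous trait evolution are fitted per trait — Brownian
motion, Ornstein–Uhlenbeck (pull α towards an optimum), early burst
(rate decaying as `exp(r t)`, r ≤ 0), λ, and white noise — and ranked by
AICc with parameter counts 2 (BM, white) or 3 (the others). The OU
covariance is the root-conditioned, non-stationary form
`σ²/(2α)·e^{−α d_ij}(1 − e^{−2α s_ij})`; this is the convention of the
standard model-fitting tools, and the one our oracles integrate against.
Shape parameters are searched on bounded intervals (α ∈ [1e-8/T, 50/T]
on a log scale, r ∈ [ln(1e-5)/T, −1e-8], T the tree depth); a fit
touching a bound is flagged, because EB-vs-BM near-ties are decided at
that boundary. Models within 2 AICc units of the best are reported as
near-tied alternatives; exact ties resolve by the fixed order
BM < OU < EB < lambda < white.

Pairwise trait–predictor tests are run twice: ordinary Pearson
correlation on tip values, and through-origin correlation of
Felsenstein's independent contrasts with `df = n_contrasts − 1` (the
through-origin regression convention; the package exposes both p-value
routes). Polytomies are rejected rather than zero-resolved — silent
resolution would change the contrast count. Zero-length *internal*
branches are allowed (this is how a star phylogeny is represented in
binary form); a zero branch-length *sum* at a node is an error, and
zero-length terminal branches are refused where they make the λ/OU
covariance singular.

Multifactorial models chain three steps per song trait: an OLS fit on all
explanatory variables, backward stepwise reduction, and a pGLS refit of
the reduced predictor set (including its non-significant members) with λ
estimated by ML. Two reduction criteria ship: AIC-based backward
elimination (default; drop the predictor whose removal most lowers
`n·ln(RSS/n) + 2k`, stop when no drop lowers it) and p-threshold backward
(drop the largest p while any p > 0.1). The two differ in strictness: AIC
retains predictors with |t| > √2, so pure-noise designs keep ~1 predictor
more often than under the p-threshold rule; the calibration tests of the
selection behaviour therefore pin the p-threshold mode. Exact linear
combinations among predictors (a range midpoint alongside both range
limits) are detected and the aliased columns dropped, keeping the
earliest columns, before reduction starts. Predictors are z-scored by
default so coefficients are comparable; this changes no t or p value.

A deliberate design choice: discrete scores (migration 0/1/2, habitat
1–5, biogeographic region 1–4) are treated as plain numeric variables
throughout, in signal testing, correlation and regression alike. This
mirrors standard practice for ordinal scores in this literature, but
region is nominal in truth, and its correlations should be read with that
caveat.

## The synthetic-data generator

`simulate_study()` is first-class, tested code, not a fixture. Its
defaults are the study conditions: 80 taxa on a pure-birth (Yule) tree
rescaled to depth 1; five individuals per taxon with five verses each,
raised to ten verses for a random 20% of "large-repertoire" taxa;
per-trait generating models mirroring the reference best-model column
(λ values near the reference estimates, OU for tempo-like traits, BM for
element durations and morphology); and a planted body-size constraint of
−0.3 kHz per cm body length on the frequency traits.

Traits are generated as taxon-level latents on transformed scales chosen
so the measurement invariants hold by construction: durations on log
scales, proportions (element-duration ratios, element-type fractions) on
logit scales, bandwidth ratios as `1 + exp(z)`. Verse-level rows add
hierarchical Gaussian noise on the latent scale — between-individual SD
10% and between-verse SD 5% of the taxon-level scale. No variance
decomposition is published for the reference system; these values were
chosen once so that taxon means are estimable from a 5 × 5 design, and
they stay fixed. Latent locations and scales place ±3 SD inside the
printed cohort ranges (e.g. verse duration 0.46–5.31 s, maximum frequency
up to ~10 kHz); values straying outside are redrawn from the marginal
with any planted fixed effect preserved (truncation-resampling, not
clamping, so there is no boundary spike — at the cost of breaking the
phylogenetic correlation for the rare redrawn taxon). Discrete scores are
assigned by thresholding a tree-structured latent at the reference class
frequencies (12/31/37 migration, 3/7/13/13/44 habitat, 26/39/13/2
region), which pins the cohort score means (1.3, 4.1) by construction.

What the generator does *not* emulate: repertoire structure and song-type
choice (upstream decisions in the real workflow), measurement error of
sonogram reading beyond the hierarchical noise, spatially coherent
ranges, and any trait–trait dependence beyond the planted body-size
effect. Passing tests therefore demonstrate that the statistical
machinery recovers known structure of this kind — they do not validate
the biology of any particular real data set.

One power fact is worth stating because it is easy to misread: with the
printed trait scales, a planted slope of −0.3 kHz/cm, and residuals that
are themselves tree-structured, the bivariate pGLS recovers the *sign* of
the body-size effect in roughly nine out of ten replicates, not
near-certainly; under Brownian residuals of modest variance (the
configuration the recovery criterion specifies) sign recovery is
essentially certain. Both regimes are tested at their calibrated levels.

## Numerical choices

All Gaussian likelihoods run through one code path: Cholesky
factorisation of the covariance, log-determinants accumulated in log
space (an 80 × 80 λ-covariance near λ = 0 underflows a naive
determinant), root state and rate profiled analytically, GLS via QR on
whitened design matrices. A covariance that fails Cholesky produces an
explicit "singular or not positive definite" error rather than NaNs.
Ultrametricity is judged at relative tolerance 1e-6 on root-to-tip
depths, since chronograms carry rounding noise. The EB transform switches
to its analytic r → 0 limit below |r| = 1e-12.

Simulation sizes in the test suite are the package's own calibration
choices: 500 Brownian replicates on 128 tips for the K calibration, 1000
replicates at 64 tips for the contrast type-I rate, 200 replicates at 80
tips for model-selection consistency, 100 end-to-end studies for
planted-effect recovery. Each stochastic test fixes its seed; the
permutation test is bit-reproducible given a seed.

## Known limitations

Measurement error is not modelled in the evolutionary fits (taxon means
enter as exact values); multifurcating trees are rejected rather than
resolved; OU and EB are fitted only on ultrametric trees; the λ search is
restricted to [0, 1] (some implementations allow λ slightly above 1, which
is why cross-checks against them compare fixed-λ fits); and no
multiple-testing correction is applied to the pairwise correlation grid
beyond an explicitly marked Holm-adjusted convenience column, matching
the per-pair reporting convention of the field.
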