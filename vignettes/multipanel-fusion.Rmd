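---
title: "Multi-panel cytometry fusion: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-panel cytometry fusion: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cytofuse)
```

## The model

`cytofuse` classifies case-control cytometry studies in which each blood
sample is measured in `M` separately stained aliquots with different
marker panels. The pipeline has two layers.

**Base layer (per aliquot).** After arcsinh transformation and
centring/scaling, a PCA with `K_base = 2` components is fitted on the
row-concatenated cells of all *training* individuals of one aliquot.
Every sample's cells are projected into this score space and binned on a
fixed `F x F` grid; the counts are smoothed with a small Gaussian kernel
and normalised to unit sum. A sample is thus summarised per aliquot as a
probability histogram over cell phenotypes — insensitive to cell count
and to cell order, but retaining the multivariate marker co-expression
through the PCA loadings.

**Top layer (fused).** The `M` unfolded histograms of each individual are
concatenated into one row of the fused matrix `H` (`I` rows, `F^2·M`
columns), which is mean-centred with the training-set column means.
OPLS-DA with a single predictive latent variable is fitted to `H` and the
class coding `y ∈ {-1, +1}`: `K_ortho` class-orthogonal components are
extracted iteratively (orthogonal weight = loading minus its projection
on the predictive weight) and deflated before the predictive component is
fitted. With `K_ortho = 0` the model is exactly one-component PLS-DA
(`w ∝ H'y`), which is how the implementation is unit-tested against an
independent closed-form oracle. VIP sparsification
(`VIP = sqrt(F*·w²)`, threshold 1, `F* = F^2·M` fused variables) zeroes
uninformative bins; the retained weights refold into one `F x F` map per
aliquot.

Assumptions worth stating: the discriminative structure must be (close
to) linear in bin abundances; panels are fused at the individual level,
so each individual needs a complete set of aliquot measurements; the
class label is binary; and the 2-component base model must capture the
phenotypic axes along which the classes differ — a deliberately low
dimension that makes the maps readable and the bins refoldable.

## Tunable parameters

* `cofactor` (default **150**, intensity units): arcsinh scale for
  conventional fluorescence data; values are compressed logarithmically
  above ~`cofactor` and linearly below.
* `F` (default **100** bins/dimension): grid resolution. 500 suits
  densely sampled data; 100 is right for samples with fewer than 10,000
  cells, where finer grids are dominated by counting noise.
* `smoothing_sd` (default **2** bins): Gaussian kernel width. Smoothing
  shares counting mass between neighbouring bins and is what lets OPLS
  exploit the correlation of nearby bins; 0 disables it.
* `margin_fraction` (default **0.05**): grid margin beyond the training
  score range, so that moderately out-of-range test cells fall into
  regular bins. Cells beyond the grid are clipped into edge bins —
  dropping them would silently change a sample's mass before the unit-sum
  normalisation.
* `K_ortho_max` (default **5**): cap for the leave-one-out selection of
  orthogonal components; ties resolve to the smallest `K` (parsimony).
* `vip_threshold` (default **1**): bins carrying less than their "fair
  share" of the unit-norm weight vector are zeroed. `NULL` disables the
  filter.
* Validation design: **5** folds, **50** repetitions, **1000**
  permutations by default.

## The synthetic generator

`simulate_study()` draws studies with known ground truth. Per individual
`i`, a latent factor `u_i ~ N(0,1)` is shared across all of that
individual's aliquots; per aliquot, population fractions follow a softmax
of `log(base_abundance) + class effect + loading·u_i + noise`; counts are
multinomial and events multivariate normal around population templates.
The softmax keeps abundances on the simplex under arbitrary effects — the
natural price is that planting an abundance increase in one population
forces a compensatory decrease in the others, exactly as in real
compositional cytometry data.

Three presets define the study designs used throughout the tests:

* **`null`** (20 vs 20 individuals, 2 panels, 2,000 cells/sample): no
  class effect; used to check calibration (chance-level accuracy,
  uninformative permutation p).
* **`single_panel_effect`**: the `immature` population of panel A1 rises
  from 10% (control) to 30% (case) in expectation, nothing else differs.
  Panel A1 carries seven additional broad background populations so the
  forced -20% compensation is spread thinly, as one expanding subset in
  blood dilutes many others a little.
* **`cross_panel_only`** (30 vs 30): `immature` (A1) and `activated`
  (A2) load +2.0/-2.0 on the latent factor, and `activated` carries a
  +1.6 logit class effect with small (0.05) independent logit noise. The
  latent variance dominates each panel's marginal, so single-panel models
  are weak; a fused model can cancel the latent factor across panels and
  recover the effect. The magnitudes were chosen at design time with an
  independent oracle (linear discriminant analysis on the realized
  population fractions of a large simulated cohort) so that the
  construction itself — not any particular pipeline — has a near-chance
  panel A, a weak panel B and a strong fused signal; matched base
  abundances of the two latent-coupled populations keep the factor's
  effect on the two panels' fractions of similar size, which is what
  makes a *linear* fused model able to cancel it.

What the generator does **not** emulate: spillover/compensation,
debris and doublets, acquisition-time drift, heavy-tailed or skewed
marker distributions, and gating hierarchies deeper than threshold
predicates. Passing tests on these designs therefore demonstrate the
correctness and the statistical behaviour of the pipeline under its own
model assumptions, not robustness to instrument artifacts.

## Numerical choices

* **Smoothing** uses a 1D Gaussian kernel (truncated at 4 sd) applied
  separably, with *reflecting* boundaries: kernel mass falling off the
  grid is folded back, so every column of the smoothing operator sums to
  1 and total mass is conserved exactly before normalisation.
* **PCA signs** are fixed deterministically (largest-magnitude loading
  element positive) so maps are reproducible across runs and platforms.
* **Unfolding** is row-major — bin `(f1, f2)` of aliquot `m` sits at
  column `(m-1)F² + (f1-1)F + f2` — and `refold_weights()` is its exact
  inverse (tested as a round trip).
* **Leave-one-out selection of `K_ortho`** runs in dual (Gram)
  coordinates: every OPLS vector lies in the span of the training rows,
  so one `O(I²p)` Gram computation replaces `I` refits of the `I x p`
  problem. A unit test pins the dual path to a brute-force primal
  leave-one-out on small problems.
* **Degenerate inputs** raise typed errors rather than proceeding:
  zero-SD reference markers (silent dropping would corrupt panel
  alignment), rank-deficient base-model data, zero-cell gates and
  histograms, incomplete sample x aliquot designs, `K_ortho` beyond the
  orthogonal rank.
* **Lasso lambda** (comparator) is selected at minimum mean inner-CV
  deviance with deterministic stratified fold ids, so comparator results
  are reproducible without consuming the global RNG stream.

## Design decisions on genuinely open points

* **Classification threshold**: the midpoint of the two training-class
  mean prediction scores. With the symmetric `{-1, +1}` coding and
  balanced classes this is ~0; the midpoint rule also behaves sensibly
  under imbalance. Final metrics classify each individual's mean
  prediction score against the mean of the per-fold thresholds.
* **VIP filtering** zeroes sub-threshold weights and re-estimates only
  the regression scalar, without refitting the orthogonal components; a
  `refit_after_vip` flag offers the refitting variant. `F*` is the total
  number of fused variables, i.e. the VIP is computed on the fused model
  covering all aliquots jointly.
* **Paired designs**: both samples of an individual are constrained to
  the same fold (identity leakage would otherwise inflate accuracy), and
  permutations flip an individual's pair of labels as a unit; for
  case-control designs labels permute across individuals.
* **Permutation cost**: each permutation refits the full pipeline on a
  single repetition of the stored split design, with `K_ortho` (and
  lasso lambda) frozen at the unpermuted choice — the standard shortcut
  that removes the inner selection loop; the repetition count is
  configurable.
* **SOM node counts** are normalised to per-sample fractions before
  classification (raw counts confound total cell number with abundance);
  a count mode is available. The SOM itself is batch-trained on a
  10 x 10 grid with PCA-plane initialisation, which makes training
  deterministic given the data.
* **Weight-mass localisation** (how concentrated the retained weights
  are on a planted population) is measured on squared weights — the
  scale on which VIP is defined. The L1 share is structurally capped
  near one half under any simplex-renormalizing generative model,
  because a planted abundance increase forces an equal total negative
  weight mass on the compensating populations.

## Problem sizes used by the test suite

The repeated double cross-validation in the packaged checks runs the
preset designs at 5 folds x 10 repetitions, the permutation check at 200
permutations, and the exhaustive minimum-spanning-tree oracle at 8 nodes;
these sizes give stable statistics for the scenario effect sizes above
while keeping the whole suite in the minutes range. The defaults
(50 repetitions, 1000 permutations) remain the recommended settings for
real studies.

## Known limitations

* One predictive latent variable: binary contrasts only.
* `K_base` is fixed at 2 by the refolding of weights into `F x F` maps;
  structure orthogonal to the first two pooled principal components of an
  aliquot is invisible to the model.
* Histogram features are abundance-compositional; purely
  marker-shift effects appear only insofar as they move cells across
  bins.
* The FCS reader/writer covers plain list-mode FCS 3.0/3.1 (float or
  byte-aligned integer data) without compensation keywords or analysis
  segments.
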