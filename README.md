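# cytofuse

Multi-panel flow cytometry fusion with histogram fingerprints and OPLS-DA.

## The problem

Multicolour flow cytometry measures a handful of protein markers on every
cell of a blood sample, but spectral overlap caps the number of markers per
measurement. Studies therefore stain several **aliquots** of the same
sample with different antibody panels — e.g. a B-cell panel, a T-cell panel
and an innate-cell panel. Analysing each panel separately discards the
information carried *between* panels: cell populations whose abundances are
individually uninformative for a clinical contrast can be strongly
predictive jointly, through their covariance across panels (the
*multivariate advantage*).

`cytofuse` implements a DAMACY-style fusion pipeline for case-control
studies with multiple panels, for immunologists and computational
cytometrists who want a single interpretable discriminant model across all
panels:

1. **Per-aliquot fingerprints.** Events are arcsinh-transformed
   (`asinh(x / 150)`), centred/scaled (cohort-reference or
   paired-individual scheme), and projected onto a 2-component PCA fitted
   on the pooled training cells of that aliquot. Each sample becomes a
   smoothed, unit-sum `F x F` histogram in score space (`F = 100` by
   default, suited to samples with fewer than 10,000 cells).
2. **Fusion.** The unfolded histograms of the `M` aliquots are
   concatenated into one matrix `H` (`I x F^2·M`, one row per individual)
   and mean-centred with the training means. Unit-sum blocks give every
   panel equal a-priori weight.
3. **Discrimination.** An OPLS-DA top model with one predictive latent
   variable is fitted to `H` and the class dummy `y ∈ {-1, +1}`; the
   number of class-orthogonal components is chosen by an internal
   leave-one-out cross-validation. Variable importance in projection,
   `VIP_f = sqrt(F* · w_f²)` with `F* = F^2·M` and unit-norm weights
   `w`, zeroes all bin weights with `VIP < 1`.
4. **Interpretation.** The sparse weight vector refolds into an
   `F x F x M` array — one *leukocyte map* per aliquot, with PCA loading
   arrows and per-class 80%-mass density contours — showing exactly which
   cells drive the classification and their marker co-expression.
5. **Validation.** Stratified 5-fold cross-validation repeated 50 times
   with stored splits (reused identically by every comparator method),
   per-individual mean prediction scores, and a permutation test
   (`p < (Σ[acc_perm ≥ acc_model] + 1) / 1000`) with hyperparameters
   frozen at the unpermuted choice. `panel_increase()` reports how many
   accuracy percentage points each panel contributes to the fusion.

Comparator arms (SOM node-count featurization with linear SVM, lasso
logistic regression or OPLS-DA; SVM on the fused histograms) and a
synthetic multi-panel study generator with known ground truth are
included, so every stage is testable without clinical data.

## Worked example

```r
library(cytofuse)

preset <- scenario_preset("single_panel_effect", seed = 11)
study  <- simulate_study(preset$templates, preset$config)
study
#> <study_dataset> 40 samples x 2 aliquots (A1, A2); classes: case=20, control=20

splits <- make_splits(study$labels, groups = study$individuals,
                      n_folds = 5, n_repetitions = 10, seed = 12)
cv <- run_double_cv(study, pipeline_config(), splits)
cv
#> <cv_result> 40 samples, 10 repetitions
#>   accuracy 1.000 | sensitivity 1.000 | specificity 1.000

model <- fit_fusion_model(study, pipeline_config())
sum(model$model$w_top != 0)
#> [1] 1196      # histogram bins retained by the VIP filter (of 20,000)

pt <- permutation_test(study, pipeline_config(), splits, cv$accuracy,
                       fixed_hyperparameters = list(K_ortho = model$K_ortho),
                       n_permutations = 100, seed = 13)
pt$p_bound
#> [1] 0.01
```

This scenario plants one effect: the `immature` population of panel A1
rises from an expected 10% of cells in controls to 30% in cases. The
double cross-validation classifies every individual correctly (accuracy,
sensitivity and specificity all 1.000), no permuted labelling reaches the
observed accuracy (`p < 1/100`), and the VIP filter keeps ~6% of the
20,000 fused bins — concentrated, as `plot_leukocyte_map()` shows, on the
planted population's region of the A1 score space.

For interpretation figures:

```r
maps <- class_mean_histograms(model, study)
plot_leukocyte_map(model$weight_maps, "A1", model$base_models[["A1"]],
                   model$grids[["A1"]], class_histograms = maps[["A1"]],
                   file = "map_A1.png")
plot_scores(cv$mean_scores, study$labels, cv$threshold, file = "scores.png")
```

A command-line front end for the whole pipeline (simulate / fit /
crossval / permtest / compare / map) is installed at
`system.file("cli", "cytofuse.R", package = "cytofuse")`.

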