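# facejudge

Predicting — and auditing — human social judgments from facial feature
spaces.

People form fast consensus impressions of unfamiliar faces (trustworthy,
dominant, attractive, baby-faced, ...), rated on 1–7 Likert scales and
averaged across raters per face. A widely used modelling strategy predicts
these mean ratings from a numeric representation of each face — an
identity embedding, PCA-reduced convolutional activations, or
landmark-derived facial geometry — with one regularized linear model per
attribute. Because a small number of latent psychological dimensions
accounts for most of the variance in such judgments, these models raise a
sharp interpretive question: does a model trained to predict, say,
*criminal-looking* learn that attribute, or a correlated neighbour such as
*masculine*? facejudge implements the predictive pipeline **and** the
audit toolkit for answering that question.

## What the package computes

For each attribute $a$ the model is $\hat y_a = X w_a + b_a$, with $w_a$
from ridge regression (LASSO and OLS available for robustness checks). The
regularization strength is selected by repeated random-split
cross-validation: 2000 seeded 80/20 splits, a 30-value grid log-spaced
over $[1, 10^5]$, mean validation MSE per grid value, minimizer refit on
all faces. Around that core:

* **Out-of-sample evaluation** — bootstrap mean and SD of Spearman's
  $\rho$ (10,000 resamples at full scale; one image drawn per identity for
  multi-image "ambient" sets), permutation chance thresholds (95th
  percentile of the shuffled null), permutation p-values, and
  Benjamini–Hochberg FDR across the evaluated family. Antonym attributes
  are predicted by negating a model's weights.
* **Variance partitioning** — for feature spaces A and B, test-set
  $R^2$ of models on A, B, and their concatenation yields
  $R^2_{uA} = R^2_{A\cup B} - R^2_B$,
  $R^2_{uB} = R^2_{A\cup B} - R^2_A$, and
  $R^2_{A\cap B} = R^2_A + R^2_B - R^2_{A\cup B}$, with bootstrap SDs and
  one-sided bootstrap p-values.
* **Cross-prediction specificity** — the full matrix of (model for
  attribute *i*) × (human ratings of attribute *j*), FDR over all cells,
  per-row best-predictor flags, and dataset-level summaries.
* **Semi-partial residual analysis** — rank correlation between human
  ratings and the residuals of one model's predictions after regressing
  out another model's predictions; identifies the single attribute whose
  model carries most of the cross-prediction structure.
* **Facial geometry** — 30 interpretable measures (eye size/shape, face
  widths and lengths, fWHR, ...) from 68-point landmark sets.
* **PCA feature reduction** — reference-set basis, mean-anchored
  projection, and predictive selection of the component count from
  training ratings only.
* **Synthetic worlds** — a seeded generator producing correlated Likert
  ratings from K latent dimensions, feature spaces with controlled
  shared/unique signal, disjoint test sets with fresh raters, ambient
  multi-image sets, and a style perturbation with per-space sensitivity;
  every downstream stage is testable against known ground truth.

## Worked example

```r
library(facejudge)

cfg <- synthetic_world_config(
  n_latent = 2, n_train_faces = 183, n_test_faces = 60, n_attributes = 5,
  rating_noise_sd = 0.65, seed = 42,
  feature_space_specs = list(
    feature_space_spec("identity-like", 32, signal_fraction_shared = 0.7,
                       signal_fraction_unique = 0.2, noise_sd = 0.1)))
world <- generate_world(cfg)

models <- fit_all_attributes(world$train$features[["identity-like"]],
                             world$train$ratings,
                             fit_config(n_cv_iterations = 200, seed = 1))
models[["attr01"]]
#> <fitted_model> attr01 ~ identity-like (ridge), 32 features, lambda = 52.98317

test <- world$test_sets[[1]]
res <- evaluate_models(models, test$ratings, test$features[["identity-like"]],
                       n_boot = 1000, n_perm = 1000, seed = 2)
print(res[, c("model_attribute", "mean_rho", "boot_sd", "chance_threshold",
              "p_perm", "q_fdr", "significant")], digits = 3)
#>   model_attribute mean_rho boot_sd chance_threshold p_perm q_fdr significant
#> 1          attr01    0.741  0.0540            0.216      0     0        TRUE
#> 2          attr02    0.820  0.0485            0.216      0     0        TRUE
#> 3          attr03    0.717  0.0683            0.200      0     0        TRUE
#> 4          attr04    0.772  0.0508            0.224      0     0        TRUE
#> 5          attr05    0.796  0.0514            0.231      0     0        TRUE
```

Each row: mean bootstrap accuracy on 60 novel faces with fresh rater
noise, its bootstrap SD, the permutation chance threshold (95th percentile
of the shuffled null), and the FDR-corrected permutation p-value — every
attribute clears chance here. The specificity audit for the same models:

```r
cpm <- cross_prediction_matrix(models, test$ratings,
                               test$features[["identity-like"]],
                               n_boot = 500, n_perm = 500, seed = 3)
cpm
#> <cross_prediction_matrix> 5 test attributes x 5 models ('identity-like')
#>   significant cells: 11 / 25

print(cross_prediction_summaries(cpm), digits = 3)
#>   control mean_abs_rho mean_row_max_abs_rho frac_significant most_impactful
#> 1    none        0.423                0.675              0.3           FALSE
```

Eleven of 25 matrix cells are significant although only five are
self-predictions: models trained on one attribute also predict correlated
attributes (mean off-diagonal $|\rho| = 0.42$), the package's central
cautionary observation. `semi_partial_residual_matrix()` then shows which
model's predictions account for that shared structure.

An end-to-end run with every artifact (CSV/JSON plus a checksummed
manifest) is one call:

```r
run_pipeline(demo_run_config(seed = 1), output_dir = "demo_run")
```

or, from a shell, `Rscript inst/cli/facejudge.R run --seed 1 --out demo_run`.

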