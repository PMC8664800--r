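---
title: "Modelling and auditing social judgments from facial feature spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and auditing social judgments from facial feature spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facejudge)
```

## The problem

People form rapid consensus impressions of unfamiliar faces — how
trustworthy, dominant, or attractive someone looks — and those impressions,
valid or not, shape consequential decisions. A popular modelling strategy
predicts the *mean human rating* of each face on each social attribute from
a numeric representation of the face: an identity embedding from a network
trained for face recognition, reduced activations of an object-recognition
network, or interpretable landmark-derived geometry. Because many social
judgments are highly inter-correlated — a handful of latent psychological
dimensions typically account for most rating variance — a model fitted to
one attribute may in fact be predicting a correlated neighbour. facejudge
implements both halves of the workflow: the predictive pipeline, and the
audits (variance partitioning, cross-prediction matrices, semi-partial
residual analysis, style-robustness contrasts) that reveal what such models
actually learn.

Real face databases and their rating sets cannot be redistributed here, so
the package ships a generative model of the *statistical situation* — the
synthetic world — and every claim the test suite makes is a claim about
recovering that world's known ground truth.

## The regression model

For each social attribute $a$ and feature space with design matrix
$X \in \mathbb{R}^{n \times p}$ (faces × features), the package fits

$$\hat{y}_a = X w_a + b_a,$$

with $w_a$ estimated by ridge regression,
$\min_w \lVert y - Xw - b\rVert^2 + \lambda \lVert w \rVert^2$. The
regularization strength is chosen by repeated random-split
cross-validation: the training faces are split 80/20 into fit and
validation parts (2000 independent splits by default; splits are sampled
per iteration, not folds), every value of a 30-point grid log-spaced over
$[1, 10^5]$ is fitted on the 80% and scored on the 20% by mean squared
error, per-grid-value errors are averaged across splits, and the minimizer
is refit on all faces. LASSO (grid $[0.01, 100]$, via glmnet) and OLS (no
tuning) run through the same protocol for robustness comparisons; ridge
solutions are computed exactly from the SVD of the standardized design, so
the whole grid costs one decomposition per split.

Choices the data cannot make for us, and what we chose:

* **Feature standardization.** Features are z-scored with training-fold
  statistics inside every cross-validation fold, and with full-sample
  statistics at refit. This is what makes one $\lambda$ grid meaningful
  across feature spaces with different native scales; it is switchable
  (`standardize = FALSE` in `fit_config()`).
* **Tie-breaking.** When several grid values achieve the minimal average
  validation error, the smallest $\lambda$ wins: equal error buys no extra
  shrinkage.
* **Constant columns** are rejected rather than silently dropped — a
  z-scored constant is undefined, and a constant feature cannot carry
  signal.
* **Antonym prediction.** A model can predict a semantically opposite
  attribute by negating its weight vector (`flip_sign = TRUE` in
  `predict()`); the intercept is left alone because all evaluation is
  rank-based and therefore shift-invariant.

## Evaluation

Accuracy is Spearman's $\rho$ between predicted and observed mean ratings
on held-out faces — rank-based because test sets may use different rating
scales. Uncertainty comes from resampling test faces with replacement
(10,000 iterations at full scale) and reporting the mean and SD of $\rho$
across resamples. For multi-image "ambient" sets, each bootstrap
iteration first draws one image per identity and then resamples
identities, so prolific identities do not dominate; when every identity
has one image this reduces *exactly* to plain resampling. Chance levels
come from shuffling the test ratings across faces: the 95th percentile of
the shuffled-$\rho$ distribution is the chance threshold, and the p-value
is the plain proportion of null draws at or above the observed $\rho$
(an add-one smoothed variant is available behind `smooth = TRUE`, default
off). p-values are Benjamini–Hochberg corrected across whatever family is
being reported — the attribute set for ordinary evaluation, *all cells*
for a cross-prediction matrix; the family is per-dataset, matching how
the results are tabulated. Bootstrap resamples in which either vector is
constant are skipped and counted, not scored as zero.

## Variance partitioning

To compare two feature spaces A and B, three models are fitted with the
same split sequence — on A, on B, and on the concatenation (jointly
re-standardized, same grid) — and each predicts the test set. With
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (SST about the test-sample mean;
the training mean is available via `baseline = "train"`):

$$R^2_{uA} = R^2_{A\cup B} - R^2_B,\qquad
  R^2_{uB} = R^2_{A\cup B} - R^2_A,\qquad
  R^2_{A\cap B} = R^2_A + R^2_B - R^2_{A\cup B}.$$

These identities are exact by construction and are asserted to machine
precision in every bootstrap draw. Out-of-sample components can be
negative; they are reported as-is because preserving the identity
outranks cosmetic truncation. The in-sample OLS inequality
$R^2_{A\cup B} \ge \max(R^2_A, R^2_B)$ is asserted only in-sample — it can
legitimately fail out-of-sample and under regularization. Component
p-values are one-sided bootstrap tail probabilities of crossing zero,
oriented by the sign of the point estimate (the natural reading of
"different from zero" for a signed component); pairwise component
differences are tested the same way.

## Cross-prediction and semi-partial residuals

The specificity audit scores every fitted model against the human ratings
of every test attribute, including attributes with no trained model — the
matrix is rectangular. The highest-$|\rho|$ cell per row is flagged: when
a row's best predictor was trained on a *different* attribute, predictions
are not attribute-specific. The semi-partial analysis asks which single
model carries that shared structure: for control model Z, every other
model's predictions Y are residualized on Z by OLS *on the raw predicted
scores*, and the residuals are rank-correlated with the human ratings X.
The OLS-then-rank hybrid is deliberate: "semi-partial Spearman" is
otherwise ambiguous, and this form controls the *linear* contribution of
Z's predictions while keeping the final accuracy metric rank-based.

Two boundary cases are defined, not errored:

* A constant-prediction control (e.g. an all-zero-weight model) regresses
  Y on the intercept alone, so residuals are centered Y and the residual
  matrix equals the raw one — a control that predicts nothing removes
  nothing.
* A model fully absorbed by the control (residual variance numerically
  zero, e.g. controlling a model with itself) is flagged degenerate and
  excluded from scoring and summaries.

Dataset-level summaries — mean $|\rho|$ over cross-prediction cells, mean
per-row maximum $|\rho|$, fraction of significant cells — exclude
same-attribute (self-prediction) pairs, so they measure cross-prediction
proper. The control minimizing mean residual accuracy is marked as most
impactful.

## Facial-geometry features

`compute_geometry_features()` turns a 68-point landmark set (iBUG 300-W
ordering; pupils approximated by eye-landmark centroids) plus a
precomputed median skin-luminance scalar into 30 interpretable measures
(eye sizes and shapes, face widths and lengths, the facial
width-to-height ratio, and so on). Faces are first canonicalized by
rotating the pupil line horizontal; every measure is a distance or a
ratio of distances, so all features are translation- and
rotation-invariant and the ratio features are scale-invariant. The
measure *names* follow the social-perception literature, but several
(cheekbone prominence, nose shape, face shape) have no standard formula;
the definitions adopted here are assumptions, centralized in
`geometry_feature_registry()` so they can be revised in one place without
touching the pipeline. No face detection, landmarking, or segmentation is
performed — landmarks and the luminance scalar are inputs.

## Dimensionality reduction

High-dimensional spaces are reduced by PCA fitted on a *reference* face
set (centering, no per-feature scaling — features within one space share
units). Projection always subtracts the reference mean, never the
projected set's own mean, so training and test faces land in the same
coordinates. The component count is selected by scanning candidates and
scoring each by the mean cross-validated Spearman accuracy across
attributes at the MSE-selected regularization strength, using
*training-set ratings only*; ties within $10^{-9}$ go to fewer components
(parsimony). Nothing in basis fitting or selection ever sees test
ratings.

## The synthetic world

`generate_world()` emulates the data-generating situation the analysis
assumes:

* **Latent structure.** Each face has a $K$-dimensional standard-normal
  latent score ($K$ = 2–4 is the empirically typical regime). Each
  attribute's mean rating is an affine map of its loading row (rows are
  unit-normalized, so the cosine between two rows is the designed
  noiseless inter-attribute correlation) scaled to 1 Likert unit of
  signal SD, placed mid-scale, plus noise, then clipped to the scale.
* **Rater averaging** is analytic: noise SD is divided by
  $\sqrt{n_\text{raters}}$ rather than simulating individual raters,
  because the modelling target is the per-face mean. Clipping after noise
  slightly distorts the extreme tails (about 0.3% of faces at default
  settings); evaluation is rank-based, so this is acceptable.
* **Feature spaces** are linear images of the latent scores (so true
  generating weights are well-defined: the package records the
  population-optimal linear weights for every attribute in every space),
  plus a linear image of space-specific latent factors unrelated to
  ratings, plus i.i.d. noise. A space may be exposed to a *subset* of the
  rating latents; exposing two spaces to overlapping but unequal subsets
  creates exact ground-truth unique and shared explained-variance
  components for validating the partitioning stack.
* **Test sets** use disjoint face identifiers and fresh rater noise
  (independent raters), with the linear maps held fixed so fitted weights
  transfer. Ambient sets replicate each identity across several images
  with fresh image-level feature noise and per-image rater noise, and
  carry an identity map for the identity-aware bootstrap.
* **Style perturbation.** A dataset-level change of image style is
  emulated as rank-one contamination: one shared random direction per
  dataset, with a per-face random magnitude, scaled by the space's style
  sensitivity. A purely constant offset was rejected as the
  operationalization because rank-based accuracy is invariant to constant
  shifts in predictions — it could not model a style change that hurts
  accuracy at all. Style-invariant spaces (sensitivity 0) are returned
  bit-identical.

What the generator does **not** emulate: individual-rater response styles
and disagreement, race and context effects, non-linear feature–judgment
relationships, and the heavy-tailed, correlated noise of real DCNN
activations. Passing tests therefore demonstrate that the *pipeline*
recovers known structure under its own assumptions — linear signal,
Gaussian noise, exchangeable faces — not that any particular real-world
feature space behaves this way.

## Reproducibility and numerical choices

All randomness flows through explicit integer seeds; pipeline stages and
per-cell analyses derive their own seeds deterministically from a global
seed plus a stage label (`derive_seed()`), so no two stages share a
stream and a whole run is byte-reproducible from one integer (the
pipeline manifest records MD5 checksums of every artifact). Ridge uses
the exact SVD solution; PCA uses `prcomp`; rank correlations average tied
ranks. Exhaustive permutation enumeration is available for $n \le 8$ and
is used to validate the sampled null. Default iteration counts in the
demonstration configuration (60 CV splits, 200 bootstrap/permutation
iterations) are sized for interactive use; `paper_scale = TRUE` restores
the full-scale 2000/10,000/10,000 counts. The test suite exercises worlds
of 100–1500 training faces, 60–1000 test faces, and 10–32 features per
space — large enough for the generative ground truth to be recovered
within stated tolerances, small enough to run in minutes.

## Known limitations

* The 30 geometry formulas imitate manually measured conventions but are
  not validated against any manual measurement set.
* The semi-partial analysis controls one model at a time; no multi-control
  partialing is provided.
* Only pairwise variance partitioning is implemented (no three-way
  decomposition).
* LASSO refitting at a single grid value relies on glmnet's path solver
  and is approximate at the default tolerance, unlike the exact ridge
  path.
* Likert clipping makes designed attribute correlations slightly
  conservative near the scale bounds.
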