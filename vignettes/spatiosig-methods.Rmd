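---
title: "Methods: spatiotemporal phospho-signaling models of cytotoxic sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal phospho-signaling models of cytotoxic sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatiosig)
```

## The problem

High-content imaging can resolve where and when a phospho-signal changes
inside a cell within the first hour of a cytotoxic stimulus such as
TNF-alpha. This package implements a pipeline that asks whether those
early, subcellular-region-resolved changes are sufficient to predict the
eventual cytotoxic sensitivity of a cell-line panel, and whether a sparse
model built from them can predict the effect of co-treatments it never saw
during training. The pipeline has five analysis stages plus a synthetic
data generator with planted ground truth:

1. **Subcellular zonation** (`partition_cell`, `quantify_regions`): a
   segmented cell is partitioned into nine regions (whole cell, cytoplasm,
   nucleus; outer/inner cytoplasm, peri-nucleus; outer/inner nucleus;
   chromosome) and the total phospho intensity is summed per region.
2. **Dose-response indexing** (`fit_loglogistic3`, `activity_auc`,
   `cytotoxicity_index`): cleaved-caspase-3 and EdU dose curves are fitted
   with a 3-parameter log-logistic; the activity area over a fixed 12-point
   log-dose grid is combined into a per-line sensitivity index.
3. **Signal profiling** (`aggregate_wells`, `normalize_profiles`,
   `build_feature_matrix`): per-cell totals become well means, replicate
   averages, and log2 fold changes against time 0, giving 1170
   (signal x region x time) events per cell line for the full design.
4. **SVM ranking** (`assemble_dataset`, `evaluate_signal`,
   `rank_and_select`): each signal's single-cell discriminability between a
   sensitive and a resistant line is scored by the cross-validated balanced
   accuracy of an SVM, and signals above 80% are carried forward.
5. **Sensitivity regression** (`loo_cv`, `final_model_and_predict`): a
   bootstrapped elastic net with leave-one-cell-line-out cross validation
   maps events to the sensitivity index; the consensus two top-weight
   features define a final OLS model applied, without refitting, to
   co-treatment measurements.

## Region zonation

Bands are defined by binary erosion/dilation with a Euclidean disk
structuring element, computed through an exact distance transform:

* outer nucleus = nucleus minus its erosion by 3 px (inner nucleus is the
  remainder);
* peri-nucleus = dilation of the nucleus by 6 px, restricted to the
  cytoplasm;
* outer cytoplasm = the 4 px band inside the cell boundary, minus the
  peri-nucleus where the two overlap (the peri-nuclear band takes
  precedence in thin cells — fixed, documented tie-break);
* chromosome = Otsu-thresholded DNA-bright pixels inside the nucleus. It
  overlaps the nuclear bands and is excluded from additivity checks.

Pixel-grid morphology carries a convention choice: center-to-center
distances overestimate the distance to the continuous region boundary by
about a quarter pixel on average, so the thresholds include a +0.25 px
correction; with it, eroding a rasterized disk of radius R by r lands
within a few percent of the continuous disk of radius R − r. Whether the
upstream imaging software measured its bands in Euclidean or chessboard
metric is not knowable from the outside; Euclidean disks are used and the
choice is isolated in `erode_mask`/`dilate_mask`. Intensity additivity
(whole cell = cytoplasm + nucleus, and the leaf bands summing to their
parents) holds exactly by construction, not approximately, and is asserted
in the tests.

Segmentation itself is out of scope: masks are inputs. Raster I/O uses
plain-text PGM because no TIFF codec is available in the supported
environment; the in-memory representation is an ordinary numeric matrix,
so any reader can be substituted.

## Dose-response model and the sensitivity index

Responses are log2 ratios to the minimum response, defined as the median
readout across replicates at the lowest dose (0.01 ng/mL). The fitted
model is `f(x) = d / (1 + exp(b (ln x − ln e)))` with `b` the slope
(negative for curves increasing with dose), `d` the top asymptote, and `e`
the midpoint in ng/mL. Fitting is plain least squares with a multi-start
over slope signs and midpoint quantiles followed by Gauss-Newton
polishing; tolerance is driven to machine precision so noiseless curves
round-trip their parameters to 1e-6, which the tests assert.

The activity area is the sum of the fitted curve over the fixed grid
`10^-2, 10^-1.5, ..., 10^3.5` ng/mL (12 points). It is positive for
induction (caspase-3) and negative for suppression (EdU). The composite
index for line *j* is

    CI_j = 1/2 ( AUC_casp_j / max_k AUC_casp_k + (−AUC_edu_j) / max_k (−AUC_edu_k) )

normalized by the panel maximum so the most sensitive line scores 1. The
source describes this index only through a caption and sign conventions
(the equation itself is an unreadable figure in the available text), so
the implemented form is a documented reconstruction; the alternative
reading — normalize the plain average — differs only by per-readout
constants and is switchable via the `form` argument.

The viability (resazurin-type) variant subtracts mean blank fluorescence,
divides by matched vehicle-control wells, converts to percent non-viable,
and sums over doses. Co-treatment effects are expressed as
delta-sensitivity: the condition's index divided by its solvent control.

## Signal profiling and QC

Wells with fewer than 100 cells are dropped. Replicate well means are
averaged **before** the log2 ratio (the order matters because the log of a
mean is not the mean of logs; averaging first follows the stated
processing order of the source pipeline). Every profile is exactly 0 at
time 0. Changes below 30% (|log2 fc| < 0.379) can be masked as no-change;
the boundary is inclusive. Masking is a QC/display rule and is **not**
applied before regression. Replicate discordance is flagged when the
across-replicate CV exceeds 3x a reference CV of 0.10, the typical
control-well variation.

## SVM ranking

No SVM library is available in the supported environment, so the solver is
built in: a dense-kernel C-SVC trained by sequential minimal optimization
with maximal-violating-pair working-set selection, RBF and linear kernels.
It is validated against linearly separable constructions, chance-level
null data, and a hand-computed balanced-accuracy oracle.

Protocol: 100 cells sampled per (time, line, replicate) stratum (4000 rows
under the default design); features are the 9 region totals plus the time
point (or whole-cell total plus time); stratified 3-fold CV repeated 3
times; features scaled to [−1, 1] with coefficients learned on the
training fold only; `(C, gamma)` selected by an inner 3-fold grid search
scored by balanced accuracy. The default grids are the conventional coarse
powers of two, `C ∈ 2^{−5..15}`, `gamma ∈ 2^{−15..3}` (the source's exact
grids are unreadable in the available text); tests use reduced grids to
stay inside their time budget, which changes nothing structurally. Fold
assignment is by cell, not by well, matching the source protocol and its
stated sampling-bias caveat; a by-well grouping would be the natural
extension.

## Sensitivity regression

Per training set (7 of 8 lines): (1) drop features with CV < 2% or
|Pearson r to the index| < 0.1 — statistics from training lines only; (2)
z-score with frozen training statistics; (3) choose `(alpha, lambda)` by
an inner leave-one-out CV over the training lines, minimizing RMSE along
the automatic lambda path for each `alpha ∈ {0.1, ..., 1.0}`; (4) run 500
bootstrap resamples (lines resampled with replacement at original size),
refit at the fixed `(alpha, lambda)`, and score each feature by its
non-zero frequency; (5) drop features with robustness < 0.8 and refit. A
fold converges when at least one feature survives with a non-zero
coefficient. `R_all`, `tau_all`, `RMSE_all` are averaged per-fold metrics
over all lines (training fits plus the held-out prediction), computed over
converged folds only; `R_test`/`tau_test` pool the held-out predictions.
Model comparison uses the variance-corrected resampled t-test
(correction `n_test/n_train = 1/7` for LOO folds) on paired held-out
squared errors.

Numerical notes: glmnet is the elastic-net engine (the same engine the
source protocol names). It standardizes the response internally, which
rescales the effective L2 penalty by 1/sd(y); the dual-route oracle tests
therefore compare on unit-variance responses, where the plain
elastic-net objective and glmnet's coincide to 1e-6. Single-lambda glmnet
calls are loose by design, so every fixed-lambda fit walks a short
warm-started path down to the target lambda.

## The synthetic world

The generator emulates: 8 cell lines with true sensitivities spread
~30-fold over [0.03, 1]; 13 signals x 9 regions x 10 time points (0-55
min); 2 replicates; 10 doses from 0.01 to 3000 ng/mL plus vehicle (an
exact three-fold ladder cannot connect those published endpoints in 10
steps, so the ladder is geometric at ~4.06x); multiplicative lognormal
noise at the cell and well level; log-logistic dose responses whose top
asymptotes scale with true sensitivity; and a planted linear law

    s = 0.369 f1 − 0.175 f2 − 0.15

where `f1` is the pRSK outer-cytoplasm log2 amplitude at 55 min and `f2`
the outer-nucleus amplitude at 2 min.

Three structural choices matter and were forced by identifiability
analysis, not tuned against test outcomes:

* **Planted components are localized bumps.** The law is pinned to exactly
  two (signal, region, time) triples. If the planted series scaled a broad
  bump, neighboring time points would be proportional copies of `f1` and,
  after z-scoring, indistinguishable from it; no sparse learner could then
  prefer the designated coordinate. The planted bumps are therefore narrow
  (adjacent sampling times see < 0.1% of the amplitude), sitting on top of
  a small ordinary background response.
* **Non-planted events carry a rank-one line-heterogeneity factor** — a
  latent per-line "global responsiveness" scalar scaling every background
  amplitude, with series-specific loadings. This emulates the line-to-line
  staining/expression offsets that dominate between-line variance in real
  imaging panels. It is also what makes recovery possible at all: with
  pure i.i.d. noise, z-scoring turns the 88 non-planted events into random
  unit-variance vectors whose spurious correlations at n = 7 training
  lines swamp any true signal — a scale-free problem that no noise level
  fixes. Real data are recoverable for the same reason this world is:
  nuisance variation is low-rank.
* **`f2` is negatively correlated with sensitivity** (resistant lines
  respond earlier at the outer nucleus), with independent line-to-line
  variation. A second feature orthogonal to sensitivity would be removed
  by the pipeline's own |r| < 0.1 relevance filter before the model ever
  saw it.

Noise defaults: per-cell CV 0.10, well-level CV 0.05 (the ~5-10%
variation reported for control conditions), both exposed as arguments.
The end-to-end recovery criterion is stated for noise CV ≤ 2%; the
acceptance test runs at well-level CV 0.25%. Well means average ~1000
cells (per-cell CV 10% leaves ~0.3% sampling error), so sub-percent
technical CV is realistic, and the quoted 5-10% figures describe
whole-condition variation that the heterogeneity factor models
separately. At exactly 2% the two planted features still rank top-2 by
consensus |beta|, but bootstrap robustness of the planted features sits
at ~0.76-0.79 in some training subsets, so fold convergence degrades to
3-5 of 8 — the stated world meets the all-folds-converge clause only in
the sub-percent noise regime. That calibration is prescribed by the
acceptance criteria themselves (the noise bound is an upper bound) and
is fixed here once.

What a green test does **not** establish: the generator has circular cells,
no point-spread or shot-noise physics, no mitotic subpopulations, no
correlated kinase-substrate dynamics, and its planted law is exactly
linear. Green recovery demonstrates that the pipeline's machinery is
correct and leak-free, not that two features suffice on any real panel.

## Degenerate inputs and tie-breaks

* Nucleus filling the whole cell: cytoplasm bands come back empty and the
  region set is flagged, not rejected.
* Flat dose-response data: fitted as `d = 0` with zero AUC; non-converged
  fits fall back to trapezoidal interpolation of raw means over the grid,
  flagged.
* Zero or missing time-0 baselines drop the series with a warning.
* Ranking ties are broken by signal name; the 0.379 masking boundary and
  the 0.80 selection/robustness thresholds are inclusive.
* Bootstrap resamples that draw a single line contribute no selections;
  all-failed bootstraps abort loudly.
* Z-scoring refuses zero-sd features (the CV filter upstream removes
  them); `sd` uses the n−1 denominator.

## Reproducibility

Every stochastic function takes a `seed`; identical seeds give
byte-identical tables. Derived child seeds are kept below 2^31. The
default cell-line panel is itself deterministic (fixed `panel_seed`).
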