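# spatiosig

Predicting cytotoxic sensitivity from early spatiotemporal phospho-signaling.

## What this package is for

Cell lines exposed to the same cytotoxic cytokine (e.g. TNFα) can respond
anywhere from indifference to widespread apoptosis. `spatiosig` implements
an analysis pipeline for high-content imaging panels that links the
*first hour* of phospho-signaling — resolved by subcellular region and
time — to the eventual cytotoxic outcome, and uses the resulting sparse
model to predict the effect of co-treatments (kinase inhibitors,
knockdowns) that were never part of training. It is aimed at
computational biologists working with single-cell imaging screens of
signaling dynamics.

The pipeline:

1. **Nine-region subcellular quantification.** Each segmented cell is zoned
   into whole cell, cytoplasm, nucleus, outer/inner cytoplasm,
   peri-nucleus, outer/inner nucleus, and chromosome (erosion/dilation
   bands of 3/6/4 px by default; Otsu-thresholded DNA-bright pixels for
   the chromosome), and total phospho intensity is summed per region.
2. **Cytotoxicity index.** Cleaved-caspase-3 and EdU dose responses are
   fitted with a 3-parameter log-logistic
   `f(x) = d / (1 + exp(b(ln x − ln e)))`; the activity area is the sum of
   `f` over the 12-point grid `10^-2 … 10^3.5` ng/mL, and the per-line
   index is the average of the two max-normalized areas (EdU negated),
   normalized so the most sensitive line scores 1.
3. **1170-event profiles.** Well means of ~10^3 cells, replicate-averaged,
   log2-normalized to time 0, organized as a cell-line × (signal, region,
   time) matrix (13 × 9 × 10 = 1170 events per line).
4. **SVM signal ranking.** Per-signal single-cell classifiers
   (RBF/linear C-SVC, built-in SMO solver) scored by cross-validated
   balanced accuracy with an 80% selection threshold.
5. **Bootstrapped elastic net.** Leave-one-cell-line-out CV; per fold:
   CV/correlation feature filters, z-scoring, nested (α, λ) selection,
   500-resample bootstrap robustness with a 0.8 survival threshold, and a
   final refit. The two consensus top-|β| features form a final OLS model
   that predicts co-treatment Δ-sensitivity (index relative to solvent
   control).

A synthetic-data module generates images, single-cell tables, and
dose-response readouts for an 8-line panel with a planted linear law
`s = 0.369·f1 − 0.175·f2 + β0` (f1: outer cytoplasm at 55 min, positive;
f2: outer nucleus at 2 min, negative), so every stage can be tested
against known ground truth. See `vignette source in vignettes/` for the
model, its assumptions, and what the synthetic world does and does not
emulate.

## Worked example

```r
library(spatiosig)

specs  <- default_cell_lines()      # 8 synthetic lines, >30-fold spread
design <- assay_design()

# cytotoxicity indices from the two dose-response readouts
casp <- generate_dose_response(specs, design, "caspase3", noise_cv = 0)
edu  <- generate_dose_response(specs, design, "edu",      noise_cv = 0)
ci   <- sensitivity_index(casp, edu)
print(ci, digits = 3)
#>   cell_line     ci
#> 1     SYN01 0.0300
#> 2     SYN02 0.0495
#> 3     SYN03 0.0817
#> 4     SYN04 0.1350
#> 5     SYN05 0.2230
#> 6     SYN06 0.3670
#> 7     SYN07 0.6060
#> 8     SYN08 1.0000

# spatiotemporal features for one signal -> LOO elastic net
wells <- generate_well_features(specs, design, signals = "pRSK",
                                well_cv = 0.0025, seed = 7)
m  <- build_feature_matrix(normalize_profiles(wells))
ev <- loo_cv(m, setNames(ci$ci, ci$cell_line)[rownames(m)], seed = 7)
ev$n_converged
#> [1] 8
round(unlist(ev$metrics), 3)
#>    R_all  tau_all RMSE_all   R_test tau_test
#>    0.919    0.938    0.046    0.947    0.786
head(round(ev$consensus_beta, 3), 3)
#> pRSK__outer_cytoplasm__t55   pRSK__outer_nucleus__t02
#>                      0.268                      0.110
```

All eight leave-one-line-out folds converge; the pooled prediction of the
held-out lines correlates with the measured index at R ≈ 0.95; and the
only two features surviving the consensus are exactly the planted ones —
the outer-cytoplasm 55-min event and the outer-nucleus 2-min event
(`consensus_beta` reports mean |β| across folds; the fitted signs are
positive and negative respectively, matching the planted law, and the
magnitudes are on the z-score scale).

A command-line front end wraps the same steps
(`inst/cli/spatiosig.R`; subcommands `simulate`, `regions`,
`doseresponse`, `profile`, `regress`, `predict`).

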