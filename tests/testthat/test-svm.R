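two_line_cells <- function(sep = 0, n = 30, seed = 1,
                           design = assay_design(
                             signals = "pRSK",
                             time_points_min = c(0, 10, 55))) {
  # sep shifts SYN02's outer-cytoplasm template upward: a localized,
  # linearly separable difference between the two lines when sep is large
  specs <- default_cell_lines(n_lines = 2, sensitivities = c(0.2, 0.8))
  specs[[2]]$templates$log2_amp[
    specs[[2]]$templates$region == "outer_cytoplasm"] <- sep
  generate_single_cell_features(specs, design, cells_per_well = n,
                                cell_cv = 0.1, well_cv = 0, seed = seed)
}

test_that("balanced accuracy matches the hand-computed confusion table", {
  # TP = 90, FN = 10, TN = 70, FP = 30 -> (0.9 + 0.7) / 2 = 0.80
  truth <- factor(c(rep("pos", 100), rep("neg", 100)), c("neg", "pos"))
  pred <- factor(c(rep("pos", 90), rep("neg", 10),
                   rep("neg", 70), rep("pos", 30)), c("neg", "pos"))
  expect_equal(balanced_accuracy(truth, pred), 0.80)
  expect_equal(balanced_accuracy(c("a", "b"), c("a", "b")), 1)
})

test_that("the SVM separates what is separable", {
  set.seed(2)
  x <- rbind(matrix(rnorm(100, -2), 50), matrix(rnorm(100, 2), 50))
  y <- factor(rep(c("a", "b"), each = 50))
  for (k in c("linear", "rbf")) {
    m <- svm_fit(x, y, kernel = k, cost = 1, gamma = 0.5)
    expect_equal(balanced_accuracy(y, predict(m, x)), 1)
  }
  # decision values flip sign across the margin
  m <- svm_fit(x, y, kernel = "linear", cost = 1)
  f <- predict(m, rbind(c(-3, -3), c(3, 3)), type = "decision")
  expect_lt(f[1], 0)
  expect_gt(f[2], 0)
})

test_that("dataset assembly samples strata deterministically", {
  cells <- two_line_cells(sep = 1, n = 110)
  ds <- assemble_dataset(cells, "pRSK", "subcellular", n_per_stratum = 100,
                         seed = 5)
  # 100 cells x 3 times x 2 lines x 2 replicates
  expect_identical(nrow(ds$x), 1200L)
  expect_identical(ncol(ds$x), 10L) # 9 regions + time
  expect_true("time_min" %in% colnames(ds$x))
  ds_wc <- assemble_dataset(cells, "pRSK", "whole_cell", n_per_stratum = 100,
                            seed = 5)
  expect_identical(ncol(ds_wc$x), 2L) # whole-cell total + time
  ds2 <- assemble_dataset(cells, "pRSK", "subcellular", n_per_stratum = 100,
                          seed = 5)
  expect_identical(ds, ds2)
  # short strata are taken whole, with a warning
  expect_warning(
    small <- assemble_dataset(two_line_cells(n = 40), "pRSK", "subcellular",
                              n_per_stratum = 100, seed = 1),
    "only")
  expect_identical(nrow(small$x), 40L * 3L * 2L * 2L)
  expect_error(assemble_dataset(cells, "missing_signal", "subcellular"),
               "not present")
})

test_that("null features give chance accuracy; planted separation gives ~1", {
  cells <- two_line_cells(sep = 0, n = 60, seed = 3)
  ds <- assemble_dataset(cells, "pRSK", "subcellular", n_per_stratum = 50,
                         seed = 3)
  # scramble labels so no real signal remains
  set.seed(8)
  ds$y <- factor(sample(as.character(ds$y)), levels(ds$y))
  res <- evaluate_signal(ds, "rbf", k_folds = 3, n_repeats = 2,
                         cost_grid = c(1, 100), gamma_grid = c(0.01, 1),
                         seed = 9)
  expect_lt(abs(res$mean_bacc - 0.5), 0.07)

  # a genuinely separable construction (two well-separated clusters)
  set.seed(4)
  ds2 <- list(x = rbind(matrix(rnorm(300, -2), 150),
                        matrix(rnorm(300, 2), 150)),
              y = factor(rep(c("res", "sen"), each = 150)),
              signal = "toy", mode = "subcellular")
  colnames(ds2$x) <- c("r1", "r2")
  res2 <- evaluate_signal(ds2, "rbf", k_folds = 3, n_repeats = 1,
                          cost_grid = c(1, 100), gamma_grid = c(0.01, 1),
                          seed = 9)
  expect_gt(res2$mean_bacc, 0.95)
  # repeat variability is reported, not dropped
  expect_false(is.na(res$sd_bacc))
  expect_length(res$fold_bacc, 6L)
})

test_that("folds are stratified and scaling is learned on training data only", {
  y <- factor(rep(c("a", "b"), times = c(30, 12)))
  for (s in 1:5) {
    ids <- local({set.seed(s); spatiosig:::stratified_folds(y, 3)})
    expect_true(all(table(ids, y) > 0))
  }
  # scaler coefficients come from the training rows alone: perturbing
  # held-out rows cannot change them
  x <- matrix(rnorm(40), 20, 2)
  tr <- 1:12
  sc1 <- spatiosig:::scale_minmax_fit(x[tr, ])
  x_mut <- x
  x_mut[13:20, ] <- x_mut[13:20, ] * 1000
  sc2 <- spatiosig:::scale_minmax_fit(x_mut[tr, ])
  expect_identical(sc1, sc2)
  scaled <- spatiosig:::scale_minmax_apply(x[tr, ], sc1)
  expect_equal(apply(scaled, 2, range), matrix(c(-1, 1, -1, 1), 2))
})

test_that("ranking sorts, breaks ties by name, and applies the threshold", {
  df <- data.frame(signal = c("sigC", "sigA", "sigB", "sigD"),
                   mean_bacc = c(0.92, 0.75, 0.92, 0.80),
                   sd_bacc = 0.01)
  rk <- rank_and_select(df, threshold = 0.80)
  expect_identical(rk$signal, c("sigB", "sigC", "sigD", "sigA"))
  expect_identical(rk$selected, c(TRUE, TRUE, TRUE, FALSE))
  one <- rank_and_select(df[1, , drop = FALSE])
  expect_identical(sum(one$selected), 1L)
})

test_that("a panel screen selects exactly the discriminative signals", {
  # 5 signals, 3 with a planted between-line difference and 2 without:
  # the three planted ones should clear the 80% threshold
  design <- assay_design(signals = paste0("sig", 1:5),
                         time_points_min = c(0, 10, 55))
  # heterogeneity off: without it every signal differs between two real
  # lines, which is exactly what this screen is meant to detect
  specs <- default_cell_lines(n_lines = 2, design = design,
                              sensitivities = c(0.2, 0.8), line_hetero = 0)
  for (sg in c("sig1", "sig3", "sig5")) {
    sel <- specs[[2]]$templates$signal == sg &
      specs[[2]]$templates$region %in% c("nucleus", "inner_nucleus")
    specs[[2]]$templates$log2_amp[sel] <-
      specs[[2]]$templates$log2_amp[sel] + 4
  }
  cells <- generate_single_cell_features(specs, design, cells_per_well = 40,
                                         cell_cv = 0.1, well_cv = 0, seed = 6)
  results <- lapply(design$signals, function(sg) {
    ds <- assemble_dataset(cells, sg, "subcellular", n_per_stratum = 40,
                           seed = 6)
    evaluate_signal(ds, "rbf", k_folds = 3, n_repeats = 1,
                    cost_grid = c(1, 100), gamma_grid = c(0.01, 1), seed = 6)
  })
  rk <- rank_and_select(results, threshold = 0.80)
  expect_setequal(rk$signal[rk$selected], c("sig1", "sig3", "sig5"))
})

test_that("subcellular features are at least as discriminative as whole-cell", {
  # the planted difference is region-localized, so region-resolved features
  # carry strictly more information than the whole-cell totals
  wins <- 0L
  for (s in 1:3) {
    design <- assay_design(signals = "pRSK", time_points_min = c(0, 10, 55))
    specs <- default_cell_lines(n_lines = 2, sensitivities = c(0.2, 0.8))
    sel <- specs[[2]]$templates$signal == "pRSK" &
      specs[[2]]$templates$region == "inner_nucleus"
    specs[[2]]$templates$log2_amp[sel] <-
      specs[[2]]$templates$log2_amp[sel] + 1.5
    cells <- generate_single_cell_features(specs, design, cells_per_well = 40,
                                           cell_cv = 0.15, well_cv = 0,
                                           seed = s)
    acc <- vapply(c("subcellular", "whole_cell"), function(md) {
      ds <- assemble_dataset(cells, "pRSK", md, n_per_stratum = 40, seed = s)
      evaluate_signal(ds, "rbf", k_folds = 3, n_repeats = 1,
                      cost_grid = c(1, 100), gamma_grid = c(0.01, 1),
                      seed = s)$mean_bacc
    }, numeric(1))
    wins <- wins + (acc[["subcellular"]] >= acc[["whole_cell"]])
  }
  expect_gte(wins, 2L)
})
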