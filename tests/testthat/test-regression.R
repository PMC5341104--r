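toy_xy <- function(n = 8, p = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("L", 1:n), paste0("f", 1:p)))
  y <- 0.8 * x[, 1] - 0.5 * x[, 2] + rnorm(n, 0, 0.01)
  list(x = x, y = y)
}

test_that("feature filtering applies both published rules", {
  set.seed(2)
  x <- cbind(const = rep(5, 8),                  # CV = 0 -> removed
             tiny_cv = 100 * (1 + rnorm(8, 0, 0.005)), # CV ~ 0.5% -> removed
             keep = rnorm(8))
  y <- x[, "keep"] * 0.9 + rnorm(8, 0, 0.05)
  flt <- filter_features(x, y)
  expect_setequal(flt$removed$feature[flt$removed$reason == "low_cv"],
                  c("const", "tiny_cv"))
  expect_true("keep" %in% colnames(flt$x))

  # |r| < 0.1 removal: an orthogonalized feature has r = 0 exactly
  x2 <- cbind(sig = y, orth = residuals(lm(rnorm(8) ~ y)))
  flt2 <- filter_features(x2, y)
  expect_identical(colnames(flt2$x), "sig")
  expect_identical(flt2$removed$reason[flt2$removed$feature == "orth"],
                   "low_cor")
})

test_that("z-scores use frozen training statistics", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f"))
  st <- zscore_stats(x)
  expect_equal(st$sd[["f"]], 1) # denominator n - 1
  expect_equal(as.numeric(zscore_apply(x, st)), c(-1, 0, 1))
  # a test value equal to the training mean maps to 0
  expect_equal(as.numeric(zscore_apply(matrix(2, 1, 1,
                                              dimnames = list(NULL, "f")), st)),
               0)
  # affine-transformed inputs give identical z-scores
  x2 <- 3 * x + 7
  expect_equal(zscore_apply(x2, zscore_stats(x2)), zscore_apply(x, st),
               ignore_attr = TRUE)
  st0 <- list(mean = 0, sd = 0)
  expect_error(zscore_apply(x, st0), "zero-sd")
})

test_that("elastic net matches the lasso and ridge oracles on a toy", {
  d <- toy_xy(n = 12, p = 3, seed = 4)
  xz <- zscore_apply(d$x, zscore_stats(d$x))
  # glmnet standardizes the response internally (1/n sd), which rescales
  # the effective L2 penalty; comparing on a unit-sd response makes the
  # plain elastic-net objective and the glmnet objective coincide
  d$y <- d$y / sqrt(mean((d$y - mean(d$y))^2))
  # alpha = 1: coordinate-descent lasso oracle, to 1e-6
  for (lam in c(0.02, 0.1, 0.3)) {
    ours <- spatiosig:::enet_fit(xz, d$y, alpha = 1, lambda = lam)
    orc <- oracle_enet_cd(xz, d$y, alpha = 1, lambda = lam)
    expect_equal(unname(ours), unname(orc), tolerance = 1e-6)
  }
  # mid alpha against the same oracle
  ours <- spatiosig:::enet_fit(xz, d$y, alpha = 0.5, lambda = 0.1)
  orc <- oracle_enet_cd(xz, d$y, alpha = 0.5, lambda = 0.1)
  expect_equal(unname(ours), unname(orc), tolerance = 1e-6)
  # alpha -> 0 at small lambda approaches the closed-form ridge solution
  lam <- 0.01
  ours <- spatiosig:::enet_fit(xz, d$y, alpha = 0, lambda = lam)
  orc <- oracle_ridge(xz, d$y, lambda2 = lam)
  expect_equal(unname(ours), unname(as.numeric(orc)), tolerance = 1e-3)
})

test_that("hyperparameter selection reacts to signal strength", {
  d <- toy_xy(n = 8, p = 6, seed = 5)
  xz <- zscore_apply(d$x, zscore_stats(d$x))
  hp <- select_hyperparams(xz, d$y, seed = 1)
  expect_lt(hp$inner_rmse, sd(d$y) / 2) # strong planted signal

  set.seed(6)
  ynoise <- rnorm(8)
  hp0 <- select_hyperparams(xz, ynoise, seed = 1)
  # pure-noise target: the chosen penalty sits near the null-model end
  expect_gt(hp0$inner_rmse, 0.8 * sd(ynoise))

  hp1 <- select_hyperparams(xz, d$y, alpha_grid = 0.7, seed = 1)
  expect_equal(hp1$alpha, 0.7) # degenerate grid: only lambda searched
})

test_that("bootstrap robustness separates essential from spurious features", {
  # f1 (nearly) identical to the target, few competitors: always selected
  set.seed(7)
  x3 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y3 <- x3[, 1] + rnorm(10, 0, 0.001)
  x3z <- zscore_apply(x3, zscore_stats(x3))
  rob3 <- bootstrap_robustness(x3z, y3, alpha = 1, lambda = 0.02,
                               n_boot = 300, seed = 1)
  expect_gte(rob3[["f1"]], 0.95)
  expect_lt(max(rob3[c("f2", "f3")]), 0.8)

  # among more iid competitors at n = 8, spurious features stay below the
  # 0.8 survival threshold while the essential feature stays above it
  set.seed(17)
  x <- matrix(rnorm(48), 8, 6,
              dimnames = list(paste0("L", 1:8), paste0("f", 1:6)))
  y <- x[, 1] + rnorm(8, 0, 0.001)
  xz <- zscore_apply(x, zscore_stats(x))
  rob <- bootstrap_robustness(xz, y, alpha = 1, lambda = 0.02,
                              n_boot = 300, seed = 1)
  expect_gte(rob[["f1"]], 0.9)
  expect_lt(max(rob[c("f2", "f3", "f4", "f5", "f6")]), 0.8)
  expect_true(all(rob >= 0 & rob <= 1))
  # identical seeds reproduce identical scores
  expect_identical(rob, bootstrap_robustness(xz, y, 1, 0.02,
                                             n_boot = 300, seed = 1))
})

test_that("the per-fold pipeline trains, predicts, and reports convergence", {
  d <- toy_xy(n = 8, p = 6, seed = 8)
  m <- train_sensitivity_model(d$x, d$y, n_boot = 100, seed = 1)
  expect_true(m$converged)
  expect_true(all(m$robustness[m$features] >= 0.8))
  pred <- predict(m, d$x)
  expect_gt(cor(pred, d$y), 0.95)
  expect_error(predict(m, d$x[, -1, drop = FALSE]), "missing")

  # a pure-noise target should not produce a convergent model
  set.seed(9)
  m0 <- train_sensitivity_model(d$x, rnorm(8), n_boot = 100, seed = 1)
  if (m0$converged) expect_gt(length(m0$features), 0) else
    expect_identical(m0$features, character(0))
})

test_that("LOO CV bookkeeping: folds, convergence, metrics", {
  d <- toy_xy(n = 8, p = 6, seed = 10)
  ev <- loo_cv(d$x, d$y, n_boot = 100, seed = 2)
  expect_length(ev$folds, 8L) # one fold per cell line
  expect_identical(names(ev$folds), rownames(d$x))
  expect_gte(ev$n_converged, 6L)
  expect_gt(ev$metrics$R_all, 0.9)
  expect_lte(abs(ev$metrics$tau_all), 1)
  expect_gte(ev$metrics$RMSE_all, 0)

  # shuffled target: little converges and nothing predicts
  set.seed(11)
  ev0 <- suppressWarnings(loo_cv(d$x, sample(d$y), n_boot = 60, seed = 2))
  expect_lte(ev0$n_converged, 4L)
  if (!is.na(ev0$metrics$R_all)) expect_lt(ev0$metrics$R_all, 0.9)
})

test_that("no leakage: perturbing a held-out line leaves its fold's model unchanged", {
  d <- toy_xy(n = 8, p = 5, seed = 12)
  ev <- loo_cv(d$x, d$y, n_boot = 60, seed = 3)
  x_mut <- d$x
  x_mut["L3", ] <- x_mut["L3", ] + 100 # mutate the test line only
  ev_mut <- loo_cv(x_mut, d$y, n_boot = 60, seed = 3)
  f <- ev$folds[["L3"]]$model
  g <- ev_mut$folds[["L3"]]$model
  expect_identical(f$features, g$features)
  expect_equal(f$beta, g$beta)
  expect_equal(f$lambda, g$lambda)
  expect_equal(f$robustness, g$robustness)
})

test_that("the corrected resampled t-test behaves at its edges", {
  d <- toy_xy(n = 8, p = 5, seed = 13)
  ev <- loo_cv(d$x, d$y, n_boot = 60, seed = 4)
  same <- compare_models(ev, ev)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 0.5) # one-sided, identical models

  # a uniformly better model wins at sufficient margin
  ev_bad <- ev
  for (l in names(ev_bad$folds))
    if (ev_bad$folds[[l]]$converged)
      ev_bad$folds[[l]]$err_test <- ev_bad$folds[[l]]$err_test + 0.5
  cmp <- compare_models(ev, ev_bad, alternative = "less")
  expect_lt(cmp$p_value, 0.05)

  two <- ev
  two$folds <- two$folds[1:2]
  ev2 <- ev; ev2$folds <- ev2$folds[1:2]
  expect_error(compare_models(two, ev2), "insufficient")
  expect_error(compare_models(ev, ev2), "different fold")
})

test_that("the final two-feature model predicts co-treatment shifts exactly", {
  specs <- default_cell_lines()
  s <- panel_sensitivities(specs)
  pf <- attr(specs, "planted_features")
  x <- true_feature_matrix(specs, signals = "pRSK") # noiseless limit

  # base line with mid-range sensitivity so sensitizing and desensitizing
  # shifts both stay inside [0, 1]
  shifts <- list(DMSO = c(0, 0), TPCA1 = c(0.9, 0), BID1870 = c(0.45, 0),
                 SB202190 = c(0, 0.5), SP600125 = c(0.1, 0.1))
  cond_specs <- lapply(names(shifts), function(nm)
    generate_cotreatment_shift(specs[[4]], shifts[[nm]][1], shifts[[nm]][2],
                               name = nm))
  cf <- true_feature_matrix(cond_specs, signals = "pRSK")[, pf]
  rownames(cf) <- names(shifts)
  res <- final_model_and_predict(x, s, cf, reference = "DMSO",
                                 top_features = pf)
  expect_equal(res$delta[["DMSO"]], 1)
  # planted delta-sensitivities from the linear law
  truth <- vapply(cond_specs, `[[`, numeric(1), "true_sensitivity") /
    cond_specs[[1]]$true_sensitivity
  expect_equal(cor(res$delta, truth, method = "kendall"), 1)
  # direction checks: F1 shift sensitizes, F2 shift desensitizes
  expect_gt(res$delta[["TPCA1"]], 1)
  expect_lt(res$delta[["SB202190"]], 1)

  expect_error(final_model_and_predict(x, s, cf[, 1, drop = FALSE], "DMSO",
                                       top_features = pf), "missing")
  expect_error(final_model_and_predict(x, s, cf, "nope", top_features = pf),
               "reference")
})
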