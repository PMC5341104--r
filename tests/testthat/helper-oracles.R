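# independent oracles used by the dual-route checks; deliberately naive
# implementations that share no code with the package internals

# coordinate-descent elastic net matching the glmnet objective
#   (1/2n) * sum((y - b0 - X b)^2) + lambda * (alpha*|b|_1 + (1-alpha)/2*|b|_2^2)
# with intercept, no standardization
oracle_enet_cd <- function(x, y, alpha, lambda, tol = 1e-12,
                           max_iter = 100000L) {
  n <- nrow(x); p <- ncol(x)
  b <- numeric(p)
  b0 <- mean(y)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  xs <- colSums(x^2) / n
  for (it in seq_len(max_iter)) {
    b_old <- b; b0_old <- b0
    r <- y - b0 - x %*% b
    for (j in seq_len(p)) {
      r <- r + x[, j] * b[j]
      rho <- sum(x[, j] * r) / n
      b[j] <- soft(rho, lambda * alpha) / (xs[j] + lambda * (1 - alpha))
      r <- r - x[, j] * b[j]
    }
    b0 <- mean(y - x %*% b)
    if (max(abs(c(b - b_old, b0 - b0_old))) < tol) break
  }
  c(b0, b)
}

# closed-form ridge with intercept on centered data (lambda2 on the
# 1/(2n) * RSS scale, i.e. penalty lambda2/2 * |b|^2)
oracle_ridge <- function(x, y, lambda2) {
  xc <- scale(x, scale = FALSE)
  yc <- y - mean(y)
  n <- nrow(x)
  b <- solve(crossprod(xc) / n + diag(lambda2, ncol(x)), crossprod(xc, yc) / n)
  b0 <- mean(y) - colMeans(x) %*% b
  c(b0, b)
}

# analytic three-parameter log-logistic response
oracle_loglogistic <- function(x, b, d, e) d / (1 + exp(b * (log(x) - log(e))))

# small helper: the default single-signal design used by regression tests
single_signal_design <- function(design = assay_design(), signal = "pRSK") {
  list(signals = signal, regions = design$regions,
       time_points_min = design$time_points_min)
}

# feature matrix of the default panel for one signal at a given noise level
panel_feature_matrix <- function(specs, signal = "pRSK", well_cv = 0.005,
                                 seed = 1L, design = assay_design()) {
  wells <- generate_well_features(specs, design, signals = signal,
                                  well_cv = well_cv, seed = seed)
  suppressWarnings(
    build_feature_matrix(normalize_profiles(wells),
                         design = single_signal_design(design, signal)))
}

panel_sensitivities <- function(specs) {
  vapply(specs, `[[`, numeric(1), "true_sensitivity")
}
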