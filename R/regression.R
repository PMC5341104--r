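#' Pre-model feature filtering
#'
#' Removes features with low variation (coefficient of variation,
#' `sd/|mean|`, below `cv_min`) or low linear association with the
#' sensitivity target (`|Pearson r| < r_min`). Statistics must be computed
#' on training lines only; this function sees only what it is given.
#'
#' @param x numeric matrix, lines x features.
#' @param y sensitivity per line.
#' @param cv_min coefficient-of-variation floor (default 0.02).
#' @param r_min absolute-correlation floor (default 0.1).
#' @return list with `x` (retained columns), `removed` (data.frame
#'   `feature`, `reason`).
#' @export
filter_features <- function(x, y, cv_min = 0.02, r_min = 0.1) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  cv <- ifelse(abs(mu) > 0, sdv / abs(mu), ifelse(sdv > 0, Inf, 0))
  low_var <- cv < cv_min
  r <- suppressWarnings(as.numeric(cor(x, y)))
  low_cor <- !low_var & (is.na(r) | abs(r) < r_min)
  removed <- data.frame(
    feature = c(colnames(x)[low_var], colnames(x)[low_cor]),
    reason = c(rep("low_cv", sum(low_var)), rep("low_cor", sum(low_cor))))
  keep <- !(low_var | low_cor)
  list(x = x[, keep, drop = FALSE], removed = removed)
}

#' Z-score standardization with frozen training statistics
#'
#' `zscore_stats()` learns per-feature mean and standard deviation
#' (denominator n-1) from training lines; `zscore_apply()` transforms any
#' matrix with those frozen statistics, so test lines never leak into the
#' standardization.
#'
#' @param x training matrix.
#' @return `zscore_stats`: list with `mean`, `sd`.
#' @export
zscore_stats <- function(x) {
  list(mean = colMeans(x), sd = apply(x, 2, sd))
}

#' @rdname zscore_stats
#' @param stats a `zscore_stats()` result.
#' @export
zscore_apply <- function(x, stats) {
  if (any(stats$sd == 0))
    stop("zero-sd feature reached z-scoring; filter upstream")
  sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
}

# Elastic net at one (alpha, lambda). glmnet single-lambda fits are known
# to be loose, so the fit walks a short warm-started path down to the
# target lambda. Single-column inputs are padded with an all-zero dummy
# that can never be selected.
enet_fit <- function(x, y, alpha, lambda) {
  pad <- ncol(x) < 2L
  if (pad) x <- cbind(x, `.dummy` = 0)
  lam_top <- max(abs(crossprod(x, y - mean(y)))) / (nrow(x) * max(alpha, 1e-3))
  lam_path <- exp(seq(log(max(lam_top, lambda * 10)), log(lambda),
                      length.out = 25))
  lam_path[length(lam_path)] <- lambda
  fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lam_path,
                        standardize = FALSE, thresh = 1e-14, maxit = 10^6)
  beta <- as.numeric(coef(fit, s = lambda))
  names(beta) <- c("(Intercept)", colnames(x))
  if (pad) beta <- beta[names(beta) != ".dummy"]
  beta
}

#' Nested cross-validation choice of the elastic-net hyperparameters
#'
#' For each mixing value `alpha` in the grid, an inner leave-one-out cross
#' validation over the training lines traces the automatic lambda path and
#' records the CV mean-squared error at each lambda; the `(alpha, lambda)`
#' pair with the smallest inner RMSE wins. With 7 training lines the inner
#' CV is 7-fold, i.e. leave-one-out.
#'
#' @param x z-scored training matrix.
#' @param y training sensitivities.
#' @param alpha_grid mixing grid (default 0.1..1.0).
#' @param seed seed (fold assignment is deterministic LOO; the seed guards
#'   any internal randomization).
#' @return list with `alpha`, `lambda`, `inner_rmse`.
#' @export
select_hyperparams <- function(x, y, alpha_grid = seq(0.1, 1, by = 0.1),
                               seed = 1L) {
  stopifnot(nrow(x) >= 3L)
  pad <- ncol(x) < 2L
  if (pad) x <- cbind(x, `.dummy` = 0)
  foldid <- seq_len(nrow(x)) # leave-one-out
  best <- NULL
  with_seed(seed, {
    for (a in alpha_grid) {
      cvfit <- tryCatch(
        glmnet::cv.glmnet(x, y, alpha = a, foldid = foldid,
                          grouped = FALSE, standardize = FALSE,
                          thresh = 1e-10),
        error = function(e) NULL)
      if (is.null(cvfit)) next
      i <- which.min(cvfit$cvm)
      if (is.null(best) || cvfit$cvm[i] < best$mse)
        best <- list(alpha = a, lambda = cvfit$lambda[i],
                     mse = cvfit$cvm[i])
    }
  })
  if (is.null(best)) stop("no (alpha, lambda) pair could be fitted")
  list(alpha = best$alpha, lambda = best$lambda,
       inner_rmse = sqrt(best$mse))
}

#' Bootstrap robustness scores of elastic-net features
#'
#' Generates `n_boot` resampled datasets (training lines drawn with
#' replacement at original size), refits the elastic net at the fixed
#' `(alpha, lambda)`, and scores each feature by the fraction of resamples
#' in which its coefficient is non-zero.
#'
#' @param x z-scored training matrix.
#' @param y training sensitivities.
#' @param alpha,lambda fixed hyperparameters.
#' @param n_boot resample count (default 500).
#' @param seed RNG seed.
#' @return named numeric vector of robustness scores in `[0, 1]`.
#' @export
bootstrap_robustness <- function(x, y, alpha, lambda, n_boot = 500L,
                                 seed = 1L) {
  n <- nrow(x)
  hits <- setNames(numeric(ncol(x)), colnames(x))
  used <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) {
        # degenerate resample (a single line); contributes no selections
        used <- used + 1L
        next
      }
      beta <- tryCatch(enet_fit(x[idx, , drop = FALSE], y[idx],
                                alpha, lambda),
                       error = function(e) NULL)
      if (is.null(beta)) next
      used <- used + 1L
      hits <- hits + (abs(beta[colnames(x)]) > 0)
    }
  })
  if (used == 0L) stop("all bootstrap refits failed")
  hits / used
}

#' Train one sensitivity regression model (the per-fold pipeline)
#'
#' Runs the full training protocol on one set of training lines: feature
#' filtering, z-scoring, nested hyperparameter selection, 500-resample
#' bootstrap robustness with removal below `robustness_min`, and a final
#' elastic-net refit on the surviving features. A model converges when at
#' least one feature survives and the refit keeps at least one non-zero
#' coefficient.
#'
#' @param x training feature matrix (raw scale).
#' @param y training sensitivities.
#' @param alpha_grid,n_boot,robustness_min,cv_min,r_min protocol knobs.
#' @param seed RNG seed.
#' @return object of class `sensitivity_model`: `features`, `beta`,
#'   `intercept`, `alpha`, `lambda`, `robustness`, `zstats`, `converged`.
#'   Non-converged models carry no weights.
#' @export
train_sensitivity_model <- function(x, y, alpha_grid = seq(0.1, 1, by = 0.1),
                                    n_boot = 500L, robustness_min = 0.8,
                                    cv_min = 0.02, r_min = 0.1, seed = 1L) {
  not_converged <- function(reason) {
    structure(list(features = character(), beta = numeric(),
                   intercept = NA_real_, alpha = NA_real_,
                   lambda = NA_real_, robustness = numeric(),
                   zstats = NULL, converged = FALSE, reason = reason),
              class = "sensitivity_model")
  }
  flt <- filter_features(x, y, cv_min = cv_min, r_min = r_min)
  if (ncol(flt$x) == 0L) return(not_converged("all features filtered"))
  zs <- zscore_stats(flt$x)
  xz <- zscore_apply(flt$x, zs)
  hp <- tryCatch(select_hyperparams(xz, y, alpha_grid,
                                    seed = child_seed(seed, 1L)),
                 error = function(e) NULL)
  if (is.null(hp)) return(not_converged("hyperparameter search failed"))
  rob <- bootstrap_robustness(xz, y, hp$alpha, hp$lambda, n_boot = n_boot,
                              seed = child_seed(seed, 2L))
  surv <- names(rob)[rob >= robustness_min]
  if (length(surv) == 0L) return(not_converged("no robust features"))
  beta <- enet_fit(xz[, surv, drop = FALSE], y, hp$alpha, hp$lambda)
  coefs <- beta[surv]
  if (all(abs(coefs) == 0)) return(not_converged("refit selected nothing"))
  zs_surv <- list(mean = zs$mean[surv], sd = zs$sd[surv])
  structure(list(features = surv, beta = coefs,
                 intercept = beta[["(Intercept)"]],
                 alpha = hp$alpha, lambda = hp$lambda,
                 robustness = rob, zstats = zs_surv, converged = TRUE,
                 reason = "ok"),
            class = "sensitivity_model")
}

#' @rdname train_sensitivity_model
#' @param object a `sensitivity_model`.
#' @param newx feature matrix containing the model's features (raw scale).
#' @param ... unused.
#' @export
predict.sensitivity_model <- function(object, newx, ...) {
  if (!object$converged) stop("model did not converge")
  miss <- setdiff(object$features, colnames(newx))
  if (length(miss)) stop("features missing from newdata: ",
                         paste(miss, collapse = ", "))
  xz <- zscore_apply(newx[, object$features, drop = FALSE], object$zstats)
  as.numeric(xz %*% object$beta + object$intercept)
}

#' Leave-one-cell-line-out cross validation of the regression protocol
#'
#' One fold per cell line: the model is trained on the other lines with the
#' full pipeline ([train_sensitivity_model()]) and used to predict the
#' held-out line. Per-fold performance (`R_all`, `tau_all`, `RMSE_all`) is
#' computed over all lines (training fits plus the held-out prediction) and
#' averaged over converged folds only; pooled held-out metrics (`R_test`,
#' `tau_test`) are computed from the converged folds' held-out predictions.
#'
#' @param x full feature matrix (all lines).
#' @param y named (or aligned) sensitivities.
#' @param alpha_grid,n_boot,robustness_min,cv_min,r_min protocol knobs.
#' @param seed RNG seed (each fold derives its own stream).
#' @return object of class `cv_evaluation`: `folds` (per-line model,
#'   prediction, per-fold metrics), `n_converged`, `metrics` (averages over
#'   converged folds and the pooled held-out metrics), `consensus_beta`
#'   (mean |beta| per feature across converged folds).
#' @export
loo_cv <- function(x, y, alpha_grid = seq(0.1, 1, by = 0.1), n_boot = 500L,
                   robustness_min = 0.8, cv_min = 0.02, r_min = 0.1,
                   seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) >= 3L, nrow(x) == length(y))
  lines <- rownames(x) %||% as.character(seq_len(nrow(x)))
  folds <- list()
  for (i in seq_len(nrow(x))) {
    m <- train_sensitivity_model(x[-i, , drop = FALSE], y[-i],
                                 alpha_grid = alpha_grid, n_boot = n_boot,
                                 robustness_min = robustness_min,
                                 cv_min = cv_min, r_min = r_min,
                                 seed = child_seed(seed, i))
    fold <- list(test_line = lines[i], model = m, converged = m$converged)
    if (m$converged) {
      pred_all <- predict(m, x)
      fold$pred_test <- pred_all[i]
      fold$pred_all <- pred_all
      fold$R_all <- cor(pred_all, y)
      fold$tau_all <- cor(pred_all, y, method = "kendall")
      fold$RMSE_all <- sqrt(mean((pred_all - y)^2))
      fold$err_test <- (pred_all[i] - y[i])^2
    }
    folds[[lines[i]]] <- fold
  }
  conv <- Filter(function(f) f$converged, folds)
  metrics <- if (length(conv) >= 1L) {
    pt <- vapply(conv, `[[`, 0, "pred_test")
    yt <- y[match(names(conv), lines)]
    list(R_all = mean(vapply(conv, `[[`, 0, "R_all")),
         tau_all = mean(vapply(conv, `[[`, 0, "tau_all")),
         RMSE_all = mean(vapply(conv, `[[`, 0, "RMSE_all")),
         R_test = if (length(conv) >= 3L) cor(pt, yt) else NA_real_,
         tau_test = if (length(conv) >= 3L)
           cor(pt, yt, method = "kendall") else NA_real_)
  } else {
    warning("fewer than one converged fold; no averaged metrics")
    list(R_all = NA_real_, tau_all = NA_real_, RMSE_all = NA_real_,
         R_test = NA_real_, tau_test = NA_real_)
  }
  all_feats <- unique(unlist(lapply(conv, function(f) f$model$features)))
  consensus <- setNames(numeric(length(all_feats)), all_feats)
  detect <- setNames(integer(length(all_feats)), all_feats)
  for (f in conv) {
    consensus[f$model$features] <- consensus[f$model$features] +
      abs(f$model$beta)
    detect[f$model$features] <- detect[f$model$features] + 1L
  }
  if (length(conv)) consensus <- consensus / length(conv)
  structure(list(folds = folds, n_converged = length(conv),
                 metrics = metrics,
                 consensus_beta = sort(consensus, decreasing = TRUE),
                 detection_count = detect, y = setNames(y, lines)),
            class = "cv_evaluation")
}

#' Corrected resampled t-test between two cross-validated models
#'
#' Variance-corrected paired t-test (Nadeau-Bengio correction with
#' `rho = n_test/n_train`) on fold-wise held-out squared errors of two
#' evaluations sharing identical fold splits. Folds where either model did
#' not converge are dropped pairwise.
#'
#' @param eval_a,eval_b `cv_evaluation` objects over the same lines.
#' @param alternative `"less"` (a better than b), `"greater"`, or
#'   `"two.sided"`.
#' @return list with `t`, `df`, `p_value`, `n_folds`.
#' @export
compare_models <- function(eval_a, eval_b,
                           alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  la <- names(eval_a$folds); lb <- names(eval_b$folds)
  if (!identical(la, lb)) stop("evaluations use different fold splits")
  ok <- vapply(la, function(l) eval_a$folds[[l]]$converged &&
                 eval_b$folds[[l]]$converged, logical(1))
  if (sum(ok) <= 2L) stop("insufficient paired converged folds (",
                          sum(ok), ")")
  d <- vapply(la[ok], function(l)
    eval_a$folds[[l]]$err_test - eval_b$folds[[l]]$err_test, numeric(1))
  J <- length(d)
  n <- length(la)
  rho <- 1 / (n - 1) # LOO: one test line, n-1 training lines
  v <- var(d)
  tstat <- if (v == 0) 0 else mean(d) / sqrt(v * (1 / J + rho))
  p <- switch(alternative,
              less = pt(tstat, df = J - 1),
              greater = pt(tstat, df = J - 1, lower.tail = FALSE),
              two.sided = 2 * pt(-abs(tstat), df = J - 1))
  list(t = tstat, df = J - 1, p_value = p, n_folds = J)
}

#' Final two-feature model and co-treatment predictions
#'
#' Ordinary least squares of sensitivity on the named top features over all
#' cell lines (the consensus two-feature model), applied without refitting
#' to co-treatment feature values; each condition's prediction is
#' normalized by the reference condition to give a predicted
#' delta-sensitivity.
#'
#' @param x feature matrix over all lines.
#' @param y sensitivities.
#' @param top_features feature names (default: top 2 of
#'   `evaluation$consensus_beta` when an evaluation is supplied).
#' @param cotreatment_features data.frame/matrix of the same features per
#'   condition (rownames = condition names), reference included.
#' @param reference reference condition name (e.g. the solvent control).
#' @param evaluation optional `cv_evaluation` supplying the consensus
#'   features.
#' @return list with `model` (lm), `features`, `fitted` (per line),
#'   `predictions` (per condition), `delta` (predicted delta-sensitivity,
#'   reference = 1).
#' @export
final_model_and_predict <- function(x, y, cotreatment_features, reference,
                                    top_features = NULL, evaluation = NULL) {
  if (is.null(top_features)) {
    if (is.null(evaluation)) stop("supply top_features or an evaluation")
    top_features <- names(evaluation$consensus_beta)[1:2]
  }
  miss <- setdiff(top_features, colnames(x))
  if (length(miss)) stop("features missing from training matrix: ",
                         paste(miss, collapse = ", "))
  cf <- as.matrix(cotreatment_features)
  miss <- setdiff(top_features, colnames(cf))
  if (length(miss)) stop("features missing from co-treatment table: ",
                         paste(miss, collapse = ", "))
  if (!reference %in% rownames(cf)) stop("reference condition not found: ",
                                         reference)
  df <- as.data.frame(x[, top_features, drop = FALSE])
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  pred <- as.numeric(predict(fit, as.data.frame(cf[, top_features,
                                                   drop = FALSE])))
  names(pred) <- rownames(cf)
  if (abs(pred[[reference]]) < 1e-12)
    stop("reference prediction is zero; delta undefined")
  list(model = fit, features = top_features, fitted = fitted(fit),
       predictions = pred, delta = pred / pred[[reference]])
}
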