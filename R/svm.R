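#' Support-vector classifier (C-SVC)
#'
#' Binary SVM trained by sequential minimal optimization (dense kernel
#' matrix, maximal-violating-pair selection). Supports radial-basis and
#' linear kernels. This is deliberately a from-scratch solver: it backs the
#' signal-ranking protocol and is validated against analytic cases in the
#' test suite.
#'
#' @param x numeric feature matrix.
#' @param y two-level factor (or coercible) of class labels.
#' @param kernel `"rbf"` or `"linear"`.
#' @param cost soft-margin parameter C.
#' @param gamma RBF kernel width (ignored for linear).
#' @param eps KKT violation tolerance.
#' @param max_iter SMO iteration cap.
#' @return an object of class `spatiosig_svm`.
#' @export
svm_fit <- function(x, y, kernel = c("rbf", "linear"), cost = 1,
                    gamma = 1 / ncol(x), eps = 1e-3, max_iter = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2L, nrow(x) == length(y), cost > 0)
  yi <- ifelse(y == levels(y)[2], 1L, -1L)
  if (is.null(max_iter)) max_iter <- max(10000L, 200L * nrow(x))
  fit <- svm_train_cpp(x, as.integer(yi), cost, gamma,
                       if (kernel == "linear") 0L else 1L, eps,
                       as.integer(max_iter))
  structure(list(x = x, yi = as.integer(yi), levels = levels(y),
                 alpha = fit$alpha, b = fit$b, kernel = kernel,
                 cost = cost, gamma = gamma, iter = fit$iter),
            class = "spatiosig_svm")
}

#' @rdname svm_fit
#' @param object a fitted `spatiosig_svm`.
#' @param newx matrix of observations to classify.
#' @param type `"class"` or `"decision"`.
#' @param ... unused.
#' @export
predict.spatiosig_svm <- function(object, newx, type = c("class", "decision"),
                                  ...) {
  type <- match.arg(type)
  f <- svm_decision_cpp(object$x, object$yi, object$alpha, object$b,
                        if (object$kernel == "linear") 0L else 1L,
                        object$gamma, as.matrix(newx))
  if (type == "decision") return(f)
  factor(ifelse(f >= 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Balanced accuracy of a binary classification
#'
#' Mean of the two per-class recalls, `(sensitivity + specificity) / 2`;
#' insensitive to class imbalance.
#'
#' @param truth,pred factors (or coercible) with the same two levels.
#' @return fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  recalls <- vapply(levels(truth), function(lv) {
    sel <- truth == lv
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] == lv)
  }, numeric(1))
  mean(recalls)
}

# linear [-1, 1] scaling with coefficients learned on the training fold only
scale_minmax_fit <- function(x) {
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}
scale_minmax_apply <- function(x, sc) {
  rng <- sc$max - sc$min
  rng[rng == 0] <- 1
  sweep(sweep(x, 2, sc$min), 2, rng, "/") * 2 - 1
}

# stratified fold assignment; every fold contains every class
stratified_folds <- function(y, k) {
  ids <- integer(length(y))
  for (lv in levels(as.factor(y))) {
    idx <- sample(which(y == lv))
    ids[idx] <- rep_len(sample(k), length(idx))
  }
  tab <- table(ids, y)
  if (any(tab == 0)) stop("stratification failed: a fold lost a class")
  ids
}

#' Assemble a per-signal single-cell classification dataset
#'
#' Samples (without replacement) `n_per_stratum` cells per
#' (time point, cell line, replicate) stratum and builds the feature matrix
#' for one signal: either the 9 per-region totals plus the time point
#' (`mode = "subcellular"`, 10 features) or the whole-cell total plus time
#' (`mode = "whole_cell"`, 2 features). With the default design (10 times,
#' 2 lines, 2 replicates, 100 cells) this yields 4000 rows.
#'
#' @param cells single-cell table (see
#'   [generate_single_cell_features()]); exactly two cell lines.
#' @param signal which signal to use.
#' @param mode `"subcellular"` or `"whole_cell"`.
#' @param n_per_stratum cells sampled per stratum (default 100); strata
#'   with fewer cells contribute all of them, with a warning.
#' @param seed RNG seed; identical seeds give identical samples.
#' @return list with `x` (features), `y` (cell-line factor), `signal`,
#'   `mode`.
#' @export
assemble_dataset <- function(cells, signal, mode = c("subcellular", "whole_cell"),
                             n_per_stratum = 100L, seed = 1L) {
  mode <- match.arg(mode)
  sig <- signal
  dt <- data.table::as.data.table(cells)
  dt <- dt[signal == sig]
  if (nrow(dt) == 0L) stop("signal not present in table: ", sig)
  lines <- sort(unique(dt$cell_line))
  if (length(lines) != 2L) stop("need exactly two cell lines, got ",
                                length(lines))
  regions <- if (mode == "whole_cell") "whole_cell" else REGION_LABELS
  dt <- dt[region %in% regions]
  wide <- data.table::dcast(dt,
    cell_line + replicate + time_min + cell_id ~ region,
    value.var = "total_intensity")
  feat_cols <- intersect(REGION_LABELS, names(wide))
  sampled <- with_seed(seed, {
    wide[, {
      n <- min(.N, n_per_stratum)
      if (.N < n_per_stratum)
        warning("stratum ", cell_line[1], "/t", time_min[1], "/r",
                replicate[1], " has only ", .N, " cells", call. = FALSE)
      .SD[sample(.N, n)]
    }, by = .(cell_line, replicate, time_min)]
  })
  x <- as.matrix(sampled[, c(feat_cols, "time_min"), with = FALSE])
  colnames(x) <- c(feat_cols, "time_min")
  list(x = x, y = factor(sampled$cell_line, levels = lines),
       signal = signal, mode = mode)
}

#' Cross-validated balanced accuracy of one signal's classifier
#'
#' The published protocol: stratified k-fold cross validation repeated
#' `n_repeats` times with random fold divisions; inside each training fold
#' the features are linearly scaled to `[-1, 1]` (coefficients from the
#' training fold only) and `(C, gamma)` are selected by an inner
#' `inner_folds`-fold grid search scored by balanced accuracy; the winning
#' model is refit on the whole training fold and scored on the held-out
#' fold. Test-fold data never touch the scaler or the grid search.
#'
#' @param dataset an [assemble_dataset()] result.
#' @param kernel `"rbf"` or `"linear"`.
#' @param k_folds outer folds (3 in the published first-stage screen).
#' @param n_repeats outer repetitions (3).
#' @param cost_grid,gamma_grid hyperparameter grids; the defaults are the
#'   conventional coarse powers of two. For a linear kernel `gamma_grid`
#'   is ignored.
#' @param inner_folds folds of the inner grid-search CV.
#' @param seed RNG seed.
#' @return object of class `svm_ranking_result`: list with `signal`,
#'   `kernel`, `mode`, `mean_bacc`, `sd_bacc`, `fold_bacc` (per fold x
#'   repeat), and the selected hyperparameters per repeat.
#' @export
evaluate_signal <- function(dataset, kernel = c("rbf", "linear"),
                            k_folds = 3L, n_repeats = 3L,
                            cost_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            inner_folds = 3L, seed = 1L) {
  kernel <- match.arg(kernel)
  x <- dataset$x; y <- dataset$y
  stopifnot(nlevels(y) == 2L)
  if (kernel == "linear") gamma_grid <- 1
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)

  accs <- c()
  chosen <- list()
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      folds <- stratified_folds(y, k_folds)
      for (k in seq_len(k_folds)) {
        tr <- folds != k
        sc <- scale_minmax_fit(x[tr, , drop = FALSE])
        xtr <- scale_minmax_apply(x[tr, , drop = FALSE], sc)
        xte <- scale_minmax_apply(x[!tr, , drop = FALSE], sc)
        ytr <- droplevels(y[tr])

        best <- NULL
        if (nrow(grid) > 1L) {
          inner <- stratified_folds(ytr, inner_folds)
          for (g in seq_len(nrow(grid))) {
            sc_acc <- mean(vapply(seq_len(inner_folds), function(ki) {
              itr <- inner != ki
              m <- svm_fit(xtr[itr, , drop = FALSE], ytr[itr], kernel,
                           cost = grid$cost[g], gamma = grid$gamma[g])
              balanced_accuracy(ytr[!itr],
                                predict(m, xtr[!itr, , drop = FALSE]))
            }, numeric(1)))
            if (is.null(best) || sc_acc > best$acc)
              best <- list(acc = sc_acc, cost = grid$cost[g],
                           gamma = grid$gamma[g])
          }
        } else {
          best <- list(acc = NA, cost = grid$cost[1], gamma = grid$gamma[1])
        }
        m <- svm_fit(xtr, ytr, kernel, cost = best$cost, gamma = best$gamma)
        accs <- c(accs, balanced_accuracy(y[!tr], predict(m, xte)))
        chosen[[length(chosen) + 1L]] <- best
      }
    }
  })
  structure(list(signal = dataset$signal, kernel = kernel,
                 mode = dataset$mode, mean_bacc = mean(accs),
                 sd_bacc = sd(accs), fold_bacc = accs,
                 hyperparams = chosen),
            class = "svm_ranking_result")
}

#' Rank signals by balanced accuracy and select candidates
#'
#' Sorts descending by mean balanced accuracy (ties broken by signal name)
#' and marks signals at or above `threshold` (default 0.80, the published
#' selection threshold) as selected.
#'
#' @param results list of [evaluate_signal()] results (or a data.frame with
#'   `signal`, `mean_bacc`, `sd_bacc`).
#' @param threshold selection threshold on mean balanced accuracy.
#' @return data.frame ordered by rank with columns `signal`, `kernel`,
#'   `mean_bacc`, `sd_bacc`, `selected`.
#' @export
rank_and_select <- function(results, threshold = 0.80) {
  if (is.data.frame(results)) {
    df <- results
    if (is.null(df$kernel)) df$kernel <- NA_character_
  } else {
    stopifnot(length(results) >= 1L)
    df <- data.frame(
      signal = vapply(results, `[[`, "", "signal"),
      kernel = vapply(results, `[[`, "", "kernel"),
      mean_bacc = vapply(results, `[[`, 0, "mean_bacc"),
      sd_bacc = vapply(results, `[[`, 0, "sd_bacc"))
  }
  df <- df[order(-df$mean_bacc, df$signal), , drop = FALSE]
  df$selected <- df$mean_bacc >= threshold
  rownames(df) <- NULL
  df
}
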