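#' Fit a three-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(x) = d / (1 + exp(b * (log(x) - log(e))))` to
#' log2 response ratios, the standard three-parameter log-logistic used for
#' activity-area calculations (`b` slope -- negative for curves increasing
#' with dose, `d` top asymptote, `e` midpoint in dose units). The optimizer
#' multi-starts over both slope signs and midpoints on the dose grid, then
#' polishes by Gauss-Newton; there is no closed form and published analyses
#' delegate to a dose-response package not available here.
#'
#' @param doses positive doses (>= 4 distinct values).
#' @param responses log2 response ratios, same length.
#' @return an object of class `loglogistic_fit`: list with `b`, `d`, `e`,
#'   `converged`, `flat`, `sse`, and the data.
#' @export
fit_loglogistic3 <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), all(is.finite(responses)))
  keep <- doses > 0
  x <- doses[keep]; y <- responses[keep]
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct positive doses")

  if (sd(y) < 1e-10) {
    return(structure(list(b = 1, d = 0, e = median(x), converged = TRUE,
                          flat = TRUE, sse = 0, doses = x, responses = y),
                     class = "loglogistic_fit"))
  }

  lx <- log(x)
  obj <- function(p) {
    mu <- p[2] / (1 + exp(p[1] * (lx - p[3])))
    sum((y - mu)^2)
  }
  d0 <- y[which.max(abs(y))]
  starts <- expand.grid(b = c(-4, -1.5, -0.5, 0.5, 1.5, 4), d = d0,
                        le = quantile(lx, c(0.25, 0.5, 0.75)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  converged <- !is.null(best)
  if (converged) {
    # Gauss-Newton polish for round-trip accuracy on clean curves
    p <- best$par
    nl <- tryCatch(
      suppressWarnings(
        nls(y ~ d / (1 + exp(b * (lx - le))),
            start = list(b = p[1], d = p[2], le = p[3]),
            control = list(maxiter = 200, tol = 1e-10, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- coef(nl)
      if (sum((y - predict(nl))^2) <= best$value + 1e-12)
        p <- as.numeric(cf)
    }
    sse <- obj(p)
    structure(list(b = p[1], d = p[2], e = exp(p[3]), converged = TRUE,
                   flat = FALSE, sse = sse, doses = x, responses = y),
              class = "loglogistic_fit")
  } else {
    structure(list(b = NA_real_, d = NA_real_, e = NA_real_,
                   converged = FALSE, flat = FALSE, sse = NA_real_,
                   doses = x, responses = y),
              class = "loglogistic_fit")
  }
}

#' Evaluate a fitted curve
#' @param object a `loglogistic_fit`.
#' @param newdata doses at which to evaluate.
#' @param ... unused.
#' @export
predict.loglogistic_fit <- function(object, newdata, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  object$d / (1 + exp(object$b * (log(newdata) - log(object$e))))
}

#' Activity area (signed AUC) of a dose-response fit
#'
#' Evaluates the fitted curve at the fixed 12-point log-dose grid
#' `10^(-2), 10^(-1.5), ..., 10^(3.5)` ng/mL and sums the responses.
#' Positive for induction (cleaved-caspase-3) curves, negative for
#' suppression (EdU) curves. For non-converged fits the raw mean responses
#' are linearly interpolated in log dose onto the grid (flat extrapolation)
#' and summed, and the result is flagged.
#'
#' @param fit a [fit_loglogistic3()] result.
#' @param grid evaluation doses.
#' @return numeric AUC with attribute `fallback` (logical).
#' @export
activity_auc <- function(fit, grid = 10^seq(-2, 3.5, by = 0.5)) {
  stopifnot(inherits(fit, "loglogistic_fit"))
  if (fit$converged) {
    val <- sum(predict(fit, grid))
    attr(val, "fallback") <- FALSE
  } else {
    means <- tapply(fit$responses, fit$doses, mean)
    xs <- log10(as.numeric(names(means)))
    val <- sum(approx(xs, as.numeric(means), xout = log10(grid),
                      rule = 2)$y)
    attr(val, "fallback") <- TRUE
  }
  val
}

# per-line log2 response ratios relative to the minimum response, defined
# as the median readout across replicates at the lowest dose
log2_ratios_to_rmin <- function(dose_table) {
  dt <- data.table::as.data.table(dose_table)
  dt <- dt[dose_ng_ml > 0]
  dt[, r_min := median(value[dose_ng_ml == min(dose_ng_ml)]),
     by = cell_line]
  dt[, log2_ratio := log2(value / r_min)]
  dt[]
}

#' Fit dose-response curves and AUCs for every cell line in a table
#'
#' Computes each line's minimum response (median at the lowest dose), log2
#' ratios to it, the log-logistic fit, and the activity AUC.
#'
#' @param dose_table data.frame with columns `cell_line`, `replicate`,
#'   `dose_ng_ml`, `value` (vehicle/zero doses are ignored).
#' @return named list of per-line lists `(fit, auc)`.
#' @export
fit_dose_response_table <- function(dose_table) {
  dt <- log2_ratios_to_rmin(dose_table)
  lines <- unique(dt$cell_line)
  out <- lapply(lines, function(cl) {
    sub <- dt[cell_line == cl]
    fit <- fit_loglogistic3(sub$dose_ng_ml, sub$log2_ratio)
    list(fit = fit, auc = activity_auc(fit))
  })
  setNames(out, lines)
}

#' Composite cytotoxicity / sensitivity index
#'
#' For each cell line `j`,
#' `CI_j = 0.5 * (AUC_casp_j / max_k AUC_casp_k + (-AUC_edu_j) / max_k (-AUC_edu_k))`,
#' then all indices are divided by the panel maximum so the most sensitive
#' line scores 1. The alternative reading (normalize the plain average by
#' its panel maximum) differs only by per-readout constants and is
#' selectable via `form`.
#'
#' @param auc_caspase,auc_edu named numeric vectors of activity AUCs for the
#'   same cell lines (EdU AUCs are typically negative).
#' @param form `"average_normalized"` (default) or `"normalize_average"`.
#' @return data.frame with columns `cell_line`, `ci` (max = 1).
#' @export
cytotoxicity_index <- function(auc_caspase, auc_edu,
                               form = c("average_normalized",
                                        "normalize_average")) {
  form <- match.arg(form)
  stopifnot(!is.null(names(auc_caspase)),
            setequal(names(auc_caspase), names(auc_edu)))
  auc_edu <- auc_edu[names(auc_caspase)]
  if (all(abs(auc_caspase) < 1e-12) && all(abs(auc_edu) < 1e-12))
    stop("no dose-response signal in any cell line")
  if (form == "average_normalized") {
    ci <- 0.5 * (auc_caspase / max(auc_caspase) +
                   (-auc_edu) / max(-auc_edu))
  } else {
    ci <- 0.5 * (auc_caspase - auc_edu)
  }
  ci <- ci / max(ci)
  data.frame(cell_line = names(auc_caspase), ci = as.numeric(ci),
             row.names = NULL)
}

#' Sensitivity indices straight from the two cytotoxicity readout tables
#'
#' Convenience wrapper: fits both readouts per line and combines their AUCs
#' with [cytotoxicity_index()].
#'
#' @param caspase_table,edu_table dose tables as in
#'   [fit_dose_response_table()].
#' @param ... passed to [cytotoxicity_index()].
#' @return data.frame with `cell_line`, `ci`.
#' @export
sensitivity_index <- function(caspase_table, edu_table, ...) {
  fc <- fit_dose_response_table(caspase_table)
  fe <- fit_dose_response_table(edu_table)
  lines <- intersect(names(fc), names(fe))
  cytotoxicity_index(
    setNames(vapply(fc[lines], function(z) as.numeric(z$auc), 0), lines),
    setNames(vapply(fe[lines], function(z) as.numeric(z$auc), 0), lines),
    ...)
}

#' Percent-non-viable AUC from a fluorescence viability assay
#'
#' Subtracts the mean blank-well background from all values, divides
#' treated wells by the mean of their matched control wells (percent
#' viable), converts to percent non-viable (`100 - viable`), averages over
#' replicates per dose, and sums over the dose series.
#'
#' @param fluor_table data.frame with columns `cell_line`, `replicate`,
#'   `dose_ng_ml`, `value`, `well_type` in
#'   `{"treated", "control", "blank"}`.
#' @return data.frame per cell line with `auc` (summed percent non-viable)
#'   and the per-dose means as attribute `dose_means`.
#' @export
viability_auc <- function(fluor_table) {
  dt <- data.table::as.data.table(fluor_table)
  stopifnot(all(c("cell_line", "dose_ng_ml", "value", "well_type")
                %in% names(dt)))
  out <- lapply(split(dt, dt$cell_line), function(sub) {
    cl <- sub$cell_line[1]
    blank <- sub[well_type == "blank", value]
    ctrl <- sub[well_type == "control", value]
    if (length(blank) == 0L || length(ctrl) == 0L)
      stop("missing blank or control wells for plate/cell line ", cl)
    bg <- mean(blank)
    ctrl_level <- mean(ctrl) - bg
    tr <- sub[well_type == "treated" & dose_ng_ml > 0]
    tr[, nonviable := 100 * (1 - (value - bg) / ctrl_level)]
    per_dose <- tr[, .(nonviable = mean(nonviable)), by = dose_ng_ml]
    structure(list(cell_line = cl, auc = sum(per_dose$nonviable)),
              dose_means = per_dose)
  })
  res <- data.frame(cell_line = vapply(out, `[[`, "", "cell_line"),
                    auc = vapply(out, `[[`, 0, "auc"), row.names = NULL)
  attr(res, "dose_means") <- lapply(out, attr, "dose_means")
  res
}

#' Co-treatment sensitivity change relative to a reference
#'
#' `delta = condition_auc / reference_auc`, the normalization of a
#' condition's sensitivity index by its solvent or scrambled control.
#'
#' @param condition_auc numeric (possibly named vector).
#' @param reference_auc nonzero scalar.
#' @return the ratio(s).
#' @export
delta_sensitivity <- function(condition_auc, reference_auc) {
  stopifnot(length(reference_auc) == 1L)
  if (!is.finite(reference_auc) || reference_auc == 0)
    stop("reference AUC must be nonzero")
  condition_auc / reference_auc
}
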