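#' Aggregate single-cell quantifications to well means
#'
#' Arithmetic mean of the per-cell totals per
#' (cell line, replicate, signal, region, time). Wells should already have
#' passed [well_qc()]; empty wells are simply absent from the output.
#'
#' @param cells data.frame/data.table with columns `cell_line`,
#'   `replicate`, `time_min`, `signal`, `region`, `total_intensity` (the
#'   shape written by [generate_single_cell_features()] or assembled from
#'   [quantify_regions()] output).
#' @return a `data.table` with one row per condition and columns
#'   `cell_line`, `replicate`, `signal`, `region`, `time_min`,
#'   `mean_intensity`, `n_cells`.
#' @export
aggregate_wells <- function(cells) {
  dt <- data.table::as.data.table(cells)
  need <- c("cell_line", "replicate", "time_min", "signal", "region",
            "total_intensity")
  stopifnot(all(need %in% names(dt)))
  dt[, .(mean_intensity = mean(total_intensity), n_cells = .N),
     by = .(cell_line, replicate, signal, region, time_min)]
}

#' Normalize well means into log2 time-course profiles
#'
#' Replicates are averaged first (order matters: log-of-mean, not
#' mean-of-log), then each (cell line, signal, region) time series is
#' divided by its value at time 0 and log2-transformed, anchoring every
#' profile at exactly 0 at time 0. Series whose time-0 baseline is missing
#' or non-positive are dropped and flagged. Replicate reproducibility is
#' summarized as the mean across time of the across-replicate CV; series
#' with `replicate_cv > 3 * ref_cv` are flagged as discordant.
#'
#' @param well_means output of [aggregate_wells()] (or
#'   [generate_well_features()]).
#' @param ref_cv reference CV for the reproducibility flag (default 0.10,
#'   the typical control-well variation).
#' @return a `data.table` of class `signal_profiles`: columns `cell_line`,
#'   `signal`, `region`, `time_min`, `log2_fc`, `replicate_cv`,
#'   `discordant`; dropped series in attribute `dropped`.
#' @export
normalize_profiles <- function(well_means, ref_cv = 0.10) {
  dt <- data.table::as.data.table(well_means)
  need <- c("cell_line", "replicate", "signal", "region", "time_min",
            "mean_intensity")
  stopifnot(all(need %in% names(dt)))
  rep_avg <- dt[, .(value = mean(mean_intensity),
                    rep_cv = if (.N > 1 && mean(mean_intensity) > 0)
                      sd(mean_intensity) / mean(mean_intensity) else 0),
                by = .(cell_line, signal, region, time_min)]
  rep_avg[, baseline := value[time_min == 0][1],
          by = .(cell_line, signal, region)]
  bad <- rep_avg[is.na(baseline) | baseline <= 0,
                 unique(paste(cell_line, signal, region, sep = "/"))]
  if (length(bad))
    warning(length(bad), " series dropped (missing or non-positive time-0 baseline)")
  rep_avg <- rep_avg[!is.na(baseline) & baseline > 0]
  rep_avg[, log2_fc := log2(value / baseline)]
  rep_avg[time_min == 0, log2_fc := 0] # anchor exactly
  out <- rep_avg[, .(replicate_cv = mean(rep_cv),
                     discordant = mean(rep_cv) > 3 * ref_cv),
                 by = .(cell_line, signal, region)][rep_avg,
                 on = c("cell_line", "signal", "region")]
  out <- out[, .(cell_line, signal, region, time_min, log2_fc,
                 replicate_cv, discordant)]
  data.table::setattr(out, "dropped", bad)
  data.table::setattr(out, "class",
                      c("signal_profiles", class(out)))
  out[]
}

#' Mask sub-threshold signaling changes
#'
#' Changes smaller than `min_fold` (default 30%, i.e. |log2| < 0.379...)
#' are treated as no-change and set to 0; the boundary is inclusive, so a
#' log2 change of exactly `log2(1.3)` is retained.
#'
#' @param profiles a [normalize_profiles()] result (or any table with a
#'   `log2_fc` column).
#' @param min_fold minimum retained fractional change.
#' @return the table with masked `log2_fc`.
#' @export
threshold_changes <- function(profiles, min_fold = 0.30) {
  dt <- data.table::as.data.table(data.table::copy(profiles))
  thr <- log2(1 + min_fold)
  dt[abs(log2_fc) < thr - 1e-12, log2_fc := 0]
  dt[]
}

#' Build the wide cell-line x event feature matrix
#'
#' Columns are the `signal__region__tNN` labels in deterministic
#' (signal, region, time) order; rows are cell lines. The full default
#' design yields 1170 columns (13 signals x 9 regions x 10 times); a single
#' signal yields 90.
#'
#' @param profiles a [normalize_profiles()] result.
#' @param design optional [assay_design()] whose axes define the expected
#'   grid; defaults to the axes present in `profiles`.
#' @return numeric matrix with rownames = cell lines.
#' @export
build_feature_matrix <- function(profiles, design = NULL) {
  dt <- data.table::as.data.table(profiles)
  signals <- if (is.null(design)) sort(unique(dt$signal)) else
    intersect(design$signals, unique(dt$signal))
  regions <- if (is.null(design)) sort(unique(dt$region)) else design$regions
  times <- if (is.null(design)) sort(unique(dt$time_min)) else
    design$time_points_min
  grid <- expand.grid(time_min = times, region = regions, signal = signals,
                      stringsAsFactors = FALSE)
  cols <- feature_name(grid$signal, grid$region, grid$time_min)
  lines <- sort(unique(dt$cell_line))
  dt[, feature := feature_name(signal, region, time_min)]
  m <- matrix(NA_real_, length(lines), length(cols),
              dimnames = list(lines, cols))
  m[cbind(match(dt$cell_line, lines), match(dt$feature, cols))] <- dt$log2_fc
  if (anyNA(m)) {
    gaps <- colnames(m)[colSums(is.na(m)) > 0]
    stop("missing (signal, region, time) cells: ",
         paste(head(gaps, 10), collapse = ", "),
         if (length(gaps) > 10) sprintf(" ... (%d total)", length(gaps)))
  }
  m
}

#' Compare per-signal maximum response levels between two cell lines
#'
#' For each signal, takes the maximum fold change over all (region, time)
#' and flags the signal as differential when the two lines' maxima differ
#' by at least `min_fold` (ratio >= 1 + min_fold on the fold-change scale).
#'
#' @param profiles a [normalize_profiles()] result covering both lines.
#' @param line_a,line_b cell-line names.
#' @param min_fold relative-difference threshold (default 30%).
#' @return data.frame per signal: `max_a`, `max_b` (fold-change scale),
#'   `ratio`, `differential`.
#' @export
max_level_comparison <- function(profiles, line_a, line_b, min_fold = 0.30) {
  dt <- data.table::as.data.table(profiles)
  stopifnot(line_a %in% dt$cell_line, line_b %in% dt$cell_line)
  mx <- dt[cell_line %in% c(line_a, line_b),
           .(max_fc = 2^max(log2_fc)), by = .(cell_line, signal)]
  wide <- data.table::dcast(mx, signal ~ cell_line, value.var = "max_fc")
  out <- data.frame(signal = wide$signal,
                    max_a = wide[[line_a]], max_b = wide[[line_b]])
  out$ratio <- pmax(out$max_a, out$max_b) / pmin(out$max_a, out$max_b)
  out$differential <- out$ratio >= 1 + min_fold
  out
}
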