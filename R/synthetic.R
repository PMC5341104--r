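#' Default assay design
#'
#' The full measurement design emulated by the synthetic module: 13 phospho
#' signals x 9 subcellular regions x 10 time points (0-55 min) = 1170
#' phosphorylation events per cell line, plus a 10-dose treatment series
#' spanning 0.01-3000 ng/mL and a vehicle control.
#'
#' The dose ladder keeps the published endpoints (0.01 and 3000 ng/mL) with
#' 10 geometrically spaced doses; an exact three-fold ladder cannot span
#' that range in 10 steps, so the step is ~4.06-fold.
#'
#' @param signals,regions,time_points_min,doses_ng_ml design axes.
#' @param replicates number of experimental replicates (>= 2).
#' @param cells_per_well nominal cells imaged per well.
#' @return an object of class `assay_design`.
#' @export
assay_design <- function(signals = c("pBCatenin", "pTBK1", "pERK", "pHSP27",
                                     "pp38", "pGSK3b", "pRSK", "pcJun",
                                     "pAKT", "pJNK", "pCREB", "pRelA", "pMK2"),
                         regions = REGION_LABELS,
                         time_points_min = c(0, 2, 5, 10, 15, 20, 25, 30, 45, 55),
                         doses_ng_ml = signif(10^seq(log10(0.01), log10(3000),
                                                     length.out = 10), 4),
                         replicates = 2L,
                         cells_per_well = 1000L) {
  stopifnot(replicates >= 2, 0 %in% time_points_min,
            all(diff(doses_ng_ml) > 0), all(doses_ng_ml > 0))
  structure(list(signals = signals, regions = regions,
                 time_points_min = sort(time_points_min),
                 doses_ng_ml = doses_ng_ml,
                 replicates = as.integer(replicates),
                 cells_per_well = as.integer(cells_per_well)),
            class = "assay_design")
}

#' Deterministic feature label for one phosphorylation event
#' @param signal,region,time_min coordinates of the event.
#' @return character label `signal__region__tNN`.
#' @export
feature_name <- function(signal, region, time_min) {
  paste0(signal, "__", region, "__t", sprintf("%02d", as.integer(time_min)))
}

# unimodal response bump: g(0) = 0, g(peak) = 1, shape set by width
# g(t) = (t/tp)^k * exp(k * (1 - t/tp)), k = (tp / width)^2
template_bump <- function(t, peak_min, width_min) {
  k <- max(1, (peak_min / width_min)^2)
  # log-space evaluation: k can be large for sharply localized responses
  ifelse(t <= 0, 0, exp(k * (log(t / peak_min) + 1 - t / peak_min)))
}

#' Construct a synthetic cell-line specification
#'
#' A cell line is a true sensitivity in `[0, 1]` plus one response-curve
#' template per (signal, region): a smooth bump in log2 fold change with a
#' peak time, peak log2 amplitude, and width. All templates equal a fold
#' change of 1 at time 0. Two designated templates (the "planted features")
#' have amplitudes tied to the true sensitivity through a linear law so
#' that downstream regression can be validated against ground truth.
#'
#' @param name identifier.
#' @param true_sensitivity dimensionless in `[0, 1]`.
#' @param templates data.frame with columns `signal`, `region`, `peak_min`,
#'   `log2_amp`, `width_min`.
#' @param noise_cv default well-level multiplicative noise CV for this line.
#' @param planted optional data.frame (columns `feature`, `signal`,
#'   `region`, `time_min`, `weight`) describing the planted linear law.
#' @param intercept intercept of the planted law.
#' @return an object of class `cell_line_spec`.
#' @export
cell_line_spec <- function(name, true_sensitivity, templates,
                           noise_cv = 0.05, planted = NULL, intercept = 0) {
  stopifnot(true_sensitivity >= 0, true_sensitivity <= 1,
            all(c("signal", "region", "peak_min", "log2_amp", "width_min")
                %in% names(templates)))
  structure(list(name = name, true_sensitivity = true_sensitivity,
                 templates = templates, noise_cv = noise_cv,
                 planted = planted, intercept = intercept),
            class = "cell_line_spec")
}

#' Default synthetic cell-line panel
#'
#' Eight cell lines with true sensitivities spread over `[0.03, 1.0]`
#' (a > 30-fold spread between the most resistant and most sensitive
#' lines). The planted linear law ties sensitivity to two spatiotemporal
#' features of the `pRSK` signal -- its outer-cytoplasm level at 55 min
#' (weight +0.369) and its outer-nucleus level at 2 min (weight -0.175):
#' `s = 0.369 * f1 - 0.175 * f2 + intercept`. The second feature varies
#' independently of sensitivity across the panel so the two planted
#' features are not collinear; the first is solved from the law. All other
#' templates are shared across lines (their responses carry no sensitivity
#' information beyond noise).
#'
#' @param n_lines number of lines (default 8).
#' @param sensitivities true sensitivities; default spread over
#'   `[0.03, 1]`.
#' @param planted_weights length-2 numeric, weights of the planted law.
#' @param intercept intercept of the planted law.
#' @param noise_cv well-level noise CV stored on each spec.
#' @param line_hetero strength of the line-to-line heterogeneity factor: a
#'   latent per-line scalar `u_j` scales every background template
#'   amplitude by `(1 + line_hetero * u_j)`, emulating the global
#'   staining/expression offsets that dominate between-line variance in
#'   imaging panels and making non-planted features strongly correlated
#'   with one another rather than independent noise.
#' @param panel_seed seed for the (fixed) template assembly; the default
#'   panel is deterministic.
#' @param design the [assay_design()] whose signal/region axes the
#'   templates cover.
#' @return list of [cell_line_spec()] objects, with attributes
#'   `planted_features` (the two feature labels) and `planted_law`.
#' @export
default_cell_lines <- function(n_lines = 8L,
                               design = assay_design(),
                               sensitivities = NULL,
                               planted_weights = c(0.369, -0.175),
                               intercept = -0.15,
                               noise_cv = 0.05,
                               line_hetero = 0.5,
                               panel_seed = 11L) {
  if (is.null(sensitivities))
    sensitivities <- signif(exp(seq(log(0.03), log(1), length.out = n_lines)), 3)
  stopifnot(length(sensitivities) == n_lines,
            all(sensitivities >= 0 & sensitivities <= 1))
  w1 <- planted_weights[1]; w2 <- planted_weights[2]

  planted <- data.frame(
    feature = c("F1", "F2"),
    signal = c("pRSK", "pRSK"),
    region = c("outer_cytoplasm", "outer_nucleus"),
    time_min = c(55, 2),
    weight = c(w1, w2))

  with_seed(panel_seed, {
    # background templates for every (signal, region): broad mid-peaked
    # bumps (every sampled time keeps >= ~20% of the peak) with amplitudes
    # bounded away from zero, so line-to-line heterogeneity reaches every
    # event rather than leaving early/late events as pure measurement noise
    grid <- expand.grid(signal = design$signals, region = design$regions,
                        stringsAsFactors = FALSE)
    grid$peak_min <- sample(c(10, 15, 20, 25, 30), nrow(grid), replace = TRUE)
    grid$log2_amp <- sample(c(-1, 1), nrow(grid), TRUE) *
      runif(nrow(grid), 0.4, 1.2)
    grid$width_min <- grid$peak_min / sqrt(runif(nrow(grid), 0.5, 0.9))
    theta <- runif(nrow(grid), 0, 2 * pi) # loading angle per series

    # second planted feature: negatively correlated with sensitivity
    # (resistant lines respond earlier at the outer nucleus) but with
    # independent line-to-line variation, so the two planted features are
    # not collinear and f2 passes the |r| >= 0.1 relevance filter
    f2 <- pmax(0.3, 1.8 - 1.6 * (sensitivities - mean(sensitivities)) +
                 rnorm(n_lines, 0, 0.8))
    f1 <- (sensitivities - w2 * f2 - intercept) / w1
    # rank-one latent line-heterogeneity (global responsiveness) factor;
    # per-series loadings vary in sign and magnitude
    u <- rnorm(n_lines)

    specs <- lapply(seq_len(n_lines), function(j) {
      tpl <- grid
      tpl$log2_amp <- tpl$log2_amp * (1 + line_hetero * cos(theta) * u[j])
      tpl$component <- "background"
      # the planted series keep a small heterogeneity-scaled background so
      # their off-peak events behave like every other event; the planted
      # components are narrow additive bumps localized at the designated
      # sampling times (adjacent grid points see < 0.1% of the amplitude),
      # so the affine law lives at exactly two (signal, region, time)
      # triples
      i12 <- ("pRSK" %in% design$signals) & (tpl$signal == "pRSK" &
                tpl$region %in% c("outer_cytoplasm", "outer_nucleus"))
      tpl$log2_amp[i12] <- 0.15 * tpl$log2_amp[i12] / abs(grid$log2_amp[i12])
      tpl <- rbind(tpl, data.frame(
        signal = "pRSK",
        region = c("outer_cytoplasm", "outer_nucleus"),
        peak_min = c(55, 2), log2_amp = c(f1[j], f2[j]),
        width_min = c(55, 2) / 20, component = "planted"))
      cell_line_spec(sprintf("SYN%02d", j), sensitivities[j], tpl,
                     noise_cv = noise_cv, planted = planted,
                     intercept = intercept)
    })
    names(specs) <- vapply(specs, `[[`, "", "name")
    structure(specs,
              planted_features = feature_name(planted$signal, planted$region,
                                              planted$time_min),
              planted_law = list(weights = planted_weights,
                                 intercept = intercept))
  })
}

# exact log2 fold-change templates of one spec over the design grid; a
# (signal, region) series may be composed of several additive bump rows
# (e.g. a background response plus a localized planted component)
template_log2_table <- function(spec, design,
                                signals = design$signals) {
  tpl <- spec$templates
  tpl <- tpl[tpl$signal %in% signals & tpl$region %in% design$regions, ]
  if (nrow(tpl) == 0L)
    stop("spec '", spec$name, "' has no templates for the requested signals")
  out <- do.call(rbind, lapply(seq_len(nrow(tpl)), function(i) {
    data.frame(signal = tpl$signal[i], region = tpl$region[i],
               time_min = design$time_points_min,
               log2_fc = tpl$log2_amp[i] *
                 template_bump(design$time_points_min, tpl$peak_min[i],
                               tpl$width_min[i]))
  }))
  out <- aggregate(log2_fc ~ signal + region + time_min, data = out, FUN = sum)
  out$cell_line <- spec$name
  out
}

#' Noiseless feature matrix implied by a panel of specs
#'
#' Rows are cell lines, columns the `signal__region__tNN` event labels,
#' values the exact log2 fold-change templates -- the ground truth against
#' which the pipeline's recovered feature matrix can be compared.
#'
#' @param specs list of [cell_line_spec()].
#' @param design an [assay_design()].
#' @param signals subset of signals (default all).
#' @return numeric matrix, lines x events.
#' @export
true_feature_matrix <- function(specs, design = assay_design(),
                                signals = design$signals) {
  rows <- lapply(specs, function(sp) {
    tab <- template_log2_table(sp, design, signals)
    setNames(tab$log2_fc, feature_name(tab$signal, tab$region, tab$time_min))
  })
  grid <- expand.grid(time_min = design$time_points_min,
                      region = design$regions, signal = signals,
                      stringsAsFactors = FALSE)
  cols <- feature_name(grid$signal, grid$region, grid$time_min)
  m <- do.call(rbind, lapply(rows, function(v) v[cols]))
  dimnames(m) <- list(unname(vapply(specs, `[[`, "", "name")), cols)
  m
}

#' Generate a single-cell feature table
#'
#' One row per (cell line, replicate, time, cell, signal, region). Each
#' per-cell value is `baseline * 2^template * well_factor * cell_factor`,
#' with lognormal well- and cell-level factors of the given CVs, so well
#' means converge to `baseline * 2^template` as cells per well grow.
#'
#' @param specs list of [cell_line_spec()] (>= 2 lines for downstream
#'   classification; a single line is allowed for profiling tests).
#' @param design an [assay_design()].
#' @param signals subset of signals to generate (memory scales with
#'   `lines x replicates x times x cells x signals x regions`).
#' @param cells_per_well overrides `design$cells_per_well`.
#' @param cell_cv per-cell multiplicative noise CV (default 0.10).
#' @param well_cv per-well multiplicative noise CV (default from each
#'   spec's `noise_cv`, 0.05).
#' @param baseline arbitrary-unit baseline intensity.
#' @param seed RNG seed; identical seeds give identical tables.
#' @return a `data.table` with columns `cell_line`, `replicate`, `well`,
#'   `time_min`, `cell_id`, `signal`, `region`, `total_intensity`.
#' @export
generate_single_cell_features <- function(specs, design = assay_design(),
                                          signals = design$signals,
                                          cells_per_well = NULL,
                                          cell_cv = 0.10, well_cv = NULL,
                                          baseline = 1000, seed = 1L) {
  if (length(specs) < 1L) stop("need at least one cell-line spec")
  ncells <- cells_per_well %||% design$cells_per_well
  tabs <- lapply(seq_along(specs), function(j) {
    sp <- specs[[j]]
    wcv <- well_cv %||% sp$noise_cv
    tpl <- data.table::as.data.table(template_log2_table(sp, design, signals))
    with_seed(child_seed(seed, j), {
      # well factor per (replicate, signal, region, time): one well per
      # (replicate, time); signal/region share the well but are stained and
      # quantified separately, so the factor is drawn per measurement series
      wells <- data.table::CJ(replicate = seq_len(design$replicates),
                              signal = signals, region = design$regions,
                              time_min = design$time_points_min)
      wells[, well_factor := rlnorm_cv(.N, wcv)]
      dt <- wells[tpl, on = c("signal", "region", "time_min"),
                  allow.cartesian = TRUE]
      dt <- dt[rep(seq_len(nrow(dt)), each = ncells)]
      dt[, cell_id := rep(seq_len(ncells), length.out = .N)]
      dt[, total_intensity := baseline * 2^log2_fc * well_factor *
           rlnorm_cv(.N, cell_cv)]
      dt[, cell_line := sp$name]
      dt[, well := paste0(sp$name, "_r", replicate, "_t",
                          sprintf("%02d", time_min))]
      dt[, .(cell_line, replicate, well, time_min, cell_id, signal, region,
             total_intensity)]
    })
  })
  data.table::rbindlist(tabs)
}

#' Generate well-level mean features directly
#'
#' The analytic large-`n` limit of [generate_single_cell_features()]
#' aggregated to well means: `baseline * 2^template * well_factor`. Used for
#' regression-scale runs where the full per-cell table would be wastefully
#' large.
#'
#' @inheritParams generate_single_cell_features
#' @return a `data.table` with columns `cell_line`, `replicate`, `signal`,
#'   `region`, `time_min`, `mean_intensity`.
#' @export
generate_well_features <- function(specs, design = assay_design(),
                                   signals = design$signals,
                                   well_cv = NULL, baseline = 1000,
                                   seed = 1L) {
  tabs <- lapply(seq_along(specs), function(j) {
    sp <- specs[[j]]
    wcv <- well_cv %||% sp$noise_cv
    tpl <- data.table::as.data.table(template_log2_table(sp, design, signals))
    with_seed(child_seed(seed, j), {
      dt <- data.table::CJ(replicate = seq_len(design$replicates),
                           signal = signals, region = design$regions,
                           time_min = design$time_points_min)
      dt <- dt[tpl, on = c("signal", "region", "time_min"),
               allow.cartesian = TRUE]
      dt[, mean_intensity := baseline * 2^log2_fc * rlnorm_cv(.N, wcv)]
      dt[, cell_line := sp$name]
      dt[, .(cell_line, replicate, signal, region, time_min, mean_intensity)]
    })
  })
  data.table::rbindlist(tabs)
}

#' Generate dose-response readout tables
#'
#' Underlying curves are 3-parameter log-logistic in log dose on the log2
#' response-ratio scale, with top asymptote proportional to the line's true
#' sensitivity: cleaved-caspase-3 responses increase with dose and
#' sensitivity, EdU responses decrease, and the viability readout returns
#' raw fluorescence with matched blank and vehicle-control wells.
#'
#' @param specs list of [cell_line_spec()].
#' @param design an [assay_design()].
#' @param readout one of `"caspase3"`, `"edu"`, `"viability"`.
#' @param noise_cv multiplicative measurement noise CV (0 = noiseless).
#' @param baseline raw readout level at zero effect.
#' @param d_max log2 top-asymptote magnitude for the most sensitive line
#'   (caspase3: `+d_max * s`; edu: `-d_max * s`).
#' @param slope,ed50 shared log-logistic slope `b` (negative = increasing
#'   curve) and midpoint `e` in ng/mL.
#' @param include_vehicle add dose-0 rows.
#' @param seed RNG seed.
#' @return a `data.table`; for `caspase3`/`edu`: columns `cell_line`,
#'   `replicate`, `dose_ng_ml`, `readout`, `value`. `viability` adds a
#'   `well_type` column with `treated`, `control`, `blank` rows.
#' @export
generate_dose_response <- function(specs, design = assay_design(),
                                   readout = c("caspase3", "edu", "viability"),
                                   noise_cv = 0.05, baseline = 1000,
                                   d_max = 4, slope = -1.5, ed50 = 10,
                                   include_vehicle = TRUE, seed = 1L) {
  readout <- match.arg(readout)
  doses <- design$doses_ng_ml
  loglogistic <- function(x, d) d / (1 + exp(slope * (log(x) - log(ed50))))
  tabs <- lapply(seq_along(specs), function(j) {
    sp <- specs[[j]]
    with_seed(child_seed(seed, j + 1000L), {
      dt <- data.table::CJ(replicate = seq_len(design$replicates),
                           dose_ng_ml = doses)
      if (readout == "caspase3") {
        l2 <- loglogistic(dt$dose_ng_ml, d_max * sp$true_sensitivity)
      } else if (readout == "edu") {
        l2 <- loglogistic(dt$dose_ng_ml, -0.75 * d_max * sp$true_sensitivity)
      } else {
        kill <- 0.8 * sp$true_sensitivity /
          (1 + exp(slope * (log(dt$dose_ng_ml) - log(ed50))))
        l2 <- log2(pmax(1e-6, 1 - kill))
      }
      dt[, value := baseline * 2^l2 * rlnorm_cv(.N, noise_cv)]
      if (include_vehicle) {
        veh <- data.table::data.table(replicate = seq_len(design$replicates),
                                      dose_ng_ml = 0,
                                      value = baseline *
                                        rlnorm_cv(design$replicates, noise_cv))
        dt <- rbind(dt, veh)
      }
      ro <- readout
      dt[, `:=`(cell_line = sp$name, readout = ro)]
      if (readout == "viability") {
        # treated/control wells share an additive background of 100 units
        dt[, value := value + 100]
        dt[, well_type := "treated"]
        extra <- data.table::data.table(
          replicate = rep(seq_len(design$replicates), 2),
          dose_ng_ml = NA_real_,
          value = c(baseline * rlnorm_cv(design$replicates, noise_cv) + 100,
                    100 * rlnorm_cv(design$replicates, noise_cv)),
          cell_line = sp$name, readout = ro,
          well_type = rep(c("control", "blank"), each = design$replicates))
        dt <- rbind(dt, extra)
      }
      dt
    })
  })
  out <- data.table::rbindlist(tabs, use.names = TRUE)
  data.table::setcolorder(out, c("cell_line", "replicate", "dose_ng_ml",
                                 "readout", "value"))
  out[]
}

#' Shift a cell-line spec's planted features (a co-treatment analogue)
#'
#' Returns a copy of `base_spec` whose planted-feature log2 amplitudes are
#' shifted by `(delta_f1, delta_f2)` and whose true sensitivity moves
#' according to the planted linear law
#' `delta_s = w1 * delta_f1 + w2 * delta_f2`. A sensitizing co-treatment is
#' a positive `delta_f1`; a desensitizing one a positive `delta_f2`.
#'
#' @param base_spec a [cell_line_spec()] carrying a planted law.
#' @param delta_f1,delta_f2 log2 shifts of the two planted features.
#' @param name name of the derived condition.
#' @return a new `cell_line_spec`.
#' @export
generate_cotreatment_shift <- function(base_spec, delta_f1, delta_f2,
                                       name = paste0(base_spec$name, "_shift")) {
  stopifnot(inherits(base_spec, "cell_line_spec"))
  if (is.null(base_spec$planted))
    stop("base spec carries no planted linear law")
  pl <- base_spec$planted
  sp <- base_spec
  sp$name <- name
  deltas <- c(delta_f1, delta_f2)
  comp <- sp$templates$component %||% rep("planted", nrow(sp$templates))
  for (i in 1:2) {
    sel <- sp$templates$signal == pl$signal[i] &
      sp$templates$region == pl$region[i] & comp == "planted"
    if (!any(sel)) stop("no planted template row for ", pl$feature[i])
    sp$templates$log2_amp[sel] <- sp$templates$log2_amp[sel] + deltas[i]
  }
  new_s <- sp$true_sensitivity + sum(pl$weight * deltas)
  if (new_s < 0)
    stop("shift drives true sensitivity below 0 (", signif(new_s, 3), ")")
  sp$true_sensitivity <- min(1, new_s)
  if (new_s > 1)
    warning("shifted sensitivity clipped at 1")
  sp
}
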