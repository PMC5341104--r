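#' Region-detection parameters
#'
#' Band widths, in pixels, used to zone a segmented cell into subcellular
#' regions. Defaults follow the published region-detection settings:
#' nuclear boundary 3 px, perinuclear boundary 6 px, cytoplasmic boundary
#' 4 px.
#'
#' @param nuclear_boundary_px width of the outer-nuclear band.
#' @param perinuclear_boundary_px width of the perinuclear band outside the
#'   nucleus.
#' @param cytoplasmic_boundary_px width of the outer-cytoplasmic band inside
#'   the cell boundary.
#' @param chromosome_method thresholding method for the DNA-bright
#'   (chromosome) region; currently only `"otsu"`.
#' @return an object of class `region_params`.
#' @export
region_params <- function(nuclear_boundary_px = 3L,
                          perinuclear_boundary_px = 6L,
                          cytoplasmic_boundary_px = 4L,
                          chromosome_method = "otsu") {
  stopifnot(nuclear_boundary_px >= 1, perinuclear_boundary_px >= 1,
            cytoplasmic_boundary_px >= 1)
  chromosome_method <- match.arg(chromosome_method, "otsu")
  structure(list(nuclear_boundary_px = as.integer(nuclear_boundary_px),
                 perinuclear_boundary_px = as.integer(perinuclear_boundary_px),
                 cytoplasmic_boundary_px = as.integer(cytoplasmic_boundary_px),
                 chromosome_method = chromosome_method),
            class = "region_params")
}

REGION_LABELS <- c("whole_cell", "cytoplasm", "nucleus",
                   "outer_cytoplasm", "inner_cytoplasm", "peri_nucleus",
                   "outer_nucleus", "inner_nucleus", "chromosome")

# squared Euclidean distance of each TRUE pixel to the nearest FALSE pixel;
# the image border counts as background
dist_to_background_sq <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  d <- edt_sq_cpp(pad)
  d[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
}

#' Binary erosion / dilation by a Euclidean disk
#'
#' Morphology on logical matrices with a disk structuring element of radius
#' `r` pixels, computed through an exact distance transform. Pixels outside
#' the image are background. Distances are center-to-center, which
#' overestimates the distance to the continuous region boundary by about a
#' quarter pixel on average; the thresholds carry that half-pixel-grid
#' correction so an eroded/dilated disk of radius R lands close to the
#' continuous disk of radius `R -+ r`.
#'
#' @param mask logical matrix.
#' @param r disk radius in pixels.
#' @return logical matrix of the same shape.
#' @export
erode_mask <- function(mask, r) {
  stopifnot(is.matrix(mask))
  if (r <= 0) return(mask)
  dist_to_background_sq(mask) > (r + 0.25)^2
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, r) {
  stopifnot(is.matrix(mask))
  if (r <= 0) return(mask)
  # distance of every pixel to the nearest mask pixel (0 on the mask itself)
  edt_sq_cpp(!mask) <= (r + 0.25)^2
}

#' Partition a segmented cell into nine subcellular regions
#'
#' Zones a cell into `whole_cell`, `cytoplasm`, `nucleus`, plus the leaf
#' bands `outer_cytoplasm`, `inner_cytoplasm`, `peri_nucleus`,
#' `outer_nucleus`, `inner_nucleus`, and the DNA-bright `chromosome` region.
#' Bands are erosion/dilation residues with disk structuring elements of the
#' widths in `params`:
#' * `outer_nucleus` = nucleus minus its erosion by the nuclear boundary
#'   width; `inner_nucleus` is the remainder.
#' * `peri_nucleus` = dilation of the nucleus by the perinuclear width,
#'   intersected with the cytoplasm.
#' * `outer_cytoplasm` = the band inside the cell boundary of the
#'   cytoplasmic width, within the cytoplasm, minus `peri_nucleus`
#'   (the perinuclear band takes precedence where the two overlap);
#'   `inner_cytoplasm` is what remains.
#' * `chromosome` = DNA-bright pixels inside the nucleus (Otsu threshold of
#'   the DNA channel restricted to the nuclear mask). It overlaps the two
#'   nuclear bands and is excluded from additivity checks.
#'
#' @param nuclear_mask,cell_mask logical matrices; the nucleus must lie
#'   inside the cell.
#' @param dna_channel optional numeric matrix used for the chromosome
#'   region; if `NULL` the chromosome mask is empty and flagged.
#' @param params a [region_params()] object.
#' @return an object of class `region_set`: a named list of nine logical
#'   masks with attributes `degenerate` (logical) and `flags` (character).
#' @export
partition_cell <- function(nuclear_mask, cell_mask, dna_channel = NULL,
                           params = region_params()) {
  nuclear_mask <- nuclear_mask > 0
  cell_mask <- cell_mask > 0
  stopifnot(is.matrix(nuclear_mask), is.matrix(cell_mask),
            all(dim(nuclear_mask) == dim(cell_mask)))
  if (!any(nuclear_mask) || !any(cell_mask))
    stop("empty nuclear or cell mask")
  if (any(nuclear_mask & !cell_mask))
    stop("nuclear mask extends outside the cell mask")

  flags <- character()
  nucleus <- nuclear_mask
  whole_cell <- cell_mask
  cytoplasm <- cell_mask & !nucleus
  if (!any(cytoplasm)) flags <- c(flags, "empty_cytoplasm")

  inner_nucleus <- erode_mask(nucleus, params$nuclear_boundary_px)
  outer_nucleus <- nucleus & !inner_nucleus
  if (!any(inner_nucleus)) flags <- c(flags, "nucleus_thinner_than_band")

  peri <- dilate_mask(nucleus, params$perinuclear_boundary_px) & cytoplasm
  rim <- cell_mask & !erode_mask(cell_mask, params$cytoplasmic_boundary_px)
  outer_cytoplasm <- rim & cytoplasm & !peri
  inner_cytoplasm <- cytoplasm & !peri & !outer_cytoplasm
  if (any(cytoplasm) && !any(inner_cytoplasm))
    flags <- c(flags, "cytoplasm_thinner_than_bands")

  if (is.null(dna_channel)) {
    chromosome <- matrix(FALSE, nrow(nucleus), ncol(nucleus))
    flags <- c(flags, "no_dna_channel")
  } else {
    stopifnot(all(dim(dna_channel) == dim(nucleus)))
    thr <- otsu_threshold(dna_channel[nucleus])
    chromosome <- nucleus & dna_channel > thr
  }

  structure(list(whole_cell = whole_cell, cytoplasm = cytoplasm,
                 nucleus = nucleus, outer_cytoplasm = outer_cytoplasm,
                 inner_cytoplasm = inner_cytoplasm, peri_nucleus = peri,
                 outer_nucleus = outer_nucleus, inner_nucleus = inner_nucleus,
                 chromosome = chromosome),
            class = "region_set",
            degenerate = length(flags) > 0L,
            flags = flags)
}

#' Quantify total channel intensity per subcellular region
#'
#' @param phospho_channel numeric matrix (same shape as the masks).
#' @param region_set a [partition_cell()] result.
#' @param cell_id identifier carried into the output.
#' @return a data.frame with columns `cell_id`, `region`, `area_px`,
#'   `total_intensity`. The additivity
#'   `total(whole_cell) = total(cytoplasm) + total(nucleus)` holds exactly.
#' @export
quantify_regions <- function(phospho_channel, region_set, cell_id = "cell") {
  stopifnot(inherits(region_set, "region_set"), is.matrix(phospho_channel),
            all(dim(phospho_channel) == dim(region_set$whole_cell)))
  data.frame(
    cell_id = cell_id,
    region = names(region_set),
    area_px = vapply(region_set, sum, numeric(1)),
    total_intensity = vapply(region_set,
                             function(m) sum(phospho_channel[m]), numeric(1)),
    row.names = NULL)
}

#' Remove low-cell-count wells
#'
#' Wells with fewer cells than `min_cells` (default 100, the published QC
#' rule) are dropped. The report carries per-well cell counts and the
#' coefficient of variation of whole-cell areas, a segmentation-stability
#' diagnostic.
#'
#' @param quants data.frame of per-cell region quantifications with at least
#'   columns `well`, `cell_id`; rows with `region == "whole_cell"` supply
#'   the per-cell areas.
#' @param min_cells minimum cells per well.
#' @return list with `kept` (filtered rows), `removed_wells`, and `report`
#'   (one row per well: `well`, `n_cells`, `area_cv`, `kept`).
#' @export
well_qc <- function(quants, min_cells = 100L) {
  if (nrow(quants) == 0L) {
    warning("empty quantification table")
    return(list(kept = quants, removed_wells = character(),
                report = data.frame(well = character(), n_cells = integer(),
                                    area_cv = numeric(), kept = logical())))
  }
  stopifnot(all(c("well", "cell_id") %in% names(quants)))
  wc <- quants[quants$region == "whole_cell", , drop = FALSE]
  if (nrow(wc) == 0L) wc <- quants # tables without region column semantics
  counts <- tapply(wc$cell_id, wc$well, function(x) length(unique(x)))
  cv <- tapply(wc$area_px, wc$well,
               function(a) if (mean(a) > 0) sd(a) / mean(a) else NA_real_)
  report <- data.frame(well = names(counts),
                       n_cells = as.integer(counts),
                       area_cv = as.numeric(cv[names(counts)]),
                       kept = as.integer(counts) >= min_cells,
                       row.names = NULL)
  removed <- report$well[!report$kept]
  list(kept = quants[!quants$well %in% removed, , drop = FALSE],
       removed_wells = removed,
       report = report)
}
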