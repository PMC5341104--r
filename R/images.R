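#' Generate a synthetic segmented-cell image
#'
#' Builds a concentric-disk cell (cell and nucleus masks, DNA channel,
#' phospho channel) whose true per-region total intensities are known by
#' construction: the phospho channel is piecewise-constant over the five
#' disjoint leaf regions (`outer_cytoplasm`, `inner_cytoplasm`,
#' `peri_nucleus`, `outer_nucleus`, `inner_nucleus`), with each region's
#' pixel value set to `target / area` so the region total matches its
#' target up to rasterization. The DNA channel covers the nucleus with a
#' brighter condensed-chromatin core so the chromosome region is
#' recoverable by thresholding.
#'
#' @param shape list with `cell_radius`, `nucleus_radius` (pixels), and
#'   optionally `size` (image side, default `2*cell_radius + 11`),
#'   `nucleus_offset` (integer xy shift of the nucleus center, default
#'   `c(0,0)`).
#' @param region_intensity_targets named numeric vector of desired total
#'   intensities over (a subset of) the leaf regions; omitted regions get 0.
#' @param params [region_params()] used both to zone the synthetic cell and
#'   to check band feasibility.
#' @param dna_intensity base DNA-channel value over the nucleus; the core
#'   (radius `chromosome_frac * nucleus_radius`) is 3x brighter.
#' @param chromosome_frac radius fraction of the bright core.
#' @param noise_sd additive Gaussian noise applied to the phospho channel
#'   (clipped at 0); default 0 keeps totals exact.
#' @param seed RNG seed for the noise; the construction itself is
#'   deterministic.
#' @return an object of class `syn_cell_image`: list with `nuclear_mask`,
#'   `cell_mask`, `dna_channel`, `phospho_channel`, and attribute
#'   `true_totals` (the analytic per-leaf-region totals actually painted).
#' @export
generate_cell_image <- function(shape = list(cell_radius = 20, nucleus_radius = 10),
                                region_intensity_targets = NULL,
                                params = region_params(),
                                dna_intensity = 100, chromosome_frac = 0.5,
                                noise_sd = 0, seed = NULL) {
  cr <- shape$cell_radius
  nr <- shape$nucleus_radius
  stopifnot(is.numeric(cr), is.numeric(nr), cr > 0, nr > 0)
  off <- shape$nucleus_offset %||% c(0, 0)
  if (nr + sqrt(sum(off^2)) >= cr)
    stop("infeasible geometry: nucleus (radius ", nr,
         ", offset ", sqrt(sum(off^2)), ") does not fit inside cell radius ", cr)
  if (cr <= nr + 1)
    stop("infeasible geometry: no room for cytoplasmic bands")

  size <- shape$size %||% (2L * ceiling(cr) + 11L)
  ctr <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
  rho_cell <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  rho_nuc <- sqrt((xs - ctr - off[1])^2 + (ys - ctr - off[2])^2)
  cell_mask <- rho_cell <= cr
  nuclear_mask <- rho_nuc <= nr

  dna <- matrix(0, size, size)
  dna[nuclear_mask] <- dna_intensity
  core <- rho_nuc <= chromosome_frac * nr
  dna[core & nuclear_mask] <- 3 * dna_intensity

  rs <- partition_cell(nuclear_mask, cell_mask, dna_channel = dna,
                       params = params)
  leaves <- c("outer_cytoplasm", "inner_cytoplasm", "peri_nucleus",
              "outer_nucleus", "inner_nucleus")
  targets <- setNames(numeric(length(leaves)), leaves)
  if (!is.null(region_intensity_targets)) {
    bad <- setdiff(names(region_intensity_targets), leaves)
    if (length(bad))
      stop("targets must name leaf regions only; offending: ",
           paste(bad, collapse = ", "))
    if (any(region_intensity_targets < 0)) stop("targets must be nonnegative")
    targets[names(region_intensity_targets)] <- region_intensity_targets
  }

  phospho <- matrix(0, size, size)
  painted <- setNames(numeric(length(leaves)), leaves)
  for (lv in leaves) {
    a <- sum(rs[[lv]])
    if (a > 0 && targets[[lv]] > 0) {
      phospho[rs[[lv]]] <- targets[[lv]] / a
      painted[[lv]] <- targets[[lv]]
    } else if (targets[[lv]] > 0) {
      warning("region ", lv, " is empty; target dropped")
    }
  }
  if (noise_sd > 0) {
    phospho <- with_seed(seed, {
      phospho + matrix(rnorm(size^2, 0, noise_sd), size, size)
    })
    phospho[phospho < 0] <- 0
    phospho[!cell_mask] <- 0
  }

  structure(list(nuclear_mask = nuclear_mask, cell_mask = cell_mask,
                 dna_channel = dna, phospho_channel = phospho),
            class = "syn_cell_image", true_totals = painted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the four rasters of a synthetic cell image as PGM files
#'
#' Masks are written as 0/255, channels rounded to integers. Companion to
#' [read_cell_image()].
#'
#' @param img a `syn_cell_image`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return the four paths, invisibly.
#' @export
write_cell_image <- function(img, dir, prefix = "cell") {
  stopifnot(inherits(img, "syn_cell_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, "_", c("nucmask", "cellmask", "dna", "phospho"), ".pgm"))
  write_pgm(img$nuclear_mask * 255, p[1], 255)
  write_pgm(img$cell_mask * 255, p[2], 255)
  write_pgm(img$dna_channel, p[3])
  write_pgm(img$phospho_channel * 1000, p[4]) # fixed-point x1000
  invisible(p)
}

#' @rdname write_cell_image
#' @export
read_cell_image <- function(dir, prefix = "cell") {
  p <- file.path(dir, paste0(prefix, "_", c("nucmask", "cellmask", "dna", "phospho"), ".pgm"))
  structure(list(nuclear_mask = read_pgm(p[1]) > 0,
                 cell_mask = read_pgm(p[2]) > 0,
                 dna_channel = read_pgm(p[3]),
                 phospho_channel = read_pgm(p[4]) / 1000),
            class = "syn_cell_image")
}
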