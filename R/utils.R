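# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. `seed = NULL` leaves the
# RNG alone (caller controls reproducibility).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, kept < 2^31.
# Arithmetic in doubles: products stay far below 2^53, so this is exact.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

# lognormal draws with unit mean and a given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance over a histogram of the values; used to
#' separate condensed-chromatin (DNA-bright) pixels from the rest of the
#' nucleus.
#'
#' @param x numeric values (e.g. DNA-channel intensities within a mask).
#' @param n_bins histogram resolution.
#' @return the threshold; values strictly above it are "bright".
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to threshold")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + as.integer((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Read / write portable graymap (PGM, P2) rasters
#'
#' Plain-text single-channel raster I/O used for masks and channel images.
#' Values are nonnegative integers; masks use 0/255.
#'
#' @param path file path.
#' @param img numeric matrix (rows = image rows).
#' @param max_val maximum gray value written to the header.
#' @return `read_pgm` returns a numeric matrix.
#' @export
write_pgm <- function(img, path, max_val = max(1, ceiling(max(img)))) {
  stopifnot(is.matrix(img), all(img >= 0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(max_val)), con)
  apply(round(img), 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only plain (P2) PGM supported: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
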