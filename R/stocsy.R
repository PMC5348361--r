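# Statistical total correlation spectroscopy (STOCSY). Resonances of one
# molecule co-vary across samples in proportion to its concentration, so
# their pairwise Pearson correlation is 1 in the noise-free limit; the
# correlation of a driver peak against the whole spectrum therefore lights
# up every resonance of the same molecule and flags close metabolic
# coupling. Computed on normalized (PQN), unscaled buckets: Pearson r is
# unchanged by any subsequent column scaling, and centering is implicit.

driver_bin_index <- function(bucket_table, driver_ppm) {
  edges <- bucket_table$bin_edges
  hit <- which(edges[, "lo"] <= driver_ppm & driver_ppm < edges[, "hi"])
  if (length(hit) == 1L) return(hit)
  for (ex in bucket_table$excluded_regions) {
    abort_if(driver_ppm >= min(ex) && driver_ppm < max(ex),
             "driver %.4f ppm falls in the excluded region %.4g-%.4g",
             driver_ppm, min(ex), max(ex))
  }
  rlang::abort(sprintf("driver %.4f ppm is outside the bucketed range",
                       driver_ppm))
}

#' 1D STOCSY trace from a driver resonance
#'
#' Correlates the bucket containing the driver chemical shift against
#' every bucket across samples, returning per-bucket Pearson correlation
#' and covariance. The requested ppm maps to its containing bin under the
#' half-open `[lo, hi)` convention.
#'
#' @param bucket_table A `bucket_table`, normally PQN-normalized.
#' @param driver_ppm Chemical shift (ppm) of the driver resonance.
#' @return Tibble of class `stocsy_trace`: `ppm`, `r`, `cov`; attributes
#'   `driver_ppm` and `driver_bin`.
#' @export
stocsy_1d <- function(bucket_table, driver_ppm) {
  abort_if(!inherits(bucket_table, "bucket_table"),
           "bucket_table must be a bucket_table")
  x <- bucket_table$matrix
  abort_if(nrow(x) < 3L, "STOCSY needs at least 3 samples, got %d", nrow(x))
  j <- driver_bin_index(bucket_table, driver_ppm)
  d <- x[, j]
  abort_if(stats::sd(d) == 0, "driver bin at %.4f ppm has zero variance",
           driver_ppm)
  sds <- apply(x, 2L, stats::sd)
  r <- rep(NA_real_, ncol(x))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(d, x[, ok, drop = FALSE]))
  cv <- as.numeric(stats::cov(d, x))
  out <- tibble::tibble(ppm = bucket_table$bin_centers, r = r, cov = cv)
  attr(out, "driver_ppm") <- driver_ppm
  attr(out, "driver_bin") <- j
  class(out) <- c("stocsy_trace", class(out))
  out
}

#' Full 2D STOCSY correlation matrix
#'
#' Pairwise Pearson correlation of every bucket with every other; the
#' symmetric, unit-diagonal matrix whose rows reproduce [stocsy_1d()]
#' traces.
#'
#' @param bucket_table A `bucket_table`, normally PQN-normalized.
#' @return Numeric bins x bins correlation matrix (class `stocsy_matrix`)
#'   with the bin centers as dimnames-carrying attribute `ppm`.
#' @export
stocsy_2d <- function(bucket_table) {
  abort_if(!inherits(bucket_table, "bucket_table"),
           "bucket_table must be a bucket_table")
  x <- bucket_table$matrix
  abort_if(nrow(x) < 3L, "STOCSY needs at least 3 samples, got %d", nrow(x))
  m <- suppressWarnings(stats::cor(x))
  diag(m) <- 1
  attr(m, "ppm") <- bucket_table$bin_centers
  class(m) <- c("stocsy_matrix", class(m))
  m
}
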