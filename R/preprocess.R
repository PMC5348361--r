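#' Reference spectra to the TSP singlet at 0.0 ppm
#'
#' Finds the apex of the reference resonance within a window around 0 ppm
#' and re-interpolates each sample onto the shared grid so the apex sits at
#' exactly 0.000 ppm. Samples without a detectable reference peak (window
#' maximum not clearly above the spectrum's median intensity) are flagged
#' and left unshifted.
#'
#' @param spectra An `nmr_spectra` object whose grid covers 0 ppm.
#' @param window Half-width of the search window around 0 ppm.
#' @return The input object with shifted intensities plus a `referencing`
#'   tibble (`sample_id`, `shift_ppm`, `flagged`).
#' @export
reference_to_tsp <- function(spectra, window = 0.1) {
  abort_if(!inherits(spectra, "nmr_spectra"), "spectra must be an nmr_spectra")
  ppm <- spectra$ppm
  abort_if(min(ppm) > -1e-9, "ppm grid does not cover 0 ppm; simulate with include_tsp = TRUE")
  in_win <- which(abs(ppm) <= window)
  n <- nrow(spectra$intensities)
  shifts <- numeric(n)
  flagged <- logical(n)
  asc <- order(ppm)  # approx() needs increasing x
  for (i in seq_len(n)) {
    y <- spectra$intensities[i, ]
    apex_idx <- in_win[which.max(y[in_win])]
    apex <- ppm[apex_idx]
    if (y[apex_idx] <= 3 * stats::median(abs(y)) ||
        apex_idx == min(in_win) || apex_idx == max(in_win)) {
      flagged[i] <- TRUE
      next
    }
    shifts[i] <- -apex
    spectra$intensities[i, ] <- stats::approx(
      x = ppm[asc], y = y[asc], xout = ppm + apex, rule = 2
    )$y
  }
  spectra$referencing <- tibble::tibble(
    sample_id = spectra$samples$sample_id, shift_ppm = shifts, flagged = flagged
  )
  spectra
}

#' Segment spectra into fixed-width integrated buckets
#'
#' Divides the ppm range into contiguous bins of the given width (half-open
#' on the ppm value, `[lo, hi)`), sums the grid intensities falling in each
#' bin and multiplies by the grid spacing so bucket values approximate the
#' integral of the spectrum over the bin. Bins overlapping an excluded
#' region (residual water and exchange-broadened signals) are dropped
#' entirely.
#'
#' The defaults — 0.0025 ppm buckets over 0.2 to 10 ppm — give 3920 bins
#' before exclusion; the cerebrum water exclusion 4.65-5.25 removes 240.
#'
#' @param spectra An `nmr_spectra` object.
#' @param width Bucket width in ppm.
#' @param range Length-2 numeric, low and high ppm bound of the bucketed
#'   region.
#' @param exclude List of length-2 numeric vectors `(lo, hi)` in ppm, or a
#'   single such vector.
#' @return A `bucket_table`: `matrix` (samples x bins, ascending bin
#'   center), `bin_centers`, `bin_edges` (two-column matrix lo/hi),
#'   `excluded_regions`, `samples`.
#' @export
bin_spectra <- function(spectra, width = 0.0025, range = c(0.2, 10),
                        exclude = NULL) {
  abort_if(!inherits(spectra, "nmr_spectra"), "spectra must be an nmr_spectra")
  abort_if(width <= 0, "width must be > 0")
  lo <- min(range); hi <- max(range)
  abort_if(lo >= hi, "range lower bound must be below upper bound")
  if (!is.null(exclude) && !is.list(exclude)) exclude <- list(exclude)
  for (ex in exclude) {
    abort_if(length(ex) != 2L, "each excluded region must be (lo, hi)")
    abort_if(min(ex) < lo - 1e-9 || max(ex) > hi + 1e-9,
             "excluded region %.4g-%.4g lies outside the bucketed range",
             min(ex), max(ex))
  }

  n_bins <- floor((hi - lo) / width + 1e-9)
  edges <- lo + width * (0:n_bins)
  bin_lo <- edges[-(n_bins + 1)]
  bin_hi <- edges[-1]

  idx <- find_bin(spectra$ppm, edges)
  counts <- tabulate(idx, nbins = n_bins)
  if (any(counts == 0L)) {
    b <- which(counts == 0L)[1]
    rlang::abort(sprintf(
      "bin [%.4f, %.4f) contains no grid point; use a coarser width or denser grid",
      bin_lo[b], bin_hi[b]))
  }

  dp <- spectra$grid_spacing %||% abs(spectra$ppm[1] - spectra$ppm[2])
  keep_pt <- !is.na(idx)
  # rowsum over the transposed matrix sums grid points per bin in one pass;
  # every bin is non-empty so rows come back as bin 1..n_bins in order.
  mat <- t(rowsum(t(spectra$intensities[, keep_pt, drop = FALSE]),
                  idx[keep_pt])) * dp
  rownames(mat) <- rownames(spectra$intensities)

  drop <- rep(FALSE, n_bins)
  for (ex in exclude) {
    drop <- drop | (bin_lo < max(ex) & bin_hi > min(ex))
  }
  keep <- which(!drop)
  structure(
    list(
      matrix = mat[, keep, drop = FALSE],
      bin_centers = (bin_lo + bin_hi)[keep] / 2,
      bin_edges = cbind(lo = bin_lo[keep], hi = bin_hi[keep]),
      excluded_regions = exclude %||% list(),
      width = width,
      samples = spectra$samples,
      truth = spectra$truth
    ),
    class = "bucket_table"
  )
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table> %d samples x %d bins (width %g ppm)%s\n",
              nrow(x$matrix), ncol(x$matrix), x$width,
              if (length(x$excluded_regions)) {
                paste0(", excluded: ", paste(
                  vapply(x$excluded_regions,
                         function(e) sprintf("%g-%g", min(e), max(e)), ""),
                  collapse = ", "))
              } else ""))
  invisible(x)
}

#' Probability quotient normalization
#'
#' Corrects per-sample dilution differences. Each spectrum is first
#' total-area normalized; quotients of each bin against a reference
#' spectrum (the median spectrum of the reference group, after total-area
#' normalization) are formed, and the sample is divided by the median
#' quotient. The stored `factor` is the total divisor actually applied
#' (row sum times median quotient), so re-applying PQN to its own output
#' yields factors of exactly 1.
#'
#' @param bucket_table A `bucket_table`.
#' @param reference_group Group label whose samples define the reference
#'   median spectrum, or `"all"` (default) for the whole cohort.
#' @return The bucket table with normalized `matrix` and a `pqn_factors`
#'   tibble (`sample_id`, `area_factor`, `quotient_factor`, `factor`).
#' @export
pqn_normalize <- function(bucket_table, reference_group = "all") {
  abort_if(!inherits(bucket_table, "bucket_table"),
           "bucket_table must be a bucket_table")
  x <- bucket_table$matrix
  abort_if(nrow(x) < 2L, "PQN needs at least 2 samples")
  rs <- unname(rowSums(x))
  abort_if(any(rs == 0), "sample(s) with all-zero spectrum: %s",
           paste(bucket_table$samples$sample_id[rs == 0], collapse = ", "))
  ta <- x / rs

  ref_rows <- if (identical(reference_group, "all")) {
    seq_len(nrow(x))
  } else {
    rows <- which(bucket_table$samples$group == reference_group)
    abort_if(length(rows) == 0L, "reference group '%s' not present",
             reference_group)
    rows
  }
  ref <- apply(ta[ref_rows, , drop = FALSE], 2L, stats::median)
  nz <- ref != 0
  abort_if(!any(nz), "reference median spectrum is all zero")
  quo <- ta[, nz, drop = FALSE] / rep(ref[nz], each = nrow(ta))
  qf <- unname(apply(quo, 1L, stats::median))
  abort_if(any(qf <= 0), "non-positive median quotient encountered")

  bucket_table$matrix <- ta / qf
  bucket_table$pqn_factors <- tibble::tibble(
    sample_id = bucket_table$samples$sample_id,
    area_factor = rs, quotient_factor = qf, factor = rs * qf
  )
  bucket_table$pqn_reference <- ref
  bucket_table
}

#' Mean-center and Pareto-scale a variable matrix
#'
#' Each column is centered and divided by the square root of its sample
#' standard deviation (n - 1 denominator), damping the dominance of intense
#' signals without flattening them to unit variance. Zero-variance columns
#' cannot be scaled and are dropped with a report.
#'
#' @param x A `bucket_table` (its `matrix` is scaled) or a plain numeric
#'   matrix.
#' @return An `nmr_processed` object: `matrix`, `column_means`,
#'   `column_sds`, `dropped_columns` (indices into the input columns),
#'   plus `bin_centers`/`samples`/`pqn_factors` carried over when the input
#'   was a bucket table.
#' @export
center_pareto <- function(x) {
  bt <- NULL
  if (inherits(x, "bucket_table")) {
    bt <- x
    x <- x$matrix
  }
  x <- as.matrix(x)
  abort_if(nrow(x) < 2L, "centering and scaling need at least 2 samples")
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  dropped <- which(sds == 0)
  keep <- which(sds > 0)
  scaled <- sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-")
  scaled <- sweep(scaled, 2L, sqrt(sds[keep]), "/")
  structure(
    list(
      matrix = scaled,
      column_means = mu[keep],
      column_sds = sds[keep],
      dropped_columns = dropped,
      bin_centers = if (!is.null(bt)) bt$bin_centers[keep] else NULL,
      samples = bt$samples,
      pqn_factors = bt$pqn_factors
    ),
    class = "nmr_processed"
  )
}

#' @export
print.nmr_processed <- function(x, ...) {
  cat(sprintf("<nmr_processed> %d samples x %d variables (%d zero-variance dropped)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$dropped_columns)))
  invisible(x)
}
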