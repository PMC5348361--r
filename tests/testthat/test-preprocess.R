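test_that("bucket arithmetic matches hand counts with and without exclusion", {
  sp <- quick_cohort(n = 2, seed = 1, n_points = 16384L)
  bt <- bin_spectra(sp, width = 0.0025, range = c(0.2, 10))
  expect_equal(ncol(bt$matrix), 3920)  # (10 - 0.2) / 0.0025

  btx <- bin_spectra(sp, width = 0.0025, range = c(0.2, 10),
                     exclude = c(4.65, 5.25))
  expect_equal(ncol(btx$matrix), 3680)  # 240 water bins removed
  expect_equal(ncol(bt$matrix) - ncol(btx$matrix), 240)
  expect_false(any(btx$bin_centers > 4.65 & btx$bin_centers < 5.25))

  # serum exclusion, implemented exactly as specified (very wide)
  bts <- bin_spectra(sp, exclude = c(4.70, 9.70))
  expect_equal(ncol(bts$matrix), 3920 - 2000)
})

test_that("bins are ordered, non-overlapping and half-open", {
  sp <- quick_cohort(n = 2, seed = 1, n_points = 16384L)
  bt <- bin_spectra(sp)
  expect_true(all(diff(bt$bin_centers) > 0))
  expect_true(all(bt$bin_edges[, "hi"] - bt$bin_edges[, "lo"] > 0))
  expect_true(all(bt$bin_edges[-1, "lo"] >= bt$bin_edges[-nrow(bt$bin_edges), "hi"] - 1e-12))
})

test_that("a constant spectrum buckets to value x width", {
  ppm <- seq(10, 0.2, length.out = 8192)
  sp <- manual_spectra(matrix(3, 2, 8192), ppm)
  bt <- bin_spectra(sp, width = 0.01)
  # bucket = sum(points) * spacing ~ c * width (grid quantization exact here?)
  counts <- 3 * sp$grid_spacing *
    (0.01 / (3 * sp$grid_spacing)) # analytic c * width
  expect_equal(max(abs(bt$matrix - 3 * 0.01)) < 3 * sp$grid_spacing, TRUE)
  # and total signal is conserved against the direct integral
  in_range <- sp$ppm >= 0.2 & sp$ppm < 0.2 + 980 * 0.01
  direct <- sum(sp$intensities[1, in_range]) * sp$grid_spacing
  expect_equal(sum(bt$matrix[1, ]), direct, tolerance = 1e-9)
})

test_that("bucketing conserves total signal on simulated spectra", {
  sp <- quick_cohort(n = 3, seed = 2, noise_sd = 0.01, n_points = 16384L)
  bt <- bin_spectra(sp)
  edges <- range(bt$bin_edges)
  in_range <- sp$ppm >= edges[1] & sp$ppm < edges[2]
  direct <- rowSums(sp$intensities[, in_range]) * sp$grid_spacing
  expect_equal(unname(rowSums(bt$matrix)), unname(direct), tolerance = 1e-9)
})

test_that("degenerate bucketing inputs are rejected", {
  sp <- quick_cohort(n = 2, seed = 1, n_points = 2048L)
  expect_error(bin_spectra(sp, width = -0.01), "width")
  expect_error(bin_spectra(sp, exclude = c(11, 12)), "outside")
  # a 2048-point grid is too coarse to fill every 0.0025 ppm bin
  expect_error(bin_spectra(sp, width = 0.0025), "no grid point")
})

test_that("PQN undoes a pure scalar difference and stores the factor ratio", {
  ppm <- seq(10, 0.2, length.out = 2048)
  base <- abs(sin(seq_len(2048) / 50)) + 0.5
  sp <- manual_spectra(rbind(base, 3 * base, base / 2), ppm)
  bt <- bin_spectra(sp, width = 0.05)
  nb <- pqn_normalize(bt)
  expect_equal(nb$matrix[1, ], nb$matrix[2, ], tolerance = 1e-12)
  expect_equal(nb$matrix[1, ], nb$matrix[3, ], tolerance = 1e-12)
  expect_equal(nb$pqn_factors$factor[2] / nb$pqn_factors$factor[1], 3,
               tolerance = 1e-12)
})

test_that("PQN is idempotent: second-pass factors are exactly 1", {
  sp <- quick_cohort(n = 4, seed = 8, dilution_log_sd = 0.3, noise_sd = 0.01,
                     n_points = 8192L)
  bt <- bin_spectra(sp, width = 0.01)
  once <- pqn_normalize(bt)
  twice <- pqn_normalize(once)
  expect_equal(twice$matrix, once$matrix, tolerance = 1e-12)
  expect_equal(twice$pqn_factors$factor, rep(1, nrow(bt$matrix)),
               tolerance = 1e-10)
})

test_that("post-PQN rows are invariant to per-sample positive scaling", {
  sp <- quick_cohort(n = 4, seed = 8, noise_sd = 0.01, n_points = 8192L)
  bt <- bin_spectra(sp, width = 0.01)
  bt_scaled <- bt
  bt_scaled$matrix[2, ] <- 17.3 * bt_scaled$matrix[2, ]
  a <- pqn_normalize(bt)
  b <- pqn_normalize(bt_scaled)
  expect_equal(a$matrix, b$matrix, tolerance = 1e-10)
})

test_that("PQN factors recover planted log-normal dilutions", {
  # dilution (log-sd 0.3) dominates per-sample scale; mild biological
  # variation remains, since with ~20 metabolites the median quotient
  # absorbs composition drift of that order into the factor
  sp <- quick_cohort(groups = c("sham", "MCAO"), n = 10, seed = 31,
                     dilution_log_sd = 0.3, conc_log_sd = 0.1,
                     noise_sd = 0, n_points = 8192L)
  bt <- pqn_normalize(bin_spectra(sp, width = 0.01))
  expect_gt(cor(bt$pqn_factors$factor, sp$truth$dilutions), 0.99)
})

test_that("PQN rejects degenerate inputs", {
  ppm <- seq(10, 0.2, length.out = 1024)
  sp <- manual_spectra(rbind(rep(1, 1024), rep(0, 1024)), ppm)
  bt <- bin_spectra(sp, width = 0.1)
  expect_error(pqn_normalize(bt), "all-zero")
  sp2 <- manual_spectra(rbind(rep(1, 1024), rep(2, 1024)), ppm)
  expect_error(pqn_normalize(bin_spectra(sp2, width = 0.1), "nope"),
               "not present")
})

test_that("Pareto scaling matches the hand-worked two-sample column", {
  m <- cbind(a = c(1, 3), b = c(5, 5))
  out <- center_pareto(m)
  # centered {-1, 1}, sd = sqrt(2), scaled by 2^(1/4)
  expect_equal(unname(out$matrix[, "a"]), c(-1, 1) / sqrt(sqrt(2)),
               tolerance = 1e-4)
  expect_equal(abs(unname(out$matrix[1, "a"])), 0.8409, tolerance = 1e-4)
  expect_equal(unname(out$dropped_columns), 2L)  # constant column dropped
})

test_that("Pareto-scaled column variance equals the original sd", {
  sp <- quick_cohort(n = 5, seed = 4, noise_sd = 0.05, n_points = 8192L)
  bt <- pqn_normalize(bin_spectra(sp, width = 0.01))
  out <- center_pareto(bt)
  orig_sd <- apply(bt$matrix, 2, sd)[setdiff(seq_len(ncol(bt$matrix)),
                                             out$dropped_columns)]
  expect_equal(unname(apply(out$matrix, 2, var)), unname(orig_sd),
               tolerance = 1e-10)
  expect_true(all(abs(colMeans(out$matrix)) < 1e-10))
  expect_error(center_pareto(m <- matrix(1, 1, 3)), "2 samples")
})

test_that("TSP referencing shifts the apex to 0 ppm within one grid step", {
  lib <- single_peak_library(center = 3)
  des <- cohort_design(groups = c("a", "b"), n_per_group = 3, seed = 6,
                       conc_log_sd = 0.1)
  sp <- simulate_cohort(des, lib, n_points = 16384L, include_tsp = TRUE,
                        calibration_sd_ppm = 0.02)
  expect_lt(min(sp$ppm), 0)  # grid extended to hold the reference peak
  ref <- reference_to_tsp(sp)
  step <- ref$grid_spacing
  for (i in seq_len(nrow(ref$intensities))) {
    win <- abs(ref$ppm) <= 0.1
    apex <- ref$ppm[win][which.max(ref$intensities[i, win])]
    expect_lt(abs(apex), step + 1e-12)
  }
  # recovered shifts undo the planted calibration offsets
  expect_lt(max(abs(ref$referencing$shift_ppm + sp$truth$calibration)),
            2 * step)
  expect_false(any(ref$referencing$flagged))
})

test_that("already-centered reference gives zero shift; no peak flags sample", {
  lib <- single_peak_library(center = 3)
  des <- cohort_design(groups = c("a", "b"), n_per_group = 2, seed = 6)
  sp <- simulate_cohort(des, lib, n_points = 8192L, include_tsp = TRUE)
  ref <- reference_to_tsp(sp)
  expect_true(all(abs(ref$referencing$shift_ppm) <= ref$grid_spacing))

  # remove the reference peak entirely: sample must be flagged, unshifted
  sp2 <- simulate_cohort(des, lib, n_points = 8192L, include_tsp = FALSE,
                         ppm_range = c(-0.2, 10))
  ref2 <- reference_to_tsp(sp2)
  expect_true(all(ref2$referencing$flagged))
  expect_identical(ref2$intensities, sp2$intensities)
})
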