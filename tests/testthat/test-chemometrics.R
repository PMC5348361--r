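test_that("PCA recovers rank-1 structure and matches the eigen oracle", {
  withr::with_seed(2, {
    u <- rnorm(12); v <- rnorm(8)
    x1 <- tcrossprod(u, v)
    x <- matrix(rnorm(12 * 8), 12, 8)
  })
  p1 <- pca(x1, 1)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-12)

  full <- pca(x, 8)  # column-centered 12 x 8 matrix has rank 8
  xc <- scale(x, scale = FALSE)
  recon <- full$scores %*% t(full$loadings)
  expect_lt(max(abs(xc - recon)), 1e-8)

  ev_oracle <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(full$explained_variance, (ev_oracle / sum(ev_oracle))[1:8],
               tolerance = 1e-10)
  expect_true(all(diff(full$explained_variance) <= 1e-12))
  expect_error(pca(x, 50), "n_components")
})

test_that("OSC scores are orthogonal to every class-indicator column", {
  pm <- planted_matrix(n_per_group = 8, p = 25, shift = 1.5, seed = 3)
  xc <- scale(pm$x, scale = FALSE)
  osc <- osc_filter(xc, pm$groups, n_factors = 2)
  y <- cbind(as.numeric(pm$groups == "a"), as.numeric(pm$groups == "b"))
  for (f in 1:2) {
    t <- osc$scores[, f]
    for (k in 1:2) {
      expect_lt(abs(sum(t * y[, k])) / (sqrt(sum(t^2)) * sqrt(sum(y[, k]^2))),
                1e-6)
    }
  }
  expect_true(all(osc$r2x_removed >= 0 & osc$r2x_removed <= 1))
})

test_that("OSC removes nothing from a matrix that is a pure class function", {
  groups <- rep(c("a", "b"), each = 6)
  y <- as.numeric(groups == "a")
  x <- scale(cbind(2 * y, -y, 3 * y + 1), scale = FALSE)
  osc <- osc_filter(x, groups, n_factors = 1)
  expect_lt(osc$r2x_removed[1], 1e-6)
  expect_equal(osc$x_corrected, x, ignore_attr = TRUE)
})

test_that("OSC recovers a planted class-orthogonal batch direction", {
  n <- 20
  groups <- rep(c("a", "b"), each = n / 2)
  withr::with_seed(7, {
    class_dir <- rnorm(40); batch_dir <- rnorm(40)
  })
  yc <- as.numeric(groups == "a") - 0.5
  batch_score <- rep(c(1, -1), n / 2) * 2      # orthogonal to class by design
  batch_score <- batch_score - mean(batch_score)
  x <- tcrossprod(yc, class_dir) + tcrossprod(batch_score, batch_dir)
  xc <- scale(x, scale = FALSE)
  planted_fraction <- sum(tcrossprod(batch_score, batch_dir)^2) / sum(xc^2)
  osc <- osc_filter(xc, groups, n_factors = 1)
  expect_equal(osc$r2x_removed[1], planted_fraction, tolerance = 0.05)
})

test_that("PLS-DA separates a planted two-group difference perfectly", {
  lib <- tiny_library()
  eff <- tibble::tibble(group = "MCAO", metabolite = "lactate", factor = 3)
  sp <- quick_cohort(n = 6, seed = 13, effects = eff, conc_log_sd = 0.05,
                     n_points = 8192L)
  proc <- center_pareto(pqn_normalize(bin_spectra(sp, width = 0.01)))
  m <- fit_plsda(proc, sp$samples$group, n_components = 2)
  expect_equal(m$accuracy, 1.0)
  t1_sham <- m$scores[sp$samples$group == "sham", 1]
  t1_mcao <- m$scores[sp$samples$group == "MCAO", 1]
  expect_true(max(t1_sham) < min(t1_mcao) || max(t1_mcao) < min(t1_sham))
})

test_that("rank-1 class-correlated X gives an exact one-component fit", {
  groups <- rep(c("a", "b"), each = 4)
  yc <- as.numeric(groups == "a") - 0.5
  withr::with_seed(5, v <- rnorm(10))
  x <- tcrossprod(yc, v)
  m <- fit_plsda(x, groups, n_components = 1)
  expect_equal(tail(m$r2x, 1), 1, tolerance = 1e-8)
  expect_equal(tail(m$r2y, 1), 1, tolerance = 1e-8)
})

test_that("NIPALS scores are mutually orthogonal and weights unit-norm", {
  pm <- planted_matrix(n_per_group = 10, p = 40, shift = 1, seed = 17)
  m <- fit_plsda(scale(pm$x, scale = FALSE), pm$groups, n_components = 2)
  expect_lt(abs(crossprod(m$scores[, 1], m$scores[, 2])), 1e-6)
  expect_equal(unname(colSums(m$weights^2)), rep(1, 2), tolerance = 1e-10)
})

test_that("model fitting is deterministic bitwise under the sign convention", {
  pm <- planted_matrix(seed = 19)
  m1 <- fit_plsda(pm$x, pm$groups, n_components = 2)
  m2 <- fit_plsda(pm$x, pm$groups, n_components = 2)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$weights, m2$weights)
  # largest-|.| weight entry is positive per component
  for (a in 1:2) expect_gt(m1$weights[which.max(abs(m1$weights[, a])), a], 0)
})

test_that("fit guards reject or truncate degenerate requests", {
  pm <- planted_matrix(n_per_group = 3, p = 4, seed = 23)
  expect_error(fit_plsda(pm$x[1:4, ], c("a", "a", "a", "b")), ">= 2 samples")
  expect_warning(fit_plsda(pm$x, pm$groups, n_components = 6), "truncated")
})

test_that("cross-validated Q2 is near zero on noise and high on signal", {
  null <- planted_matrix(n_per_group = 8, p = 20, shift = 0, seed = 29)
  cv_null <- cross_validate(null$x, null$groups, repeats = 50, seed = 1)
  expect_lte(cv_null$q2, 0.05)

  strong <- planted_matrix(n_per_group = 8, p = 20, shift = 5,
                           signal_bins = 1:5, noise_sd = 1, seed = 31)
  cv_sig <- cross_validate(strong$x, strong$groups, repeats = 50, seed = 1)
  expect_gt(cv_sig$q2, 0.9)

  expect_true(all(cv_null$q2_per_repeat <= 1))
  expect_true(all(cv_sig$q2_per_repeat <= 1))
  expect_error(cross_validate(null$x[1:3, ], c("a", "a", "b"), folds = 2),
               "fewer samples than folds")
})

test_that("OSC fitted outside the folds leaks optimism into Q2", {
  # On null data, Q2 with OSC inside each training fold must not exceed
  # Q2 when OSC has already seen the held-out labels (mean over replicates).
  diffs <- vapply(1:50, function(s) {
    null <- planted_matrix(n_per_group = 6, p = 15, shift = 0, seed = 1000 + s)
    proper <- cross_validate(null$x, null$groups, repeats = 2,
                             osc_factors = 1, seed = s)$q2
    xc <- scale(null$x, scale = FALSE)
    leaky_x <- osc_filter(xc, null$groups, n_factors = 1)$x_corrected
    leaky <- cross_validate(leaky_x, null$groups, repeats = 2,
                            osc_factors = 0, seed = s)$q2
    leaky - proper
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("permutation report bookkeeping and p-value formula are exact", {
  sig <- planted_matrix(n_per_group = 6, p = 15, shift = 4, signal_bins = 1:4,
                        seed = 37)
  rep_ <- permutation_test(sig$x, sig$groups, n_perm = 99, seed = 2,
                           repeats = 3)
  expect_equal(nrow(rep_$permuted), 99)
  b_q2 <- sum(rep_$permuted$q2 >= rep_$observed[["q2"]])
  expect_equal(rep_$p_q2, (b_q2 + 1) / 100)
  # strong effect: observed Q2 beats all permutations
  expect_equal(rep_$p_q2, 1 / 100)
  expect_error(permutation_test(sig$x, sig$groups, n_perm = 0), "n_perm")
})

test_that("S-plot values match a brute-force Pearson/covariance oracle", {
  pm <- planted_matrix(n_per_group = 7, p = 12, shift = 1.2, seed = 41)
  xc <- scale(pm$x, scale = FALSE)
  m <- fit_plsda(xc, pm$groups, n_components = 2)
  s <- splot(m, xc)
  t1 <- m$scores[, 1]
  n <- length(t1)
  for (j in seq_len(ncol(xc))) {
    xj <- xc[, j]
    cov_oracle <- sum((t1 - mean(t1)) * (xj - mean(xj))) / (n - 1)
    corr_oracle <- cov_oracle / (sd(t1) * sd(xj))
    expect_equal(s$cov1[j], cov_oracle, tolerance = 1e-10)
    expect_equal(s$corr1[j], corr_oracle, tolerance = 1e-10)
  }
  expect_true(all(abs(s$corr1) <= 1 + 1e-12))
  expect_true(all(sign(s$cov1) == sign(s$corr1) | s$cov1 == 0))
  expect_equal(s$color_value, abs(s$corr1))
})

test_that("a bin copying the first score has corr 1 and cov var(t1)", {
  pm <- planted_matrix(n_per_group = 6, p = 10, shift = 1, seed = 43)
  xc <- scale(pm$x, scale = FALSE)
  m <- fit_plsda(xc, pm$groups, n_components = 1)
  x2 <- cbind(xc, copy = m$scores[, 1])
  s <- splot(m, x2)
  expect_equal(s$corr1[ncol(x2)], 1, tolerance = 1e-12)
  expect_equal(s$cov1[ncol(x2)], var(m$scores[, 1]), tolerance = 1e-12)
})

test_that("back-scaled loadings re-express covariance in pre-Pareto units", {
  sp <- quick_cohort(n = 5, seed = 47, noise_sd = 0.02, n_points = 8192L)
  proc <- center_pareto(pqn_normalize(bin_spectra(sp, width = 0.01)))
  m <- fit_plsda(proc, sp$samples$group, n_components = 2)
  s <- splot(m, proc)
  expect_equal(s$back_scaled_loading, s$cov1 * sqrt(proc$column_sds),
               ignore_attr = TRUE)
})

test_that("planted discriminating bins rank in the top decile of |corr1|", {
  hits <- vapply(1:20, function(s) {
    pm <- planted_matrix(n_per_group = 8, p = 50, shift = 3, noise_sd = 1,
                         signal_bins = 1:2, seed = 500 + s)
    xc <- scale(pm$x, scale = FALSE)
    osc <- osc_filter(xc, pm$groups)
    m <- fit_plsda(osc$x_corrected, pm$groups, n_components = 2)
    sres <- splot(m, xc)
    top <- order(abs(sres$corr1), decreasing = TRUE)[1:5]  # top decile of 50
    all(1:2 %in% top)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
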