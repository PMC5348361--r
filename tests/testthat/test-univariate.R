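make_groups_df <- function(values_by_group) {
  # values_by_group: named list group -> matrix (samples x metabolites)
  purrr::imap_dfr(values_by_group, function(m, g) {
    df <- tibble::as_tibble(m, .name_repair = ~ paste0("m", seq_along(.)))
    df$group <- g
    df
  })
}

test_that("identical groups give fold change exactly 1", {
  m <- matrix(c(1, 2, 3, 4), 4, 2)
  df <- make_groups_df(list(sham = m, MCAO = m))
  out <- fold_change_tests(df, reference = "sham")
  expect_true(all(out$fold_change == 1))
})

test_that("BH adjustment matches the hand-computed step-up", {
  # q_i = min_{j >= i} p_(j) * m / j for p = {0.01, 0.02, 0.04}
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  # and the same numbers flow through the fold-change table
  withr::with_seed(1, {
    base <- matrix(rnorm(30, 10, 1), 10, 3)
    shift <- matrix(rnorm(30, 10, 1), 10, 3)
  })
  df <- make_groups_df(list(sham = base, MCAO = shift))
  out <- fold_change_tests(df, reference = "sham")
  expect_equal(out$q_bh, p.adjust(out$p_raw, "BH"))
  expect_true(all(out$q_bh >= out$p_raw))
  expect_true(all(out$q_bh <= 1))
})

test_that("BH q-values are permutation-invariant and monotone in p", {
  withr::with_seed(4, p <- runif(25))
  q <- p.adjust(p, "BH")
  perm <- sample(25)
  expect_equal(sort(p.adjust(p[perm], "BH")), sort(q))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("planted 2-fold changes are recovered with strong significance", {
  ok <- vapply(1:100, function(s) {
    withr::with_seed(600 + s, {
      ref <- matrix(rnorm(10 * 5, mean = 100, sd = 5), 10, 5)
      trt <- matrix(rnorm(10 * 5, mean = 100, sd = 5), 10, 5)
      trt[, 1] <- rnorm(10, mean = 200, sd = 10)  # 2-fold, 5% noise
    })
    df <- make_groups_df(list(sham = ref, MCAO = trt))
    out <- fold_change_tests(df, reference = "sham")
    row <- out[out$metabolite == "m1", ]
    row$fold_change >= 1.9 && row$fold_change <= 2.1 && row$q_bh < 0.001
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("null data keep the BH false-discovery fraction at or below 0.05", {
  fdr <- vapply(1:20, function(s) {
    withr::with_seed(700 + s, {
      a <- matrix(rnorm(8 * 200), 8, 200)
      b <- matrix(rnorm(8 * 200), 8, 200)
    })
    df <- make_groups_df(list(sham = a, MCAO = b))
    out <- fold_change_tests(df, reference = "sham")
    mean(out$q_bh < 0.05)
  }, numeric(1))
  expect_lte(mean(fdr), 0.05)
})

test_that("stars are a pure function of q with exact boundaries", {
  out <- nmrpls:::stars_from_q(c(0.0009, 0.001, 0.0011, 0.01, 0.011,
                                 0.05, 0.0501, 0.9))
  expect_equal(out, c("***", "***", "**", "**", "*", "*", "", ""))
})

test_that("zero reference mean flags the metabolite instead of failing", {
  df <- tibble::tibble(group = rep(c("sham", "MCAO"), each = 3),
                       m1 = c(0, 0, 0, 1, 2, 3),
                       m2 = c(1, 2, 3, 2, 4, 6))
  out <- fold_change_tests(df, reference = "sham")
  expect_true(out$flagged[out$metabolite == "m1"])
  expect_true(is.na(out$fold_change[out$metabolite == "m1"]))
  expect_false(out$flagged[out$metabolite == "m2"])
})

test_that("z-scores standardize across samples and mirror symmetric groups", {
  withr::with_seed(8, v <- rnorm(12, 5, 2))
  df <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                       m1 = c(v[1:6], -v[1:6] + 2 * mean(c(v[1:6], -v[1:6]))))
  # construct exact mirror: group b = reflection of group a about grand mean
  x <- c(v[1:6], 2 * mean(v[1:6]) - v[1:6])
  df$m1 <- x
  z <- (x - mean(x)) / sd(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  zt <- zscore_table(df)
  expect_equal(zt$mean_z[zt$group == "a"], -zt$mean_z[zt$group == "b"],
               tolerance = 1e-10)
})

test_that("group mean-z equals (group mean - grand mean) / grand sd", {
  withr::with_seed(9, {
    df <- tibble::tibble(group = rep(c("a", "b", "c"), each = 5),
                         m1 = rnorm(15, 3, 2), m2 = rnorm(15))
  })
  zt <- zscore_table(df)
  for (m in c("m1", "m2")) {
    gm <- tapply(df[[m]], df$group, mean)
    oracle <- (gm - mean(df[[m]])) / sd(df[[m]])
    got <- zt$mean_z[zt$metabolite == m][match(names(gm),
                                               zt$group[zt$metabolite == m])]
    expect_equal(unname(got), as.numeric(oracle), tolerance = 1e-10)
  }
  # zero-variance metabolite flagged as NA
  df$m3 <- 1
  expect_true(all(is.na(zscore_table(df)$mean_z[
    zscore_table(df)$metabolite == "m3"])))
})

test_that("ANOVA F matches the sums-of-squares oracle", {
  withr::with_seed(10, {
    df <- tibble::tibble(group = rep(c("a", "b", "c"), times = c(5, 7, 6)),
                         p1 = rnorm(18, rep(c(0, 1, 0.5), c(5, 7, 6))))
  })
  res <- anova_tukey(df)
  g <- df$group; v <- df$p1
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / 2) / (ssw / (18 - 3))
  expect_equal(res$omnibus$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)
})

test_that("two-group Tukey collapses to the pooled-variance t-test", {
  withr::with_seed(11, {
    df <- tibble::tibble(group = rep(c("a", "b"), c(6, 8)),
                         p1 = rnorm(14, rep(c(0, 0.8), c(6, 8))))
  })
  res <- anova_tukey(df)
  tt <- t.test(p1 ~ group, data = df, var.equal = TRUE)
  expect_equal(res$pairwise$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("identical groups give zero F numerator and p of 1", {
  block <- c(1, 2, 3, 4)
  df <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                       p1 = rep(block, 3))
  res <- anova_tukey(df)
  expect_equal(unname(res$pairwise$estimate), rep(0, 3))
  expect_true(all(res$pairwise$p_adj > 0.999))
  expect_error(anova_tukey(tibble::tibble(group = c("a", "a", "b"),
                                          p1 = 1:3)),
               "single sample")
})

test_that("2^-ddCT worked cases are exact", {
  ct <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    group = c("ctrl", "ctrl", "trt", "trt"),
    Actb = c(15, 15, 15, 15),
    Nrf2 = c(20, 20, 19, 23.3219)
  )
  out <- ddct(ct, "Nrf2", "Actb", "ctrl")
  # control samples sit at the control mean: relative expression 1
  expect_equal(out$rel_expr[out$group == "ctrl"], c(1, 1))
  # ddCT = -1 doubles expression
  expect_equal(out$rel_expr[out$sample_id == "s3"], 2)
  # ddCT = 3.3219 gives 0.1000
  expect_equal(out$rel_expr[out$sample_id == "s4"], 0.1, tolerance = 1e-4)

  ct$Nrf2[2] <- NA
  expect_warning(out2 <- ddct(ct, "Nrf2", "Actb", "ctrl"), "missing CT")
  expect_equal(nrow(out2), 3)
})
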