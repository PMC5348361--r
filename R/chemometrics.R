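# Multivariate core: PCA, orthogonal signal correction, NIPALS PLS-DA,
# repeated two-fold cross-validation, permutation testing and the S-plot.

as_matrix_input <- function(x) {
  if (inherits(x, "nmr_processed")) x$matrix
  else if (inherits(x, "bucket_table")) x$matrix
  else as.matrix(x)
}

#' Principal component analysis of a processed matrix
#'
#' Thin wrapper over the singular-value decomposition of the column-centered
#' matrix, returning scores, loadings and explained-variance fractions.
#'
#' @param x An `nmr_processed` object or numeric matrix (samples x
#'   variables).
#' @param n_components Number of components to return.
#' @return A list of class `nmr_pca`: `scores`, `loadings`,
#'   `explained_variance` (fractions, non-increasing), `center`.
#' @export
pca <- function(x, n_components = 2L) {
  x <- as_matrix_input(x)
  maxc <- min(nrow(x) - 1L, ncol(x))
  abort_if(n_components < 1L || n_components > maxc,
           "n_components must be in 1..%d, got %s", maxc, n_components)
  ctr <- center_cols(x)
  sv <- svd(ctr$x)
  ev <- sv$d^2 / sum(sv$d^2)
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components)
  loadings <- sv$v[, k, drop = FALSE]
  for (a in k) {
    s <- sign_fix(loadings[, a])
    loadings[, a] <- s * loadings[, a]
    scores[, a] <- s * scores[, a]
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[k], center = ctr$means),
            class = "nmr_pca")
}

# Projection of t onto the orthogonal complement of the columns of Y.
orth_to <- function(t, y) {
  t - y %*% solve(crossprod(y), crossprod(y, t))
}

#' Orthogonal signal correction (OSC) filtering
#'
#' Removes from the data matrix components that are mathematically
#' orthogonal to the class structure (instrumental or physiological
#' variation unrelated to group membership). Uses the NIPALS-style
#' iteration: start from the first principal-component score,
#' orthogonalize it against the class-indicator matrix, regress the data
#' onto the orthogonalized score to get a weight vector, recompute the
#' score, and repeat to convergence; the converged orthogonal component is
#' then deflated from the matrix. Removing a single factor is the usual
#' conservative choice — each factor removed increases the risk of
#' overfitting downstream models.
#'
#' @param x Centered matrix or `nmr_processed` object.
#' @param groups Class labels, length `nrow(x)`.
#' @param n_factors Number of orthogonal factors to remove.
#' @param tol Relative score-change convergence tolerance.
#' @param max_iter Iteration cap per factor; non-convergence is an error
#'   reporting the iteration count and last relative change.
#' @return An `osc_model`: `x_corrected`, `scores`, `loadings`, `weights`,
#'   `r2x_removed` (fraction of total variance removed per factor),
#'   `groups`.
#' @export
osc_filter <- function(x, groups, n_factors = 1L, tol = 1e-8,
                       max_iter = 500L) {
  x <- as_matrix_input(x)
  abort_if(length(groups) != nrow(x), "groups length must match rows of x")
  y <- dummy_matrix(groups)
  abort_if(n_factors < 0L, "n_factors must be >= 0")
  x0 <- x
  ss0 <- sum(x^2)
  n <- nrow(x); p <- ncol(x)
  scores <- matrix(0, n, n_factors)
  loadings <- matrix(0, p, n_factors)
  weights <- matrix(0, p, n_factors)
  r2x_removed <- numeric(n_factors)

  for (f in seq_len(n_factors)) {
    # The iteration's fixed point is the leading right singular vector of
    # the class-orthogonalized matrix P X; starting there, the orthogonalize/
    # regress loop below verifies convergence in a step or two instead of
    # grinding through a slow power iteration when the spectrum is flat.
    xp <- x - y %*% solve(crossprod(y), crossprod(y, x))
    sv <- svd(xp, nu = 0L, nv = 1L)
    if (sv$d[1L] < 1e-10 * sqrt(max(ss0, 1e-300))) {
      r2x_removed[f] <- 0
      next
    }
    t <- as.numeric(x %*% sv$v[, 1L])
    t_scale <- sqrt(sum(t^2))
    converged <- FALSE
    delta <- NA_real_
    null_factor <- FALSE
    for (it in seq_len(max_iter)) {
      t_orth <- orth_to(t, y)
      if (sqrt(sum(t_orth^2)) < 1e-12 * max(t_scale, 1e-300)) {
        null_factor <- TRUE
        break
      }
      w <- crossprod(x, t_orth)
      w <- w / sqrt(sum(w^2))
      t_new <- x %*% w
      delta <- sqrt(sum((t_new - t)^2)) / sqrt(sum(t_new^2))
      t <- as.numeric(t_new)
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (null_factor) {
      r2x_removed[f] <- 0
      next
    }
    abort_if(!converged,
             "OSC factor %d did not converge in %d iterations (last relative change %.3g)",
             f, max_iter, delta)
    # final orthogonalization guarantees exact orthogonality to every class
    # indicator column before deflation
    t <- as.numeric(orth_to(t, y))
    pl <- as.numeric(crossprod(x, t)) / sum(t^2)
    s <- sign_fix(pl)
    t <- s * t; pl <- s * pl; w <- s * w
    x <- x - tcrossprod(t, pl)
    scores[, f] <- t
    loadings[, f] <- pl
    weights[, f] <- as.numeric(w)
    r2x_removed[f] <- sum(tcrossprod(t, pl)^2) / ss0
  }
  structure(list(x_corrected = x, scores = scores, loadings = loadings,
                 weights = weights, r2x_removed = r2x_removed,
                 groups = groups, ss0 = ss0, x_original = x0),
            class = "osc_model")
}

#' Apply a fitted OSC filter to new samples
#'
#' Projects new (identically preprocessed and centered) samples onto the
#' stored orthogonal weight vectors and deflates the corresponding
#' component, as done for the training data.
#'
#' @param model An `osc_model`.
#' @param newdata Matrix with the same columns as the training data.
#' @return The corrected matrix.
#' @export
osc_apply <- function(model, newdata) {
  x <- as_matrix_input(newdata)
  abort_if(ncol(x) != nrow(model$loadings),
           "newdata has %d columns, model expects %d",
           ncol(x), nrow(model$loadings))
  for (f in seq_len(ncol(model$weights))) {
    w <- model$weights[, f]
    if (all(w == 0)) next
    t_new <- x %*% w
    x <- x - tcrossprod(as.numeric(t_new), model$loadings[, f])
  }
  x
}

# Lean NIPALS PLS2 on pre-built matrices; everything else wraps this.
plsda_core <- function(x, y, ncomp, tol = 1e-10, max_iter = 500L) {
  xc <- center_cols(x)
  yc <- center_cols(y)
  X <- xc$x; Y <- yc$x
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  maxcomp <- min(n - 1L, p)
  truncated <- FALSE
  if (ncomp > maxcomp) {
    ncomp <- maxcomp
    truncated <- TRUE
  }
  Tm <- matrix(0, n, ncomp); W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp); C <- matrix(0, q, ncomp)
  r2x <- numeric(ncomp); r2y <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    if (sum(X^2) < 1e-12 * max(ssx0, 1e-300) ||
        sum(Y^2) < 1e-14 * max(ssy0, 1e-300)) {
      truncated <- TRUE
      break
    }
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- as.numeric(crossprod(X, u)) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t <- as.numeric(X %*% w)
      cc <- as.numeric(crossprod(Y, t)) / sum(t^2)
      u <- as.numeric(Y %*% cc) / sum(cc^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    s <- sign_fix(w)
    w <- s * w; t <- s * t; cc <- s * cc
    pl <- as.numeric(crossprod(X, t)) / sum(t^2)
    X <- X - tcrossprod(t, pl)
    Y <- Y - tcrossprod(t, cc)
    used <- used + 1L
    Tm[, a] <- t; W[, a] <- w; P[, a] <- pl; C[, a] <- cc
    r2x[a] <- 1 - sum(X^2) / ssx0
    r2y[a] <- 1 - sum(Y^2) / ssy0
  }
  k <- seq_len(used)
  list(scores = Tm[, k, drop = FALSE], weights = W[, k, drop = FALSE],
       x_loadings = P[, k, drop = FALSE], y_weights = C[, k, drop = FALSE],
       r2x = r2x[k], r2y = r2y[k], n_components = used,
       x_means = xc$means, y_means = yc$means, truncated = truncated)
}

plsda_coef <- function(fit) {
  # regression coefficients B such that Yhat = (X - x_means) B + y_means
  W <- fit$weights; P <- fit$x_loadings; C <- fit$y_weights
  W %*% solve(crossprod(P, W), t(C))
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares regression against a centered class-indicator
#' (dummy) matrix, fitted component-wise by NIPALS with deflation of both
#' blocks by the X-score. A deterministic sign convention (largest-|.|
#' weight entry positive) makes repeated fits comparable bitwise.
#'
#' With `n_components = "auto"`, components are added while cross-validated
#' Q2 improves by more than 0.01, up to 5.
#'
#' @param x Matrix or `nmr_processed` (samples x variables), typically
#'   OSC-corrected.
#' @param groups Class labels; every class needs at least 2 samples.
#' @param n_components Integer, or `"auto"`.
#' @param cv_seed Seed for the fold shuffling used by `"auto"` selection.
#' @return A `plsda_model`: `scores`, `weights`, `x_loadings`, `y_weights`,
#'   cumulative `r2x` and `r2y`, `groups`, `levels`, centering vectors,
#'   training `fitted_classes` and `accuracy`.
#' @export
fit_plsda <- function(x, groups, n_components = 2L, cv_seed = 1L) {
  x <- as_matrix_input(x)
  abort_if(length(groups) != nrow(x), "groups length must match rows of x")
  tab <- table(groups)
  abort_if(any(tab < 2L), "every group needs >= 2 samples (offending: %s)",
           paste(names(tab)[tab < 2L], collapse = ", "))
  y <- dummy_matrix(groups)

  if (identical(n_components, "auto")) {
    best_q2 <- -Inf
    n_components <- 1L
    for (a in 1:5) {
      q2a <- cross_validate(x, groups, n_components = a, osc_factors = 0L,
                            seed = cv_seed)$q2
      if (q2a > best_q2 + 0.01) {
        best_q2 <- q2a
        n_components <- a
      } else {
        break
      }
    }
  }
  abort_if(!is.numeric(n_components) || n_components < 1L,
           "n_components must be a positive integer or 'auto'")

  fit <- plsda_core(x, y, as.integer(n_components))
  if (fit$truncated) {
    rlang::warn(sprintf("component count truncated to %d (rank limit)",
                        fit$n_components))
  }
  B <- plsda_coef(fit)
  yhat <- sweep(x, 2L, fit$x_means, "-") %*% B
  yhat <- sweep(yhat, 2L, fit$y_means, "+")
  lv <- colnames(y)
  fitted_classes <- lv[max.col(yhat, ties.method = "first")]
  structure(
    c(fit,
      list(groups = groups, levels = lv, coefficients = B,
           fitted_classes = fitted_classes,
           accuracy = mean(fitted_classes == as.character(groups)),
           q2 = NA_real_)),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "<plsda_model> %d components, %d classes | R2X %.3f, R2Y %.3f%s, training accuracy %.3f\n",
    x$n_components, length(x$levels),
    utils::tail(x$r2x, 1), utils::tail(x$r2y, 1),
    if (is.finite(x$q2)) sprintf(", Q2 %.3f", x$q2) else "",
    x$accuracy))
  invisible(x)
}

#' Predict classes for new samples from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Matrix with the training columns.
#' @param ... Unused.
#' @return Tibble with predicted dummy values per class and the `.class`
#'   column (largest predicted indicator).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  x <- as_matrix_input(newdata)
  yhat <- sweep(x, 2L, object$x_means, "-") %*% object$coefficients
  yhat <- sweep(yhat, 2L, object$y_means, "+")
  colnames(yhat) <- object$levels
  out <- tibble::as_tibble(yhat)
  out$.class <- object$levels[max.col(yhat, ties.method = "first")]
  out
}

# Stratified fold assignment: within each group, shuffle then deal folds.
stratified_folds <- function(groups, folds) {
  assign <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    abort_if(length(idx) < folds,
             "group '%s' has %d samples, fewer than %d folds",
             g, length(idx), folds)
    assign[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
  }
  assign
}

#' Repeated stratified k-fold cross-validation of OSC-PLS-DA
#'
#' The full modelling chain — centering, optional OSC filtering, PLS-DA —
#' is refit inside every training fold; the held-out samples are corrected
#' with the training-fold OSC filter and predicted. Q2 is
#' `1 - PRESS / SS` over the held-out dummy matrix, pooled over folds and
#' averaged over repeats; repeating the two-fold split damps the variance
#' of any single random split. R2Y is taken from the fit on all samples.
#'
#' @param x Matrix or `nmr_processed`.
#' @param groups Class labels; every group needs at least `folds` samples.
#' @param folds Number of folds (default 2).
#' @param repeats Number of random fold splits to average (default 50).
#' @param osc_factors OSC factors removed inside each training fold.
#' @param n_components PLS components.
#' @param seed Seed for the fold shuffling.
#' @return List of class `plsda_cv`: `r2y`, `q2` (mean over repeats),
#'   `q2_per_repeat`.
#' @export
cross_validate <- function(x, groups, folds = 2L, repeats = 50L,
                           osc_factors = 1L, n_components = 2L, seed = 1L) {
  x <- as_matrix_input(x)
  groups <- as.character(groups)
  y <- dummy_matrix(groups)
  n <- nrow(x)
  abort_if(min(table(groups)) < folds,
           "smallest group (%d) has fewer samples than folds (%d)",
           min(table(groups)), folds)

  full <- fit_pipeline_once(x, groups, osc_factors, n_components)
  q2_rep <- numeric(repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_of <- stratified_folds(groups, folds)
      press <- 0; ss <- 0
      for (k in seq_len(folds)) {
        tr <- fold_of != k
        xt <- x[tr, , drop = FALSE]
        ctr <- center_cols(xt)
        xt <- ctr$x
        xv <- sweep(x[!tr, , drop = FALSE], 2L, ctr$means, "-")
        if (osc_factors > 0L) {
          osc <- osc_filter(xt, groups[tr], n_factors = osc_factors)
          xt <- osc$x_corrected
          xv <- osc_apply(osc, xv)
        }
        fit <- plsda_core(xt, y[tr, , drop = FALSE], n_components)
        B <- plsda_coef(fit)
        yhat <- sweep(xv, 2L, fit$x_means, "-") %*% B
        yhat <- sweep(yhat, 2L, fit$y_means, "+")
        resid <- y[!tr, , drop = FALSE] - yhat
        press <- press + sum(resid^2)
        ss <- ss + sum(sweep(y[!tr, , drop = FALSE], 2L,
                             colMeans(y[tr, , drop = FALSE]), "-")^2)
      }
      q2_rep[r] <- 1 - press / ss
    }
  })
  structure(list(r2y = full$r2y, q2 = mean(q2_rep), q2_per_repeat = q2_rep),
            class = "plsda_cv")
}

# One full modelling pass (center + optional OSC + PLS-DA) on all samples.
fit_pipeline_once <- function(x, groups, osc_factors, n_components) {
  ctr <- center_cols(x)
  xm <- ctr$x
  if (osc_factors > 0L) {
    xm <- osc_filter(xm, groups, n_factors = osc_factors)$x_corrected
  }
  fit <- plsda_core(xm, dummy_matrix(groups), n_components)
  list(r2y = utils::tail(fit$r2y, 1), r2x = utils::tail(fit$r2x, 1))
}

#' Permutation test of OSC-PLS-DA model validity
#'
#' Class labels are permuted and the entire modelling chain — OSC
#' filtering (which uses the labels and must therefore be rerun under each
#' permutation), PLS-DA and cross-validated Q2 — is recomputed each time.
#' Empirical p-values use the add-one estimator `(b + 1) / (n_perm + 1)`
#' where `b` counts permuted statistics at least as large as the observed.
#'
#' @param x Matrix or `nmr_processed`.
#' @param groups Class labels.
#' @param n_perm Number of label permutations (2000 for a final model;
#'   smaller values are fine for exploration).
#' @param seed Seed controlling permutations and fold shuffles.
#' @param folds,repeats,osc_factors,n_components Passed to the modelling
#'   chain; `repeats` here is per permutation, so modest values keep the
#'   test affordable.
#' @return A `perm_report`: `n_perm`, `observed` (r2y, q2), `permuted`
#'   tibble, `p_r2y`, `p_q2`.
#' @export
permutation_test <- function(x, groups, n_perm = 2000L, seed = 1L,
                             folds = 2L, repeats = 5L, osc_factors = 1L,
                             n_components = 2L) {
  abort_if(n_perm < 1L, "n_perm must be >= 1")
  x <- as_matrix_input(x)
  groups <- as.character(groups)
  seeds <- child_seeds(seed, n_perm + 1L)
  obs_cv <- cross_validate(x, groups, folds = folds, repeats = repeats,
                           osc_factors = osc_factors,
                           n_components = n_components, seed = seeds[1L])
  perm <- matrix(NA_real_, n_perm, 2L,
                 dimnames = list(NULL, c("r2y", "q2")))
  for (b in seq_len(n_perm)) {
    pg <- with_seed(seeds[b + 1L], sample(groups))
    cv <- cross_validate(x, pg, folds = folds, repeats = repeats,
                         osc_factors = osc_factors,
                         n_components = n_components, seed = seeds[b + 1L])
    perm[b, ] <- c(cv$r2y, cv$q2)
  }
  p_r2y <- (sum(perm[, "r2y"] >= obs_cv$r2y) + 1) / (n_perm + 1)
  p_q2 <- (sum(perm[, "q2"] >= obs_cv$q2) + 1) / (n_perm + 1)
  structure(
    list(n_perm = n_perm,
         observed = c(r2y = obs_cv$r2y, q2 = obs_cv$q2),
         permuted = tibble::as_tibble(perm),
         p_r2y = p_r2y, p_q2 = p_q2),
    class = "perm_report"
  )
}

#' @export
print.perm_report <- function(x, ...) {
  cat(sprintf(
    "<perm_report> %d permutations | observed R2Y %.3f (p = %.4g), Q2 %.3f (p = %.4g)\n",
    x$n_perm, x$observed["r2y"], x$p_r2y, x$observed["q2"], x$p_q2))
  invisible(x)
}

#' S-plot: covariance vs correlation of variables with the first score
#'
#' For every variable, the covariance and Pearson correlation with the
#' first PLS-DA score are computed across samples. Variables in the upper
#' right or lower left of the covariance/correlation plane, far from the
#' origin, are the reliable class discriminators; `|corr1|` doubles as the
#' color scale of the correlation-colored loading (pseudo-spectrum) plot.
#' The back-scaled loading re-expresses the covariance in pre-Pareto units
#' by multiplying with the square root of each variable's original
#' standard deviation.
#'
#' @param model A fitted `plsda_model`.
#' @param x The `nmr_processed` object (or matrix) the model was fitted
#'   on; an `nmr_processed` input supplies the per-variable sds used for
#'   back-scaling and the ppm axis.
#' @return A tibble of class `splot_result`: `variable`, `ppm` (if known),
#'   `cov1`, `corr1`, `color_value`, `back_scaled_loading`.
#' @export
splot <- function(model, x) {
  abort_if(!inherits(model, "plsda_model"), "model must be a plsda_model")
  sds <- if (inherits(x, "nmr_processed")) x$column_sds else NULL
  ppm <- if (inherits(x, "nmr_processed")) x$bin_centers else NULL
  xm <- as_matrix_input(x)
  t1 <- model$scores[, 1L]
  abort_if(stats::sd(t1) == 0, "first score has zero variance")
  cov1 <- as.numeric(stats::cov(t1, xm))
  corr1 <- as.numeric(stats::cor(t1, xm))
  out <- tibble::tibble(
    variable = colnames(xm) %||% seq_len(ncol(xm)),
    ppm = if (is.null(ppm)) NA_real_ else ppm,
    cov1 = cov1,
    corr1 = corr1,
    color_value = abs(corr1),
    back_scaled_loading = if (is.null(sds)) cov1 else cov1 * sqrt(sds)
  )
  class(out) <- c("splot_result", class(out))
  out
}
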