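# Sparse PLS in canonical mode linking metabolite concentrations (X) to
# phenotype parameters (Y), and extraction of the thresholded bipartite
# relevance network.

# Keep the `keep` largest-|.| entries, soft-thresholding by the largest
# discarded magnitude so retained entries shrink toward zero continuously.
soft_keep <- function(v, keep) {
  if (keep >= length(v)) return(v)
  cut <- sort(abs(v), decreasing = TRUE)[keep + 1L]
  out <- sign(v) * pmax(abs(v) - cut, 0)
  # ties at the cutoff could retain fewer than `keep`; break ties by index
  if (sum(out != 0) < keep) {
    ord <- order(abs(v), decreasing = TRUE)
    need <- setdiff(ord[seq_len(keep)], which(out != 0))
    out[need] <- sign(v[need]) * 1e-12
  }
  out
}

scale_unit <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  abort_if(any(sds == 0), "zero-variance column(s): %s",
           paste(colnames(x)[sds == 0], collapse = ", "))
  list(x = sweep(sweep(x, 2L, mu, "-"), 2L, sds, "/"), means = mu, sds = sds)
}

numeric_block <- function(data, what) {
  if (is.data.frame(data)) {
    keep <- setdiff(names(data), c("sample_id", "group"))
    num <- keep[vapply(data[keep], is.numeric, logical(1))]
    abort_if(length(num) == 0L, "%s block has no numeric columns", what)
    m <- as.matrix(data[num])
    rownames(m) <- if ("sample_id" %in% names(data)) data$sample_id else NULL
    m
  } else {
    as.matrix(data)
  }
}

#' Sparse PLS (canonical mode) between metabolites and phenotypes
#'
#' NIPALS-style alternating regression with soft-thresholded loading
#' vectors: per component only the `keepX` (`keepY`) largest-magnitude X
#' (Y) loading entries stay nonzero, yielding variable-selected canonical
#' variates. Both blocks are unit-variance scaled first (the phenotype
#' panel mixes scores, activities and densities on incomparable units).
#' Canonical-mode deflation regresses each block on its own variate.
#'
#' @param x Metabolite block: data frame (numeric columns; `sample_id` /
#'   `group` ignored) or matrix, samples x metabolites.
#' @param y Phenotype block, same samples and row order.
#' @param n_components Number of components.
#' @param keepX,keepY Number of nonzero loading entries per component
#'   (defaults: 25 or all X columns if fewer; all Y columns).
#' @return An `spls_model`: sparse `x_loadings` / `y_loadings`,
#'   `x_variates` / `y_variates`, scaled data blocks, `keepX`, `keepY`.
#' @export
fit_spls <- function(x, y, n_components = 3L, keepX = NULL, keepY = NULL) {
  xm <- numeric_block(x, "X")
  ym <- numeric_block(y, "Y")
  abort_if(nrow(xm) != nrow(ym), "X has %d samples but Y has %d",
           nrow(xm), nrow(ym))
  if (!is.null(rownames(xm)) && !is.null(rownames(ym))) {
    abort_if(!identical(rownames(xm), rownames(ym)),
             "X and Y sample ids do not match")
  }
  keepX <- keepX %||% min(25L, ncol(xm))
  keepY <- keepY %||% ncol(ym)
  abort_if(keepX < 1L || keepY < 1L, "keepX and keepY must be >= 1")
  abort_if(keepX > ncol(xm), "keepX (%d) exceeds X columns (%d)", keepX, ncol(xm))
  abort_if(keepY > ncol(ym), "keepY (%d) exceeds Y columns (%d)", keepY, ncol(ym))
  n_components <- min(n_components, nrow(xm) - 1L, ncol(xm), ncol(ym))

  sx <- scale_unit(xm); sy <- scale_unit(ym)
  X <- sx$x; Y <- sy$x
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  A <- matrix(0, p, n_components); B <- matrix(0, q, n_components)
  Tm <- matrix(0, n, n_components); U <- matrix(0, n, n_components)
  for (h in seq_len(n_components)) {
    M <- crossprod(X, Y)
    sv <- svd(M, nu = 1L, nv = 1L)
    a <- sv$u[, 1L]; b <- sv$v[, 1L]
    for (it in 1:500) {
      a_new <- soft_keep(as.numeric(M %*% b), keepX)
      a_new <- a_new / sqrt(sum(a_new^2))
      b_new <- soft_keep(as.numeric(crossprod(M, a_new)), keepY)
      b_new <- b_new / sqrt(sum(b_new^2))
      if (sqrt(sum((a_new - a)^2)) < 1e-10 && sqrt(sum((b_new - b)^2)) < 1e-10) {
        a <- a_new; b <- b_new
        break
      }
      a <- a_new; b <- b_new
    }
    # (a, b) and (-a, -b) are the same model; flipping one side alone would
    # anti-align the paired variates, so the convention flips them jointly
    s <- sign_fix(a)
    a <- s * a; b <- s * b
    t <- as.numeric(X %*% a); u <- as.numeric(Y %*% b)
    # canonical-mode deflation: each block on its own variate
    X <- X - tcrossprod(t, as.numeric(crossprod(X, t)) / sum(t^2))
    Y <- Y - tcrossprod(u, as.numeric(crossprod(Y, u)) / sum(u^2))
    A[, h] <- a; B[, h] <- b; Tm[, h] <- t; U[, h] <- u
  }
  rownames(A) <- colnames(xm); rownames(B) <- colnames(ym)
  structure(
    list(x_loadings = A, y_loadings = B, x_variates = Tm, y_variates = U,
         x_scaled = sx$x, y_scaled = sy$x, keepX = keepX, keepY = keepY,
         n_components = n_components,
         x_names = colnames(xm), y_names = colnames(ym)),
    class = "spls_model"
  )
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("<spls_model> %d components, keepX = %d / %d, keepY = %d / %d\n",
              x$n_components, x$keepX, length(x$x_names),
              x$keepY, length(x$y_names)))
  invisible(x)
}

#' Bipartite metabolite-phenotype association network from an sPLS model
#'
#' Pairwise similarity between metabolite j and parameter k is the sum
#' over components of the products of their correlations with the averaged
#' latent variate `z_h = (t_h + u_h) / 2` — the standard relevance-network
#' construction for two-block PLS. Values are clipped to `[-1, 1]` (clip
#' events are counted and should be zero in practice) and pairs with
#' `|similarity|` above the threshold become edges, colored by sign when
#' plotted.
#'
#' @param model A fitted `spls_model`.
#' @param threshold Absolute-similarity edge threshold in `[0, 1]`
#'   (default 0.8).
#' @param keep_isolates Keep nodes without any edge in the node table?
#' @return An `association_network`: `nodes` tibble (`name`, `type`),
#'   `edges` tibble (`from` metabolite, `to` parameter, `weight`),
#'   `threshold`, `similarity` matrix, `n_clipped`.
#' @export
similarity_network <- function(model, threshold = 0.8, keep_isolates = FALSE) {
  abort_if(!inherits(model, "spls_model"), "model must be an spls_model")
  abort_if(threshold < 0 || threshold > 1, "threshold must be in [0, 1]")
  H <- model$n_components
  sim <- matrix(0, length(model$x_names), length(model$y_names),
                dimnames = list(model$x_names, model$y_names))
  for (h in seq_len(H)) {
    z <- (model$x_variates[, h] + model$y_variates[, h]) / 2
    cx <- as.numeric(stats::cor(model$x_scaled, z))
    cy <- as.numeric(stats::cor(model$y_scaled, z))
    sim <- sim + tcrossprod(cx, cy)
  }
  n_clipped <- sum(abs(sim) > 1)
  sim_clipped <- pmin(pmax(sim, -1), 1)

  hit <- which(abs(sim_clipped) > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = model$x_names[hit[, 1L]],
    to = model$y_names[hit[, 2L]],
    weight = sim_clipped[hit]
  ) |>
    dplyr::arrange(.data$from, .data$to)
  node_names <- if (keep_isolates) {
    c(model$x_names, model$y_names)
  } else {
    c(intersect(model$x_names, edges$from),
      intersect(model$y_names, edges$to))
  }
  nodes <- tibble::tibble(
    name = node_names,
    type = ifelse(node_names %in% model$x_names, "metabolite", "parameter")
  )
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         similarity = sim_clipped, n_clipped = n_clipped),
    class = "association_network"
  )
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("<association_network> %d nodes, %d edges (|similarity| > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Write an association network as edge-list and node-table files
#'
#' Tab-delimited, deterministically ordered (edges by metabolite then
#' parameter name, lexicographic), weights at 6 decimals. A write/read
#' round trip reproduces the edge multiset exactly.
#'
#' @param network An `association_network`.
#' @param path Directory (created if needed) receiving `edges.tsv` and
#'   `nodes.tsv`.
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(network, path) {
  abort_if(!inherits(network, "association_network"),
           "network must be an association_network")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  abort_if(!ok, "cannot create or write to directory '%s'", path)
  edges <- dplyr::arrange(network$edges, .data$from, .data$to)
  edges$weight <- sprintf("%.6f", edges$weight)
  ef <- file.path(path, "edges.tsv")
  nf <- file.path(path, "nodes.tsv")
  utils::write.table(edges, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$nodes, nf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = ef, nodes = nf))
}

#' Read an association network written by [export_network()]
#'
#' @param path Directory containing `edges.tsv` and `nodes.tsv`.
#' @param threshold Threshold recorded on the reconstructed object.
#' @return An `association_network` (without the similarity matrix).
#' @export
read_network <- function(path, threshold = 0.8) {
  ef <- file.path(path, "edges.tsv")
  nf <- file.path(path, "nodes.tsv")
  abort_if(!file.exists(ef) || !file.exists(nf),
           "'%s' does not contain edges.tsv and nodes.tsv", path)
  edges <- tibble::as_tibble(utils::read.delim(ef, colClasses =
    c(from = "character", to = "character", weight = "numeric")))
  nodes <- tibble::as_tibble(utils::read.delim(nf, colClasses = "character"))
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 similarity = NULL, n_clipped = NA_integer_),
            class = "association_network")
}
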