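# broom-style tidy()/glance() methods and ggplot2 autoplot() methods for
# every fitted result type.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy plsda_model
#' @export
tidy.plsda_model <- function(x, ...) {
  scores <- tibble::as_tibble(x$scores, .name_repair = ~ paste0("t", seq_along(.)))
  dplyr::bind_cols(tibble::tibble(group = as.character(x$groups)), scores)
}

#' @method glance plsda_model
#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    r2x = utils::tail(x$r2x, 1),
    r2y = utils::tail(x$r2y, 1),
    q2 = x$q2,
    accuracy = x$accuracy
  )
}

#' @method tidy nmr_pca
#' @export
tidy.nmr_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, .name_repair = ~ paste0("PC", seq_along(.)))
}

#' @method glance nmr_pca
#' @export
glance.nmr_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_variance),
                 explained_variance = x$explained_variance)
}

#' @method tidy osc_model
#' @export
tidy.osc_model <- function(x, ...) {
  tibble::tibble(
    factor = seq_along(x$r2x_removed),
    r2x_removed = x$r2x_removed
  )
}

#' @method glance perm_report
#' @export
glance.perm_report <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm,
                 r2y = x$observed[["r2y"]], q2 = x$observed[["q2"]],
                 p_r2y = x$p_r2y, p_q2 = x$p_q2)
}

#' @method tidy perm_report
#' @export
tidy.perm_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(kind = "observed", r2y = x$observed[["r2y"]],
                   q2 = x$observed[["q2"]]),
    dplyr::mutate(x$permuted, kind = "permuted")
  )
}

#' @method tidy spls_model
#' @export
tidy.spls_model <- function(x, ...) {
  xl <- tibble::as_tibble(x$x_loadings,
                          .name_repair = ~ paste0("comp", seq_along(.)))
  yl <- tibble::as_tibble(x$y_loadings,
                          .name_repair = ~ paste0("comp", seq_along(.)))
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(block = "X", variable = x$x_names), xl),
    dplyr::bind_cols(tibble::tibble(block = "Y", variable = x$y_names), yl)
  ) |>
    tidyr::pivot_longer(dplyr::starts_with("comp"), names_to = "component",
                        names_prefix = "comp", values_to = "loading") |>
    dplyr::mutate(component = as.integer(.data$component))
}

#' @method tidy association_network
#' @export
tidy.association_network <- function(x, ...) {
  x$edges
}

#' @method glance association_network
#' @export
glance.association_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 threshold = x$threshold,
                 n_positive = sum(x$edges$weight > 0),
                 n_negative = sum(x$edges$weight < 0))
}

#' PLS-DA score plot
#'
#' @param object A `plsda_model`.
#' @param components Which two components to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plsda_model
#' @export
autoplot.plsda_model <- function(object, components = c(1L, 2L), ...) {
  abort_if(max(components) > object$n_components,
           "model has only %d components", object$n_components)
  df <- tibble::tibble(
    t1 = object$scores[, components[1L]],
    t2 = object$scores[, components[2L]],
    group = as.character(object$groups)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t1, .data$t2, color = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, color = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("t[%d]", components[1L]),
                  y = sprintf("t[%d]", components[2L]),
                  title = "PLS-DA scores") +
    ggplot2::theme_minimal()
}

#' S-plot of covariance vs correlation with the first score
#'
#' Discriminating variables sit in the upper-right and lower-left corners.
#'
#' @param object An `splot_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot splot_result
#' @export
autoplot.splot_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cov1, .data$corr1,
                                       color = .data$color_value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  limits = c(0, 1), name = "|r|") +
    ggplot2::labs(x = "cov(t1, x)", y = "corr(t1, x)", title = "S-plot") +
    ggplot2::theme_minimal()
}

#' Correlation-colored loading pseudo-spectrum
#'
#' Back-scaled covariance loadings against ppm, colored by the absolute
#' correlation with the first score (hot = discriminating).
#'
#' @param splot_result An `splot_result` with a ppm axis.
#' @return A ggplot.
#' @export
plot_loadings <- function(splot_result) {
  abort_if(!inherits(splot_result, "splot_result"),
           "input must be an splot_result")
  abort_if(all(is.na(splot_result$ppm)), "splot_result has no ppm axis")
  ggplot2::ggplot(splot_result,
                  ggplot2::aes(.data$ppm, .data$back_scaled_loading,
                               color = .data$color_value)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  limits = c(0, 1), name = "|r|") +
    ggplot2::labs(x = "ppm", y = "back-scaled loading",
                  title = "Correlation-colored loadings") +
    ggplot2::theme_minimal()
}

#' STOCSY pseudo-spectrum colored by correlation
#'
#' @param object A `stocsy_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stocsy_trace
#' @export
autoplot.stocsy_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$ppm, .data$cov,
                                       color = abs(.data$r))) +
    ggplot2::geom_line(ggplot2::aes(group = 1), linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = attr(object, "driver_ppm"),
                        linetype = "dashed", color = "grey50") +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  limits = c(0, 1), name = "|r|") +
    ggplot2::labs(x = "ppm", y = "cov(driver, x)",
                  title = sprintf("STOCSY, driver %.3f ppm",
                                  attr(object, "driver_ppm"))) +
    ggplot2::theme_minimal()
}

#' Permutation-test scatter of permuted vs observed statistics
#'
#' @param object A `perm_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perm_report
#' @export
autoplot.perm_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(dplyr::filter(df, .data$kind == "permuted"),
                  ggplot2::aes(.data$r2y, .data$q2)) +
    ggplot2::geom_point(alpha = 0.3, size = 1) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$kind == "observed"),
                        color = "red", size = 3, shape = 17) +
    ggplot2::labs(x = "R2Y", y = "Q2",
                  title = sprintf("Permutation test (%d permutations)",
                                  object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Bipartite association-network plot
#'
#' Metabolites on the left, parameters on the right; edges colored red for
#' positive and blue for negative association.
#'
#' @param object An `association_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot association_network
#' @export
autoplot.association_network <- function(object, ...) {
  nodes <- object$nodes
  mets <- nodes$name[nodes$type == "metabolite"]
  pars <- nodes$name[nodes$type == "parameter"]
  pos <- dplyr::bind_rows(
    tibble::tibble(name = mets, x = 0,
                   y = seq_len(length(mets)) / max(1, length(mets))),
    tibble::tibble(name = pars, x = 1,
                   y = seq_len(length(pars)) / max(1, length(pars)))
  )
  edges <- object$edges |>
    dplyr::left_join(pos, by = c(from = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(pos, by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, color = .data$weight),
      linewidth = 0.5) +
    ggplot2::scale_color_gradient2(low = "blue", mid = "grey90",
                                   high = "red", limits = c(-1, 1),
                                   name = "similarity") +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       hjust = rep(c(1.2, -0.2),
                                   c(length(mets), length(pars))),
                       size = 3) +
    ggplot2::xlim(-0.5, 1.5) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Association network (|s| > %g)",
                                  object$threshold))
}

#' Heatmap of z-scored group means with significance stars
#'
#' Metabolites as rows, groups as columns, diverging color scale; stars
#' from the BH-adjusted comparisons against the reference group.
#'
#' @param zscores Output of [zscore_table()].
#' @param univariate Optional output of [fold_change_tests()]; its stars
#'   annotate the corresponding cells.
#' @param group_order Optional column order.
#' @return A ggplot.
#' @export
plot_heatmap <- function(zscores, univariate = NULL, group_order = NULL) {
  df <- zscores
  if (!is.null(group_order)) {
    df$group <- factor(df$group, levels = group_order)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$metabolite,
                                        fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "mean z") +
    ggplot2::labs(x = NULL, y = NULL, title = "Group-mean z-scores") +
    ggplot2::theme_minimal()
  if (!is.null(univariate)) {
    stars <- univariate |>
      dplyr::mutate(group = sub(" vs .*$", "", .data$comparison)) |>
      dplyr::select("metabolite", "group", "stars") |>
      dplyr::filter(.data$stars != "")
    if (!is.null(group_order)) {
      stars$group <- factor(stars$group, levels = group_order)
    }
    p <- p + ggplot2::geom_text(data = stars,
                                ggplot2::aes(.data$group, .data$metabolite,
                                             label = .data$stars),
                                inherit.aes = FALSE, size = 3)
  }
  p
}
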