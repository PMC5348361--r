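# Per-metabolite statistics: fold changes with Welch tests and BH control,
# z-scored heatmap tables, ANOVA + Tukey for phenotype parameters, and the
# 2^-ddCT transform for qPCR data.

stars_from_q <- function(q) {
  dplyr::case_when(
    q <= 0.001 ~ "***",
    q <= 0.01 ~ "**",
    q <= 0.05 ~ "*",
    TRUE ~ ""
  )
}

split_value_cols <- function(data, group_col) {
  abort_if(!group_col %in% names(data), "column '%s' not found", group_col)
  value_cols <- setdiff(names(data), c(group_col, "sample_id"))
  num <- vapply(data[value_cols], is.numeric, logical(1))
  value_cols <- value_cols[num]
  abort_if(length(value_cols) == 0L, "no numeric value columns found")
  list(groups = as.character(data[[group_col]]), value_cols = value_cols)
}

#' Fold changes and Welch tests against a reference group, BH-adjusted
#'
#' For every metabolite and every non-reference group, computes the
#' mean-ratio fold change versus the reference group, a two-sided Welch
#' (unequal-variance) t-test, and Benjamini-Hochberg adjusted q-values with
#' the adjustment family being all metabolites within one comparison.
#' Significance stars are keyed to the adjusted values at 0.05 / 0.01 /
#' 0.001. Fold changes are meaningful on normalized, unscaled data
#' (ratios on Pareto-scaled data would be distorted).
#'
#' @param data Data frame: one row per sample, a group column plus numeric
#'   metabolite columns (an optional `sample_id` column is ignored).
#' @param group_col Name of the group column.
#' @param reference Reference group label (default `"sham"`).
#' @return A tibble of class `univariate_table`: `metabolite`,
#'   `comparison`, `fold_change`, `log2_fc`, `p_raw`, `q_bh`, `stars`.
#'   Metabolites with a zero reference mean get `NA` fold change and a
#'   `flagged` marker.
#' @export
fold_change_tests <- function(data, group_col = "group", reference = "sham") {
  sp <- split_value_cols(data, group_col)
  groups <- sp$groups
  abort_if(!reference %in% groups, "reference group '%s' not present",
           reference)
  others <- setdiff(unique(groups), reference)
  ref_rows <- groups == reference

  purrr::map_dfr(others, function(g) {
    rows <- groups == g
    res <- purrr::map_dfr(sp$value_cols, function(m) {
      xr <- data[[m]][ref_rows]
      xg <- data[[m]][rows]
      mr <- mean(xr)
      flagged <- mr == 0
      fc <- if (flagged) NA_real_ else mean(xg) / mr
      p <- tryCatch(stats::t.test(xg, xr)$p.value, error = function(e) NA_real_)
      tibble::tibble(metabolite = m, comparison = paste0(g, " vs ", reference),
                     fold_change = fc,
                     log2_fc = if (flagged || fc <= 0) NA_real_ else log2(fc),
                     p_raw = p, flagged = flagged)
    })
    res$q_bh <- stats::p.adjust(res$p_raw, method = "BH")
    res$stars <- stars_from_q(res$q_bh)
    res
  }) -> out
  class(out) <- c("univariate_table", class(out))
  out
}

#' Per-group mean z-scores of metabolite levels
#'
#' Each metabolite is z-scored across all samples (mean 0, sd 1), then the
#' z-scores are averaged within groups — the values shown as heatmap cells
#' when displaying group-level metabolite shifts.
#'
#' @inheritParams fold_change_tests
#' @return Tibble: `metabolite`, `group`, `mean_z`. Zero-variance
#'   metabolites are flagged with `NA` mean_z.
#' @export
zscore_table <- function(data, group_col = "group") {
  sp <- split_value_cols(data, group_col)
  abort_if(nrow(data) < 2L, "need at least 2 samples")
  purrr::map_dfr(sp$value_cols, function(m) {
    v <- data[[m]]
    s <- stats::sd(v)
    z <- if (s == 0) rep(NA_real_, length(v)) else (v - mean(v)) / s
    tibble::tibble(metabolite = m, group = sp$groups, z = z)
  }) |>
    dplyr::group_by(.data$metabolite, .data$group) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop")
}

#' One-way ANOVA with Tukey's HSD post hoc per parameter
#'
#' Standard one-way analysis of variance followed by Tukey's honestly
#' significant difference test on all group pairs (Tukey-Kramer for
#' unbalanced groups), as used for assay-panel parameters.
#'
#' @inheritParams fold_change_tests
#' @return List of class `anova_tukey`: `omnibus` tibble (`parameter`,
#'   `f_statistic`, `p_value`) and `pairwise` tibble (`parameter`,
#'   `contrast`, `estimate`, `p_adj`).
#' @export
anova_tukey <- function(data, group_col = "group") {
  sp <- split_value_cols(data, group_col)
  tab <- table(sp$groups)
  abort_if(length(tab) < 2L, "need at least 2 groups")
  abort_if(any(tab < 2L), "group(s) with a single sample: %s",
           paste(names(tab)[tab < 2L], collapse = ", "))
  g <- factor(sp$groups)
  omni <- list(); pairw <- list()
  for (m in sp$value_cols) {
    fit <- stats::aov(v ~ g, data = data.frame(v = data[[m]], g = g))
    an <- summary(fit)[[1]]
    omni[[m]] <- tibble::tibble(parameter = m,
                                f_statistic = an[["F value"]][1],
                                p_value = an[["Pr(>F)"]][1])
    tk <- stats::TukeyHSD(fit)$g
    pairw[[m]] <- tibble::tibble(parameter = m,
                                 contrast = rownames(tk),
                                 estimate = tk[, "diff"],
                                 p_adj = tk[, "p adj"])
  }
  structure(list(omnibus = dplyr::bind_rows(omni),
                 pairwise = dplyr::bind_rows(pairw)),
            class = "anova_tukey")
}

#' Relative qPCR expression by the 2^-ddCT method
#'
#' Cycle-threshold values of each target gene are normalized to a
#' reference gene within each sample (dCT), then to the mean dCT of the
#' control group (ddCT); relative expression is `2^-ddCT`, so control
#' samples average 1 by construction.
#'
#' @param ct Data frame: `sample_id`, group column, one numeric CT column
#'   per gene.
#' @param target_genes Character vector of gene columns to quantify.
#' @param reference_gene Housekeeping gene column (e.g. `"Actb"`).
#' @param control_group Label of the control group.
#' @param group_col Name of the group column.
#' @return Tibble: `sample_id`, `group`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`. Samples with a missing CT are dropped
#'   for that gene with a warning.
#' @export
ddct <- function(ct, target_genes, reference_gene, control_group,
                 group_col = "group") {
  abort_if(!reference_gene %in% names(ct), "reference gene '%s' not found",
           reference_gene)
  abort_if(anyNA(ct[[reference_gene]]),
           "reference gene '%s' has missing CT values", reference_gene)
  abort_if(!control_group %in% ct[[group_col]],
           "control group '%s' not present", control_group)
  missing_genes <- setdiff(target_genes, names(ct))
  abort_if(length(missing_genes) > 0, "target gene(s) not found: %s",
           paste(missing_genes, collapse = ", "))

  purrr::map_dfr(target_genes, function(gene) {
    keep <- !is.na(ct[[gene]])
    if (any(!keep)) {
      rlang::warn(sprintf("dropping %d sample(s) with missing CT for %s",
                          sum(!keep), gene))
    }
    dct <- ct[[gene]][keep] - ct[[reference_gene]][keep]
    grp <- as.character(ct[[group_col]][keep])
    ddct_ <- dct - mean(dct[grp == control_group])
    tibble::tibble(sample_id = ct$sample_id[keep], group = grp, gene = gene,
                   delta_ct = dct, delta_delta_ct = ddct_,
                   rel_expr = 2^(-ddct_))
  })
}
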