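# Pipeline orchestration: validated configuration, staged execution with
# logging, metabolite-level quantification, and the bundled demo fixture.

#' Map buckets to metabolites and integrate concentration proxies
#'
#' Buckets whose center lies within `tol` of any library peak center are
#' assigned to that metabolite; each metabolite's proxy concentration is
#' the sum of its assigned bucket values. This is the bucket-level
#' analogue of integrating assigned resonances, and supplies the
#' metabolite-by-sample table used by the univariate and network stages.
#'
#' @param bucket_table A `bucket_table` (normally PQN-normalized).
#' @param library Peak table from [build_metabolite_library()].
#' @param tol Half-width (ppm) of the integration window per peak.
#' @return Tibble: `sample_id`, `group`, one numeric column per
#'   metabolite with at least one assigned bucket.
#' @export
integrate_metabolites <- function(bucket_table, library, tol = 0.01) {
  abort_if(!inherits(bucket_table, "bucket_table"),
           "bucket_table must be a bucket_table")
  centers <- bucket_table$bin_centers
  out <- tibble::tibble(sample_id = bucket_table$samples$sample_id,
                        group = bucket_table$samples$group)
  for (m in unique(library$metabolite)) {
    pk <- library$center_ppm[library$metabolite == m]
    sel <- rep(FALSE, length(centers))
    for (cp in pk) sel <- sel | abs(centers - cp) <= tol
    if (!any(sel)) next
    out[[m]] <- rowSums(bucket_table$matrix[, sel, drop = FALSE])
  }
  out
}

#' Assign each bucket to the nearest library metabolite
#'
#' @inheritParams integrate_metabolites
#' @return Character vector (length = number of buckets) of metabolite
#'   names, `NA` where no peak lies within `tol`.
#' @export
assign_bins <- function(bucket_table, library, tol = 0.01) {
  centers <- bucket_table$bin_centers
  res <- rep(NA_character_, length(centers))
  best <- rep(Inf, length(centers))
  for (k in seq_len(nrow(library))) {
    d <- abs(centers - library$center_ppm[k])
    hit <- d <= tol & d < best
    res[hit] <- library$metabolite[k]
    best[hit] <- d[hit]
  }
  res
}

default_config <- function() {
  list(
    tissue = "cerebrum",
    groups = c("sham", "MCAO", "A", "B", "C", "AB", "AC", "BC", "ABC"),
    n_per_group = 10L,
    seed = 1L,
    noise_sd = 0.02,
    dilution_log_sd = 0.3,
    conc_log_sd = 0.2,
    shift_jitter_sd_ppm = 0,
    baseline_amplitude = 0,
    n_points = 16384L,
    width = 0.0025,
    range = c(0.2, 10),
    exclude = list(c(4.65, 5.25)),
    pqn_reference = "all",
    model_groups = c("sham", "MCAO"),
    osc_factors = 1L,
    n_components = 2L,
    folds = 2L,
    repeats = 50L,
    n_perm = 200L,
    reference_group = "sham",
    stocsy_drivers = numeric(),
    keepX = 25L,
    keepY = NULL,
    network_threshold = 0.8,
    n_parameters = 6L,
    phenotype_noise_sd = 0.1
  )
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (0.0025 ppm buckets over 0.2-10 ppm,
#' cerebrum water exclusion, one OSC factor, two components, repeated
#' two-fold cross-validation, network threshold 0.8) and overrides the
#' named entries. Unknown keys are rejected so typos fail before any
#' computation. The demo default of 200 permutations keeps a run fast; a
#' final model would use 2000.
#'
#' @param ... Named overrides of the default entries.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(cfg))
  abort_if(length(unknown) > 0, "unknown config key(s): %s",
           paste(unknown, collapse = ", "))
  abort_if(is.null(names(over)) && length(over) > 0,
           "config overrides must be named")
  cfg[names(over)] <- over
  abort_if(cfg$width <= 0, "width must be > 0")
  abort_if(cfg$n_per_group < 2L, "n_per_group must be >= 2")
  abort_if(cfg$noise_sd < 0, "noise_sd must be >= 0")
  abort_if(cfg$n_perm < 1L, "n_perm must be >= 1")
  abort_if(cfg$folds < 2L, "folds must be >= 2")
  abort_if(cfg$network_threshold < 0 || cfg$network_threshold > 1,
           "network_threshold must be in [0, 1]")
  abort_if(!all(cfg$model_groups %in% cfg$groups),
           "model_groups must be a subset of groups")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file of overrides (same keys as [pipeline_config()]).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  abort_if(!file.exists(path), "config file '%s' does not exist", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$exclude) && is.matrix(raw$exclude)) {
    raw$exclude <- lapply(seq_len(nrow(raw$exclude)),
                          function(i) raw$exclude[i, ])
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages: simulate -> bucket/exclude -> PQN -> Pareto -> OSC-PLS-DA on
#' the configured group pair -> cross-validation -> permutation test ->
#' S-plot -> metabolite integration -> univariate tables -> optional
#' STOCSY traces -> phenotype simulation -> sPLS association network. All
#' tabular artifacts are written as delimited text, model summaries as
#' JSON, and a log records every parameter used plus per-stage wall time.
#' Reruns with the same config are bit-identical for the deterministic
#' stages.
#'
#' @param config A `pipeline_config` (or named overrides passed to
#'   [pipeline_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with every stage result (`spectra`,
#'   `bucket_table`, `processed`, `osc`, `model`, `cv`, `permutation`,
#'   `splot`, `metabolites`, `univariate`, `zscores`, `stocsy`,
#'   `phenotypes`, `spls`, `network`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("nmrpls_run_")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config = unclass(config),
              config_hash = rlang::hash(unclass(config)),
              seed = config$seed, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(sprintf("FAILED at stage '%s': %s", name,
                         conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      rlang::abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
    log$stages[[name]] <<- list(elapsed_s = proc.time()[["elapsed"]] - t0)
    res
  }
  seeds <- child_seeds(config$seed, 4L)

  lib <- build_metabolite_library(config$tissue)
  spectra <- t_stage("simulate", {
    des <- cohort_design(
      groups = config$groups, n_per_group = config$n_per_group,
      effects = default_effects(config$groups, lib),
      conc_log_sd = config$conc_log_sd,
      dilution_log_sd = config$dilution_log_sd,
      shift_jitter_sd_ppm = config$shift_jitter_sd_ppm,
      noise_sd = config$noise_sd,
      baseline_amplitude = config$baseline_amplitude, seed = seeds[1L])
    simulate_cohort(des, lib, n_points = config$n_points,
                    ppm_range = config$range)
  })
  bucket <- t_stage("preprocess", {
    bt <- bin_spectra(spectra, width = config$width, range = config$range,
                      exclude = config$exclude)
    pqn_normalize(bt, reference_group = config$pqn_reference)
  })
  write_bucket_table(bucket, file.path(out_dir, "buckets_normalized.tsv"))

  sel <- bucket$samples$group %in% config$model_groups
  sub_bucket <- bucket
  sub_bucket$matrix <- bucket$matrix[sel, , drop = FALSE]
  sub_bucket$samples <- bucket$samples[sel, ]
  processed <- t_stage("scale", center_pareto(sub_bucket))
  groups2 <- sub_bucket$samples$group

  osc <- t_stage("osc", osc_filter(processed, groups2,
                                   n_factors = config$osc_factors))
  model <- t_stage("plsda", fit_plsda(osc$x_corrected, groups2,
                                      n_components = config$n_components))
  cv <- t_stage("cross_validate",
                cross_validate(processed, groups2, folds = config$folds,
                               repeats = config$repeats,
                               osc_factors = config$osc_factors,
                               n_components = config$n_components,
                               seed = seeds[2L]))
  model$q2 <- cv$q2
  perm <- t_stage("permutation",
                  permutation_test(processed, groups2,
                                   n_perm = config$n_perm, seed = seeds[2L],
                                   folds = config$folds,
                                   osc_factors = config$osc_factors,
                                   n_components = config$n_components))
  sp <- t_stage("splot", splot(model, processed))
  utils::write.table(sp, file.path(out_dir, "splot.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tidy(model), file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_components = model$n_components,
         r2x = utils::tail(model$r2x, 1), r2y = utils::tail(model$r2y, 1),
         q2 = cv$q2, osc_r2x_removed = osc$r2x_removed,
         p_r2y = perm$p_r2y, p_q2 = perm$p_q2, n_perm = perm$n_perm,
         config_hash = log$config_hash, seed = config$seed),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)

  mets <- t_stage("integrate", integrate_metabolites(bucket, lib))
  uni <- t_stage("univariate",
                 fold_change_tests(mets, reference = config$reference_group))
  zs <- t_stage("zscore", zscore_table(mets))
  utils::write.table(uni, file.path(out_dir, "univariate.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(zs, file.path(out_dir, "zscores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  traces <- t_stage("stocsy", {
    lapply(config$stocsy_drivers, function(d) {
      tr <- stocsy_1d(bucket, d)
      utils::write.table(tr, file.path(out_dir,
                                       sprintf("stocsy_%.3f.tsv", d)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tr
    })
  })

  net_res <- t_stage("network", {
    ph <- simulate_phenotypes(spectra$truth$concentrations,
                              n_parameters = config$n_parameters,
                              noise_sd = config$phenotype_noise_sd,
                              seed = seeds[3L])
    xblock <- dplyr::select(mets, -dplyr::any_of("group"))
    spls <- fit_spls(xblock, ph$parameters,
                     keepX = min(config$keepX,
                                 ncol(xblock) - 1L),
                     keepY = config$keepY)
    net <- similarity_network(spls, threshold = config$network_threshold)
    export_network(net, file.path(out_dir, "network"))
    list(phenotypes = ph, spls = spls, network = net)
  })

  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    spectra = spectra, bucket_table = bucket, processed = processed,
    osc = osc, model = model, cv = cv, permutation = perm, splot = sp,
    metabolites = mets, univariate = uni, zscores = zs, stocsy = traces,
    phenotypes = net_res$phenotypes, spls = net_res$spls,
    network = net_res$network, out_dir = out_dir, log = log
  ))
}

# Plausible group effects for the demo cohort: the lesion raises lactate,
# glutamate, glutamine and alanine and lowers glucose and citrate; single
# and double treatments recover part of the shift, the triple most of it.
default_effects <- function(groups, library) {
  mets_up <- intersect(c("lactate", "glutamate", "glutamine", "alanine"),
                       unique(library$metabolite))
  mets_dn <- intersect(c("glucose", "citrate"), unique(library$metabolite))
  recovery <- c(MCAO = 0, A = 0.35, B = 0.35, C = 0.35,
                AB = 0.6, AC = 0.6, BC = 0.6, ABC = 0.9)
  rows <- list()
  for (g in intersect(names(recovery), groups)) {
    r <- recovery[[g]]
    for (m in mets_up) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(group = g, metabolite = m, factor = 2 - r * 1)
    }
    for (m in mets_dn) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(group = g, metabolite = m, factor = 0.5 + r * 0.5)
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate the small bundled test cohort
#'
#' A 4-group (sham, MCAO, AB, ABC), n = 8 cohort with exactly three
#' planted discriminating metabolites (lactate up, glutamine up, glucose
#' down in MCAO, partially recovered under treatment) and a 6-parameter
#' phenotype panel, written as delimited text. Regenerating with the same
#' seed reproduces the files byte-for-byte.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, spectra, buckets, metadata
#'   and phenotypes are written there.
#' @param n_points Grid points (reduced from the full default to keep the
#'   fixture light).
#' @return List: `spectra`, `bucket_table` (PQN-normalized), `phenotypes`
#'   (with mixing ground truth), `design`, `library`, `planted` (the three
#'   metabolite names).
#' @export
make_fixtures <- function(seed = 42L, dir = NULL, n_points = 16384L) {
  lib <- build_metabolite_library("cerebrum")
  planted <- c("lactate", "glutamine", "glucose")
  effects <- dplyr::bind_rows(
    tibble::tibble(group = "MCAO", metabolite = planted,
                   factor = c(2.2, 2.0, 0.45)),
    tibble::tibble(group = "AB", metabolite = planted,
                   factor = c(1.6, 1.5, 0.7)),
    tibble::tibble(group = "ABC", metabolite = planted,
                   factor = c(1.1, 1.05, 0.95))
  )
  des <- cohort_design(groups = c("sham", "MCAO", "AB", "ABC"),
                       n_per_group = 8L, effects = effects,
                       conc_log_sd = 0.15, dilution_log_sd = 0.3,
                       noise_sd = 0.01, seed = seed)
  spectra <- simulate_cohort(des, lib, n_points = n_points)
  bucket <- pqn_normalize(bin_spectra(spectra, exclude = c(4.65, 5.25)))
  ph <- simulate_phenotypes(spectra$truth$concentrations, n_parameters = 6L,
                            noise_sd = 0.05, seed = seed + 1L)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_spectra(spectra, file.path(dir, "spectra.tsv"))
    write_bucket_table(bucket, file.path(dir, "buckets.tsv"))
    utils::write.table(ph$parameters, file.path(dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(spectra = spectra, bucket_table = bucket, phenotypes = ph,
       design = des, library = lib, planted = planted)
}
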