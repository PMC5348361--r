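#' Built-in metabolite peak library
#'
#' Returns a peak table of metabolite templates typical of aqueous tissue
#' extracts or serum in 1D 1H-NMR. Each metabolite is modelled as a set of
#' stick resonances (center, relative area, linewidth); multiplicities are
#' collapsed into single Lorentzian lines at the multiplet center. The
#' cerebrum and serum libraries share the core small-molecule panel and
#' differ in a few tissue-typical signals.
#'
#' Chemical shifts follow common assignment tables; in particular glutamine
#' carries resonances at 2.14 and 2.44 ppm and glutamate at 2.10 and
#' 2.34 ppm, the pairs classically used to tell the two apart by
#' correlation analysis.
#'
#' @param tissue `"cerebrum"` or `"serum"`.
#' @return A tibble of class `nmr_library` with one row per resonance:
#'   `metabolite`, `center_ppm`, `relative_area`, `linewidth_ppm`,
#'   `base_area`.
#' @export
#' @examples
#' lib <- build_metabolite_library("cerebrum")
#' dplyr::filter(lib, metabolite == "glutamine")
build_metabolite_library <- function(tissue = c("cerebrum", "serum")) {
  abort_if(
    !is.character(tissue) || !tissue[1] %in% c("cerebrum", "serum"),
    "unknown tissue label '%s'; expected 'cerebrum' or 'serum'",
    as.character(tissue[1])
  )
  tissue <- match.arg(tissue)

  # name, base_area, then peaks as (center_ppm, relative_area) pairs;
  # linewidth defaults to 0.003 ppm everywhere (FWHM).
  core <- list(
    list("isoleucine",   0.8, c(0.94, 0.6, 1.01, 0.4)),
    list("leucine",      1.0, c(0.96, 1.0)),
    list("valine",       0.7, c(1.04, 0.6, 3.61, 0.2)),
    list("lactate",      2.5, c(1.33, 0.75, 4.11, 0.25)),
    list("alanine",      1.2, c(1.48, 1.0)),
    list("acetate",      0.9, c(1.92, 1.0)),
    list("GABA",         0.8, c(1.90, 0.4, 2.29, 0.4, 3.01, 0.2)),
    list("glutamate",    1.5, c(2.10, 0.5, 2.34, 0.5)),
    list("glutamine",    1.3, c(2.14, 0.5, 2.44, 0.5)),
    list("pyruvate",     0.6, c(2.37, 1.0)),
    list("citrate",      0.8, c(2.54, 0.5, 2.66, 0.5)),
    list("creatine",     1.1, c(3.04, 0.6, 3.93, 0.4)),
    list("choline",      0.7, c(3.20, 1.0)),
    list("taurine",      1.4, c(3.26, 0.5, 3.42, 0.5)),
    list("glycine",      1.0, c(3.56, 1.0)),
    list("myo-inositol", 1.2, c(3.52, 0.4, 3.62, 0.3, 4.06, 0.3)),
    list("glucose",      2.0, c(3.40, 0.3, 3.72, 0.4, 5.23, 0.3)),
    list("formate",      0.3, c(8.46, 1.0))
  )
  extra <- switch(tissue,
    cerebrum = list(
      list("NAA",       1.6, c(2.02, 0.8, 2.49, 0.2)),
      list("aspartate", 0.7, c(2.68, 0.5, 2.80, 0.5)),
      list("AMP",       0.4, c(8.26, 0.5, 8.60, 0.5))
    ),
    serum = list(
      list("betaine",    0.9, c(3.25, 0.7, 3.90, 0.3)),
      list("TMAO",       0.8, c(3.27, 1.0)),
      list("acetoacetate", 0.5, c(2.27, 1.0))
    )
  )

  rows <- purrr::map_dfr(c(core, extra), function(m) {
    pk <- matrix(m[[3]], ncol = 2, byrow = TRUE)
    tibble::tibble(
      metabolite = m[[1]],
      center_ppm = pk[, 1],
      relative_area = pk[, 2],
      linewidth_ppm = 0.003,
      base_area = m[[2]]
    )
  })
  stopifnot(
    all(rows$center_ppm >= 0.2 & rows$center_ppm <= 10),
    all(rows$relative_area > 0), all(rows$linewidth_ppm > 0),
    !anyDuplicated(rows$center_ppm)
  )
  class(rows) <- c("nmr_library", class(rows))
  rows
}

#' Describe a multi-group cohort for spectrum simulation
#'
#' The default nine-group layout mirrors a factorial stroke-model drug study:
#' a sham group, an untreated lesion (MCAO) group, three single-component
#' treatments A, B, C, their pairwise combinations and the full triple.
#'
#' @param groups Ordered character vector of group labels; the first is the
#'   reference whose concentration factors are all 1.
#' @param n_per_group Samples per group (>= 2).
#' @param effects Tibble with columns `group`, `metabolite`, `factor` giving
#'   the multiplicative concentration change of a metabolite in a group
#'   relative to the reference. Unlisted pairs default to 1.
#' @param conc_log_sd Per-sample biological variability of each metabolite
#'   concentration, as the sd of a log-normal multiplier.
#' @param dilution_log_sd Sd of the log-normal per-sample dilution factor.
#' @param shift_jitter_sd_ppm Sd of the per-sample, per-metabolite chemical
#'   shift jitter (ppm).
#' @param noise_sd Sd of additive Gaussian point noise.
#' @param baseline_amplitude Scale of the smooth per-sample baseline.
#' @param seed Integer seed controlling every stochastic draw.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(groups = c("sham", "MCAO", "A", "B", "C",
                                     "AB", "AC", "BC", "ABC"),
                          n_per_group = 10L,
                          effects = NULL,
                          conc_log_sd = 0.2,
                          dilution_log_sd = 0.3,
                          shift_jitter_sd_ppm = 0,
                          noise_sd = 0,
                          baseline_amplitude = 0,
                          seed = 1L) {
  abort_if(n_per_group < 2L, "n_per_group must be >= 2, got %s", n_per_group)
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  abort_if(dilution_log_sd < 0, "dilution_log_sd must be >= 0")
  abort_if(shift_jitter_sd_ppm < 0, "shift_jitter_sd_ppm must be >= 0")
  abort_if(baseline_amplitude < 0, "baseline_amplitude must be >= 0")
  abort_if(anyDuplicated(groups) > 0, "group labels must be unique")
  if (is.null(effects)) {
    effects <- tibble::tibble(group = character(), metabolite = character(),
                              factor = numeric())
  }
  abort_if(
    !all(c("group", "metabolite", "factor") %in% names(effects)),
    "effects must have columns group, metabolite, factor"
  )
  abort_if(any(effects$factor <= 0), "all effect factors must be > 0")
  ref <- effects$factor[effects$group == groups[1]]
  abort_if(any(ref != 1), "reference group '%s' factors must all be 1", groups[1])
  structure(
    list(groups = groups, n_per_group = as.integer(n_per_group),
         effects = effects, conc_log_sd = conc_log_sd,
         dilution_log_sd = dilution_log_sd,
         shift_jitter_sd_ppm = shift_jitter_sd_ppm, noise_sd = noise_sd,
         baseline_amplitude = baseline_amplitude, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

lorentzian <- function(ppm, center, fwhm) {
  gamma <- fwhm / 2
  (gamma / pi) / ((ppm - center)^2 + gamma^2)
}

#' Simulate a cohort of 1D 1H-NMR spectra with known ground truth
#'
#' Each sample's spectrum is the dilution-scaled sum over metabolites of
#' concentration times unit-area Lorentzian multiplets, plus an optional
#' smooth baseline and Gaussian noise. Every stochastic draw (per-sample
#' concentrations, dilution factors, shift jitter, calibration offsets) is
#' retained in the `truth` element so downstream recovery can be verified.
#'
#' @param design A [cohort_design()].
#' @param library A peak table from [build_metabolite_library()] (or any
#'   tibble with the same columns).
#' @param n_points Number of grid points (default 16384).
#' @param ppm_range Spectral range, low to high ppm; the stored axis is
#'   descending as spectrometers plot it.
#' @param include_tsp Plant a TSP-like reference singlet at 0.0 ppm (the
#'   grid is extended below 0 to hold it) so that [reference_to_tsp()] has
#'   a calibration anchor.
#' @param calibration_sd_ppm Sd of a per-sample miscalibration offset added
#'   to every resonance (undone by referencing).
#' @return An `nmr_spectra` object: `ppm` (descending), `intensities`
#'   (samples x points), `samples` (tibble: `sample_id`, `group`), `truth`
#'   (list: `concentrations`, `dilutions`, `jitter`, `calibration`).
#' @export
simulate_cohort <- function(design, library,
                            n_points = 16384L,
                            ppm_range = c(0.2, 10),
                            include_tsp = FALSE,
                            calibration_sd_ppm = 0) {
  abort_if(!inherits(design, "cohort_design"), "design must be a cohort_design")
  abort_if(nrow(library) == 0L, "metabolite library is empty")
  abort_if(design$n_per_group < 2L, "n_per_group must be >= 2")
  abort_if(design$noise_sd < 0, "noise_sd must be >= 0")

  lo <- min(ppm_range); hi <- max(ppm_range)
  if (include_tsp) lo <- min(lo, -0.2)
  ppm <- seq(hi, lo, length.out = n_points)   # descending
  dp <- abs(ppm[1] - ppm[2])

  mets <- unique(library$metabolite)
  groups <- rep(design$groups, each = design$n_per_group)
  n <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n))

  # group x metabolite effect lookup, default 1
  eff <- matrix(1, nrow = length(design$groups), ncol = length(mets),
                dimnames = list(design$groups, mets))
  if (nrow(design$effects)) {
    bad <- setdiff(design$effects$metabolite, mets)
    abort_if(length(bad) > 0, "effects name unknown metabolites: %s",
             paste(bad, collapse = ", "))
    for (k in seq_len(nrow(design$effects))) {
      eff[design$effects$group[k], design$effects$metabolite[k]] <-
        design$effects$factor[k]
    }
  }

  with_seed(design$seed, {
    conc <- eff[groups, , drop = FALSE] *
      matrix(exp(stats::rnorm(n * length(mets), 0, design$conc_log_sd)),
             n, length(mets))
    dimnames(conc) <- list(sample_ids, mets)
    dil <- exp(stats::rnorm(n, 0, design$dilution_log_sd))
    jit <- matrix(stats::rnorm(n * length(mets), 0, design$shift_jitter_sd_ppm),
                  n, length(mets), dimnames = list(sample_ids, mets))
    calib <- stats::rnorm(n, 0, calibration_sd_ppm)
    base_coef <- matrix(stats::runif(n * 3, -1, 1), n, 3)
    noise <- if (design$noise_sd > 0) {
      matrix(stats::rnorm(n * n_points, 0, design$noise_sd), n, n_points)
    } else NULL
  })

  peaks <- split(library, library$metabolite)
  intens <- matrix(0, n, n_points, dimnames = list(sample_ids, NULL))
  for (i in seq_len(n)) {
    s <- numeric(n_points)
    for (m in mets) {
      pk <- peaks[[m]]
      amp <- dil[i] * conc[i, m] * pk$base_area[1]
      shift <- jit[i, m] + calib[i]
      for (j in seq_len(nrow(pk))) {
        s <- s + amp * pk$relative_area[j] *
          lorentzian(ppm, pk$center_ppm[j] + shift, pk$linewidth_ppm[j])
      }
    }
    if (include_tsp) s <- s + 5 * lorentzian(ppm, 0 + calib[i], 0.003)
    if (design$baseline_amplitude > 0) {
      u <- (ppm - lo) / (hi - lo)
      s <- s + design$baseline_amplitude *
        (base_coef[i, 1] + base_coef[i, 2] * u + base_coef[i, 3] * sinpi(u))
    }
    intens[i, ] <- s
  }
  if (!is.null(noise)) intens <- intens + noise

  structure(
    list(
      ppm = ppm, intensities = intens,
      samples = tibble::tibble(sample_id = sample_ids, group = groups),
      truth = list(concentrations = conc, dilutions = dil, jitter = jit,
                   calibration = calib),
      grid_spacing = dp
    ),
    class = "nmr_spectra"
  )
}

#' @export
print.nmr_spectra <- function(x, ...) {
  cat(sprintf("<nmr_spectra> %d samples x %d points, %.3f..%.3f ppm, %d groups\n",
              nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm),
              length(unique(x$samples$group))))
  invisible(x)
}

#' Simulate phenotype parameters from ground-truth concentrations
#'
#' Emulates the clinical-chemistry, expression and outcome panel measured
#' alongside the spectra: each parameter is a sparse linear combination of
#' metabolite concentrations plus Gaussian noise. The mixing matrix is
#' returned so network-recovery tests have a ground truth.
#'
#' @param truth_concentrations Samples x metabolites matrix (e.g.
#'   `cohort$truth$concentrations`).
#' @param mixing Optional parameters x metabolites matrix; if `NULL` a
#'   random sparse matrix is drawn (1-3 contributing metabolites per
#'   parameter, weights of either sign).
#' @param n_parameters Number of parameters when `mixing` is drawn.
#' @param noise_sd Gaussian noise sd added to each parameter, on the scale
#'   of that parameter's noiseless sd.
#' @param seed Integer seed.
#' @return List with `parameters` (tibble, `sample_id` plus one column per
#'   parameter) and `mixing` (parameters x metabolites matrix).
#' @export
simulate_phenotypes <- function(truth_concentrations, mixing = NULL,
                                n_parameters = 6L, noise_sd = 0, seed = 1L) {
  abort_if(is.null(truth_concentrations) || !nrow(truth_concentrations),
           "truth concentrations are empty")
  conc <- as.matrix(truth_concentrations)
  mets <- colnames(conc)
  default_names <- c("SOD_like", "MDA_like", "GSH_like", "score_like",
                     "Nrf2_expr_like", "HO1_expr_like")
  with_seed(seed, {
    if (is.null(mixing)) {
      mixing <- matrix(0, n_parameters, ncol(conc))
      colnames(mixing) <- mets
      rownames(mixing) <- if (n_parameters <= length(default_names)) {
        default_names[seq_len(n_parameters)]
      } else {
        sprintf("param_%02d", seq_len(n_parameters))
      }
      for (k in seq_len(n_parameters)) {
        nk <- sample(1:3, 1)
        cols <- sample(ncol(conc), nk)
        mixing[k, cols] <- stats::runif(nk, 0.5, 2) * sample(c(-1, 1), nk, TRUE)
      }
    } else {
      mixing <- as.matrix(mixing)
      abort_if(ncol(mixing) != ncol(conc),
               "mixing has %d columns but truth has %d metabolites",
               ncol(mixing), ncol(conc))
      if (is.null(rownames(mixing))) {
        rownames(mixing) <- sprintf("param_%02d", seq_len(nrow(mixing)))
      }
    }
    vals <- conc %*% t(mixing)
    if (noise_sd > 0) {
      sds <- apply(vals, 2, stats::sd)
      vals <- vals + matrix(stats::rnorm(length(vals)), nrow(vals)) *
        rep(noise_sd * sds, each = nrow(vals))
    }
  })
  params <- tibble::as_tibble(vals)
  params <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(conc) %||%
                     sprintf("S%03d", seq_len(nrow(conc)))),
    params
  )
  list(parameters = params, mixing = mixing)
}
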