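# Shared builders for desk-scale test cohorts. Coarse grids keep tests
# fast; bucket width is widened accordingly so bins stay non-empty.

tiny_library <- function(metabolites = NULL) {
  lib <- build_metabolite_library("cerebrum")
  if (!is.null(metabolites)) lib <- lib[lib$metabolite %in% metabolites, ]
  lib
}

# One-metabolite template with a single isolated unit-area peak.
single_peak_library <- function(center = 3, width = 0.003, base_area = 1) {
  structure(
    tibble::tibble(metabolite = "probe", center_ppm = center,
                   relative_area = 1, linewidth_ppm = width,
                   base_area = base_area),
    class = c("nmr_library", class(tibble::tibble()))
  )
}

quick_cohort <- function(groups = c("sham", "MCAO"), n = 5L, seed = 1L,
                         effects = NULL, noise_sd = 0, dilution_log_sd = 0,
                         conc_log_sd = 0.2, library = NULL,
                         n_points = 4096L, ...) {
  lib <- library %||% tiny_library()
  des <- cohort_design(groups = groups, n_per_group = n, effects = effects,
                       noise_sd = noise_sd, dilution_log_sd = dilution_log_sd,
                       conc_log_sd = conc_log_sd, seed = seed, ...)
  simulate_cohort(des, lib, n_points = n_points)
}

# Hand-built spectra object for exactly controlled matrices.
manual_spectra <- function(intensities, ppm, groups = NULL) {
  n <- nrow(intensities)
  structure(
    list(ppm = ppm, intensities = intensities,
         samples = tibble::tibble(
           sample_id = sprintf("S%03d", seq_len(n)),
           group = groups %||% rep("g", n)),
         truth = NULL, grid_spacing = abs(ppm[1] - ppm[2])),
    class = "nmr_spectra"
  )
}

# Gaussian class-structured matrix: planted mean shift on `signal_bins`.
planted_matrix <- function(n_per_group = 10L, p = 30L, shift = 1,
                           signal_bins = 1:3, noise_sd = 1, seed = 1L) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_group * p, sd = noise_sd), 2 * n_per_group, p)
    x[seq_len(n_per_group), signal_bins] <-
      x[seq_len(n_per_group), signal_bins] + shift
    list(x = x, groups = rep(c("a", "b"), each = n_per_group))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
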