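# Delimited-text input/output for spectra and bucket tables, with JSON
# sidecars for the metadata that a flat matrix cannot carry.

sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Write a spectrum matrix as delimited text
#'
#' First row is the ppm axis, one subsequent row per sample (first column
#' the sample id); a companion `<file>.meta.tsv` carries sample ids and
#' group labels.
#'
#' @param spectra An `nmr_spectra`.
#' @param path Output file path (tab-delimited).
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(spectra, path) {
  abort_if(!inherits(spectra, "nmr_spectra"), "spectra must be an nmr_spectra")
  m <- rbind(ppm = spectra$ppm, spectra$intensities)
  df <- data.frame(sample_id = c("ppm", spectra$samples$sample_id), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(spectra$samples, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum matrix written by [write_spectra()]
#'
#' Accepts comma- or tab-delimited files (sniffed from the first line).
#'
#' @param path File path.
#' @return An `nmr_spectra` (without ground truth).
#' @export
read_spectra <- function(path) {
  abort_if(!file.exists(path), "file '%s' does not exist", path)
  sep <- sniff_sep(path)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE)
  ppm <- as.numeric(raw[1L, -1L])
  ids <- as.character(raw[-1L, 1L])
  intens <- as.matrix(raw[-1L, -1L, drop = FALSE])
  storage.mode(intens) <- "double"
  dimnames(intens) <- list(ids, NULL)
  meta_path <- paste0(path, ".meta.tsv")
  samples <- if (file.exists(meta_path)) {
    tibble::as_tibble(utils::read.delim(meta_path,
                                        colClasses = "character"))
  } else {
    tibble::tibble(sample_id = ids, group = NA_character_)
  }
  structure(
    list(ppm = ppm, intensities = intens,
         samples = samples[match(ids, samples$sample_id), ],
         truth = NULL, grid_spacing = abs(ppm[1] - ppm[2])),
    class = "nmr_spectra"
  )
}

#' Write a bucket table with a JSON sidecar
#'
#' The matrix goes to `<path>` (tab-delimited, bin centers as header); bin
#' edges, excluded regions, group labels and any PQN factors go to
#' `<path>.json`.
#'
#' @param bucket_table A `bucket_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bucket_table <- function(bucket_table, path) {
  abort_if(!inherits(bucket_table, "bucket_table"),
           "bucket_table must be a bucket_table")
  df <- data.frame(sample_id = bucket_table$samples$sample_id,
                   bucket_table$matrix, check.names = FALSE)
  names(df)[-1L] <- sprintf("%.5f", bucket_table$bin_centers)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    bin_centers = bucket_table$bin_centers,
    bin_edges = bucket_table$bin_edges,
    excluded_regions = bucket_table$excluded_regions,
    width = bucket_table$width,
    samples = bucket_table$samples,
    pqn_factors = bucket_table$pqn_factors
  )
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a bucket table written by [write_bucket_table()]
#'
#' @param path File path (the `<path>.json` sidecar must sit beside it).
#' @return A `bucket_table`.
#' @export
read_bucket_table <- function(path) {
  abort_if(!file.exists(path), "file '%s' does not exist", path)
  side_path <- paste0(path, ".json")
  abort_if(!file.exists(side_path), "sidecar '%s' is missing", side_path)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  edges <- as.matrix(side$bin_edges)
  colnames(edges) <- c("lo", "hi")
  excl <- side$excluded_regions
  if (is.matrix(excl)) excl <- lapply(seq_len(nrow(excl)), function(i) excl[i, ])
  structure(
    list(matrix = m, bin_centers = side$bin_centers, bin_edges = edges,
         excluded_regions = excl %||% list(), width = side$width,
         samples = tibble::as_tibble(side$samples),
         pqn_factors = if (!is.null(side$pqn_factors))
           tibble::as_tibble(side$pqn_factors) else NULL),
    class = "bucket_table"
  )
}
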