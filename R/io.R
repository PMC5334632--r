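# Reading and writing the pipeline's interchange formats: runs as JSON
# (gzip-capable), feature tables and bioactivity as CSV, plus optional
# import of centroided mzML through the mzR backend.

run_connection <- function(path, open) {
  if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, open)
  else file(path, open)
}

#' Write an MSE run to the JSON spectral format
#'
#' Schema: `{sample_id, metadata, spectra: [{rt, function, mz: [], intensity: []}]}`.
#' Paths ending in `.gz` are gzip-compressed. Full numeric precision is
#' retained, so the round trip is lossless and deterministic.
#'
#' @param run An `mse_run`.
#' @param path Output path (`.json` or `.json.gz`).
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "mse_run"))
  doc <- list(
    sample_id = run$sample_id,
    metadata = run$metadata,
    spectra = lapply(run$spectra, function(s)
      list(rt = s$rt, `function` = s$fn, mz = s$mz, intensity = s$intensity))
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  con <- run_connection(path, "wb")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Read an MSE run written by [write_run()]
#'
#' @param path Input path.
#' @return An `mse_run`.
#' @export
read_run <- function(path) {
  con <- run_connection(path, "rb")
  on.exit(close(con))
  doc <- jsonlite::fromJSON(readLines(con, warn = FALSE),
                            simplifyVector = FALSE)
  for (field in c("sample_id", "spectra"))
    if (is.null(doc[[field]]))
      stop("malformed run file: missing '", field, "'")
  spectra <- lapply(seq_along(doc$spectra), function(i) {
    s <- doc$spectra[[i]]
    if (is.null(s$rt) || is.null(s$`function`))
      stop("malformed run file: spectrum ", i, " lacks rt or function")
    mz <- as.numeric(unlist(s$mz))
    int <- as.numeric(unlist(s$intensity))
    if (length(mz) != length(int))
      stop("malformed run file: spectrum ", i,
           " has mismatched mz/intensity lengths")
    if (is.unsorted(mz, strictly = TRUE) && length(mz) > 1)
      stop("malformed run file: spectrum ", i, " mz not strictly ascending")
    list(rt = s$rt, fn = s$`function`, mz = mz, intensity = int)
  })
  run <- list(sample_id = doc$sample_id, metadata = doc$metadata,
              spectra = spectra)
  class(run) <- "mse_run"
  run
}

#' Write a feature table to CSV
#'
#' Columns: feature_id, mz, rt, then one column per sample.
#'
#' @param ft A `feature_table`.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  out <- cbind(ft$features, as.data.frame(t(ft$matrix)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input CSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("feature_id", "mz", "rt")
  if (!all(needed %in% names(tab)))
    stop("malformed feature table: needs columns ",
         paste(needed, collapse = ", "))
  sample_cols <- setdiff(names(tab), needed)
  mat <- t(as.matrix(tab[, sample_cols, drop = FALSE]))
  colnames(mat) <- tab$feature_id
  out <- list(features = tab[, needed], matrix = mat,
              sample_ids = sample_cols)
  class(out) <- "feature_table"
  out
}

#' Read a bioactivity (cell viability) CSV
#'
#' Expects columns `sample_id` and `viability_percent` (% viability of
#' solvent-treated control cells).
#'
#' @param path Input CSV path.
#' @return Data frame with one record per sample.
#' @export
read_bioactivity <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "viability_percent") %in% names(tab)))
    stop("malformed bioactivity file: needs sample_id, viability_percent")
  tab$viability_percent <- suppressWarnings(as.numeric(tab$viability_percent))
  bad <- which(is.na(tab$viability_percent) | tab$viability_percent < 0)
  if (length(bad))
    stop("malformed bioactivity record at row ", bad[1],
         " (sample ", tab$sample_id[bad[1]], "): missing or negative viability")
  tab
}

#' Write a bioactivity table to CSV
#'
#' @param bio Data frame with `sample_id` and `viability_percent`.
#' @param path Output CSV path.
#' @export
write_bioactivity <- function(bio, path) {
  utils::write.csv(bio[, c("sample_id", "viability_percent")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Import a centroided mzML file as an MSE run
#'
#' Optional convenience for real acquisitions; requires the `mzR` package.
#' Spectra are assigned to the low- or high-energy function by their MS
#' level (level 1 to function 1, level >= 2 to function 2), which matches
#' how two-function data-independent acquisitions are commonly exported.
#'
#' @param path mzML file path.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return An `mse_run`.
#' @export
read_mzml <- function(path, sample_id = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML import requires the 'mzR' package")
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    pk <- mzR::peaks(ms, i)
    o <- order(pk[, 1])
    list(rt = hdr$retentionTime[i] / 60,
         fn = if (hdr$msLevel[i] <= 1) 1L else 2L,
         mz = pk[o, 1], intensity = pk[o, 2])
  })
  run <- list(sample_id = sample_id %||% basename(path),
              metadata = list(source = path),
              spectra = spectra)
  class(run) <- "mse_run"
  run
}
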