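#' Write a spectrum as two-column delimited text
#'
#' Header line `wavenumber,intensity`, ascending wavenumber.
#'
#' @param s Spectrum tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  s <- as_spectrum_tbl(s)
  utils::write.csv(
    data.frame(wavenumber = s$wavenumber, intensity = s$intensity),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a spectrum from two-column delimited text
#'
#' Validates a strictly increasing numeric wavenumber axis; malformed
#' rows are reported with their line number.
#'
#' @param path File path (CSV with header `wavenumber,intensity`).
#' @return A spectrum tibble.
#' @export
read_spectrum <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (ncol(raw) < 2) abort("spectrum file must have two columns")
  wn <- suppressWarnings(as.numeric(raw[[1]]))
  ii <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(!is.finite(wn) | !is.finite(ii))
  if (length(bad)) {
    abort(sprintf("malformed row at line %d of '%s'", bad[1] + 1L, path))
  }
  if (is.unsorted(wn, strictly = TRUE)) {
    abort(sprintf("wavenumber axis in '%s' is not strictly increasing", path))
  }
  new_spectrum(wn, ii)
}

#' Write a dataset manifest as JSON
#'
#' @param manifest Tibble with columns `id`, `category`, `split` and
#'   optionally `path`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest from JSON
#'
#' Validates category and split tokens.
#'
#' @param path Manifest JSON file.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  m <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  bad <- setdiff(unique(m$category), .categories)
  if (length(bad)) abort(sprintf("unknown category token '%s'", bad[1]))
  bad_split <- setdiff(unique(m$split), c("train", "val", "test"))
  if (length(bad_split)) {
    abort(sprintf("unknown split token '%s'", bad_split[1]))
  }
  m
}

#' Write prototype spectra as a delimited table
#'
#' One column per component on the resampled feature axis.
#'
#' @param prototypes L x K prototype matrix.
#' @param axis Feature wavenumber axis (length L).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prototypes <- function(prototypes, axis, path) {
  df <- data.frame(wavenumber = axis, prototypes)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read prototype spectra written by [write_prototypes()]
#'
#' @param path CSV path.
#' @return A list with `prototypes` (L x K matrix) and `axis`.
#' @export
read_prototypes <- function(path) {
  df <- utils::read.csv(path)
  list(
    prototypes = as.matrix(df[, setdiff(names(df), "wavenumber"),
                              drop = FALSE]),
    axis = df$wavenumber
  )
}
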