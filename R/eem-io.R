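#' Read an EEM from a delimited wide-matrix file
#'
#' Expects emission wavelengths in the first column and excitation
#' wavelengths in the header row (Aqualog-style wide export, one file per
#' sample). A non-numeric corner cell (e.g. "Sample") is ignored. The
#' delimiter is auto-detected from the extension: `.csv` comma, anything
#' else tab. Descending wavelength axes are reversed so the returned object
#' satisfies the ascending-grid invariant.
#'
#' @param path File path.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param dialect Only `"wide_matrix"` is supported.
#' @return An [eem()] with an empty correction set.
#' @export
load_eem_csv <- function(path, sample_id = NULL, dialect = "wide_matrix") {
  dialect <- match.arg(dialect, "wide_matrix")
  if (!file.exists(path)) {
    flk_error(paste("no such file:", path), "fdomlink_format_error")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    flk_error(paste("empty or header-only EEM file:", path),
              "fdomlink_format_error")
  }
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    flk_error(sprintf("ragged EEM file %s: row %d has %d fields, expected %d",
                      path, bad, widths[bad], widths[1]), "fdomlink_format_error")
  }
  header <- trimws(cells[[1]])
  ex <- suppressWarnings(as.numeric(header))
  corner_skipped <- is.na(ex[1])
  if (corner_skipped) ex <- ex[-1]
  if (anyNA(ex)) {
    flk_error(sprintf("non-numeric excitation header in %s (column %d)",
                      path, which(is.na(ex))[1] + corner_skipped),
              "fdomlink_format_error")
  }
  body <- cells[-1]
  n_fields <- widths[1]
  if (n_fields != length(ex) + 1L) {
    flk_error(sprintf("EEM file %s: %d data columns but %d excitation labels",
                      path, n_fields - 1L, length(ex)), "fdomlink_format_error")
  }
  em <- numeric(length(body))
  intensity <- matrix(NA_real_, length(body), length(ex))
  for (i in seq_along(body)) {
    raw <- trimws(body[[i]])
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals) & !(toupper(raw) %in% c("NA", "NAN", "")))
    if (length(bad)) {
      flk_error(sprintf("non-numeric cell '%s' in %s at row %d, column %d",
                        raw[bad[1]], path, i + 1L, bad[1]),
                "fdomlink_format_error")
    }
    em[i] <- vals[1]
    intensity[i, ] <- vals[-1]
  }
  if (anyNA(em)) {
    flk_error(sprintf("non-numeric emission wavelength in %s at row %d",
                      path, which(is.na(em))[1] + 1L), "fdomlink_format_error")
  }
  # reorder to ascending axes
  if (is.unsorted(em, strictly = FALSE)) {
    o <- order(em); em <- em[o]; intensity <- intensity[o, , drop = FALSE]
  }
  if (is.unsorted(ex, strictly = FALSE)) {
    o <- order(ex); ex <- ex[o]; intensity <- intensity[, o, drop = FALSE]
  }
  if (anyDuplicated(em) || anyDuplicated(ex)) {
    flk_error(paste("duplicate wavelengths in", path), "fdomlink_format_error")
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  eem(sample_id, ex, em, intensity)
}

#' Write an EEM as a delimited wide matrix
#'
#' Inverse of [load_eem_csv()]: the round trip preserves wavelengths and
#' intensities bit-exactly (values are written with full precision).
#'
#' @param x An [eem()].
#' @param path Output path; `.csv` writes commas, anything else tabs.
#' @export
write_eem_csv <- function(x, path) {
  validate_eem(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  header <- paste(c("Sample", fmt(x$ex_nm)), collapse = sep)
  rows <- vapply(seq_along(x$em_nm), function(i) {
    paste(c(fmt(x$em_nm[i]), fmt(x$intensity[i, ])), collapse = sep)
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a two-column absorbance spectrum (wavelength nm, decadic absorbance)
#'
#' @param path CSV/TSV path with columns `wl_nm` and `absorbance` (header
#'   optional; the first two columns are used).
#' @param sample_id Sample id; defaults to file name.
#' @param pathlength_cm Cuvette path length, cm.
#' @return An [absorbance_spectrum()].
#' @export
load_absorbance_csv <- function(path, sample_id = NULL, pathlength_cm = 1) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), sep, fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[1])))
  tab <- utils::read.table(path, sep = sep, header = has_header)
  if (ncol(tab) < 2L) {
    flk_error(paste("absorbance file needs two columns:", path),
              "fdomlink_format_error")
  }
  wl <- as.numeric(tab[[1]]); a <- as.numeric(tab[[2]])
  o <- order(wl)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  absorbance_spectrum(sample_id, wl[o], a[o], pathlength_cm)
}

#' Read a sample metadata table (TSV)
#'
#' Mandatory columns: `sample_id`, `matrix_type`, `group`, `doc_mg_per_L`;
#' any further columns are carried along as environmental variables.
#'
#' @param path TSV path.
#' @return A validated `data.frame`.
#' @export
load_metadata_tsv <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "matrix_type", "group", "doc_mg_per_L")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    flk_error(paste("metadata missing columns:", paste(missing, collapse = ", ")),
              "fdomlink_format_error")
  }
  validate_sample_meta(meta)
}
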