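#' Excitation-emission matrix (EEM) objects
#'
#' An `eem` holds one sample's fluorescence intensity surface over an
#' excitation x emission wavelength grid, together with the ordered set of
#' preprocessing corrections already applied to it. Intensities are stored
#' with emission wavelengths in rows and excitation wavelengths in columns.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param ex_nm Strictly ascending numeric vector of excitation wavelengths (nm).
#' @param em_nm Strictly ascending numeric vector of emission wavelengths (nm).
#' @param intensity Numeric matrix, `length(em_nm)` rows x `length(ex_nm)`
#'   columns. Raw counts or Raman units; `NA` marks excised/missing cells.
#' @param corrections Character vector, subset of
#'   `c("blank_subtracted", "ife_corrected", "raman_normalized",
#'   "scatter_excised", "trimmed")`, each at most once.
#' @param units `"arbitrary"` or `"RU"`; `"RU"` exactly when
#'   `"raman_normalized"` is among the corrections.
#' @return An object of class `eem`.
#' @export
eem <- function(sample_id, ex_nm, em_nm, intensity,
                corrections = character(), units = "arbitrary") {
  obj <- structure(
    list(sample_id = as.character(sample_id),
         ex_nm = as.numeric(ex_nm), em_nm = as.numeric(em_nm),
         intensity = as.matrix(intensity),
         corrections = as.character(corrections), units = units),
    class = "eem")
  validate_eem(obj)
  obj
}

EEM_CORRECTIONS <- c("blank_subtracted", "ife_corrected", "raman_normalized",
                     "scatter_excised", "trimmed")

validate_eem <- function(x) {
  if (!identical(dim(x$intensity), c(length(x$em_nm), length(x$ex_nm)))) {
    flk_error(sprintf(
      "intensity is %d x %d but grid implies %d emission x %d excitation",
      nrow(x$intensity), ncol(x$intensity), length(x$em_nm), length(x$ex_nm)),
      "fdomlink_shape_error")
  }
  if (!all(is.finite(x$ex_nm)) || !all(is.finite(x$em_nm)) ||
      any(x$ex_nm <= 0) || any(x$em_nm <= 0)) {
    flk_error("wavelengths must be finite and positive", "fdomlink_format_error")
  }
  if (!is_strictly_ascending(x$ex_nm) || !is_strictly_ascending(x$em_nm)) {
    flk_error("wavelengths must be strictly ascending", "fdomlink_format_error")
  }
  if (anyDuplicated(x$corrections)) {
    flk_error("duplicate correction flag", "fdomlink_state_error")
  }
  if (!all(x$corrections %in% EEM_CORRECTIONS)) {
    flk_error("unknown correction flag", "fdomlink_state_error")
  }
  if (!x$units %in% c("arbitrary", "RU")) {
    flk_error("units must be 'arbitrary' or 'RU'", "fdomlink_state_error")
  }
  ru <- "raman_normalized" %in% x$corrections
  if (ru != identical(x$units, "RU")) {
    flk_error("units must be 'RU' iff raman_normalized was applied",
              "fdomlink_state_error")
  }
  invisible(x)
}

# add a correction flag, refusing re-application
add_correction <- function(x, flag) {
  if (flag %in% x$corrections) {
    flk_error(sprintf("correction '%s' already applied to sample '%s'",
                      flag, x$sample_id), "fdomlink_state_error")
  }
  x$corrections <- c(x$corrections, flag)
  x
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> sample '%s': %d em x %d ex (%g-%g / %g-%g nm), units %s\n",
              x$sample_id, length(x$em_nm), length(x$ex_nm),
              min(x$em_nm), max(x$em_nm), min(x$ex_nm), max(x$ex_nm), x$units))
  cat("  corrections:", if (length(x$corrections)) paste(x$corrections, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Absorbance spectrum object
#'
#' Decadic absorbance (dimensionless, instrument path `pathlength_cm`)
#' on a strictly ascending wavelength grid, typically 230-800 nm at 1 nm.
#'
#' @param sample_id Character scalar.
#' @param wl_nm Strictly ascending wavelengths (nm).
#' @param absorbance Finite decadic absorbance values.
#' @param pathlength_cm Cuvette path length in cm (default 1).
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(sample_id, wl_nm, absorbance, pathlength_cm = 1) {
  wl_nm <- as.numeric(wl_nm); absorbance <- as.numeric(absorbance)
  if (length(wl_nm) != length(absorbance)) {
    flk_error("wavelength and absorbance lengths differ", "fdomlink_shape_error")
  }
  if (!is_strictly_ascending(wl_nm)) {
    flk_error("absorbance wavelengths must be strictly ascending",
              "fdomlink_format_error")
  }
  if (!all(is.finite(absorbance))) {
    flk_error("absorbance must be finite", "fdomlink_format_error")
  }
  if (!is.numeric(pathlength_cm) || pathlength_cm <= 0) {
    flk_error("pathlength must be > 0", "fdomlink_argument_error")
  }
  structure(list(sample_id = as.character(sample_id), wl_nm = wl_nm,
                 absorbance = absorbance, pathlength_cm = pathlength_cm),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("<absorbance_spectrum> '%s': %d points %g-%g nm, path %g cm\n",
              x$sample_id, length(x$wl_nm), min(x$wl_nm), max(x$wl_nm),
              x$pathlength_cm))
  invisible(x)
}

#' EEM dataset: a stack of EEMs on a shared grid plus sample metadata
#'
#' @param eems List of [eem()] objects sharing identical `ex_nm` and `em_nm`.
#' @param meta Optional `data.frame` of sample metadata with a `sample_id`
#'   column covering every EEM. Conventional columns: `matrix_type`
#'   (`"water"`/`"sediment"`), `group` (`"HH"`/`"LH"`/`"R"`), `doc_mg_per_L`,
#'   plus free-form environmental variables.
#' @return An object of class `eem_dataset`.
#' @export
eem_dataset <- function(eems, meta = NULL) {
  if (!length(eems)) flk_error("empty EEM list", "fdomlink_argument_error")
  g <- eems[[1]]
  for (e in eems) {
    validate_eem(e)
    if (length(e$ex_nm) != length(g$ex_nm) || length(e$em_nm) != length(g$em_nm) ||
        max(abs(e$ex_nm - g$ex_nm)) > WL_TOL || max(abs(e$em_nm - g$em_nm)) > WL_TOL) {
      flk_error(sprintf("sample '%s' is not on the shared grid; harmonize first",
                        e$sample_id), "fdomlink_shape_error")
    }
  }
  ids <- vapply(eems, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) flk_error("duplicate sample ids", "fdomlink_format_error")
  names(eems) <- ids
  if (!is.null(meta)) {
    meta <- validate_sample_meta(meta)
    missing <- setdiff(ids, meta$sample_id)
    if (length(missing)) {
      flk_error(paste("samples missing from metadata:",
                      paste(missing, collapse = ", ")), "fdomlink_format_error")
    }
  }
  structure(list(eems = eems, meta = meta, ex_nm = g$ex_nm, em_nm = g$em_nm,
                 sample_ids = ids),
            class = "eem_dataset")
}

validate_sample_meta <- function(meta) {
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% names(meta)) {
    flk_error("metadata lacks a sample_id column", "fdomlink_format_error")
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    flk_error("duplicate sample_id in metadata", "fdomlink_format_error")
  }
  if ("matrix_type" %in% names(meta) &&
      !all(meta$matrix_type %in% c("water", "sediment"))) {
    flk_error("matrix_type must be 'water' or 'sediment'", "fdomlink_format_error")
  }
  if ("group" %in% names(meta) && !all(meta$group %in% c("HH", "LH", "R"))) {
    flk_error("group must be one of HH, LH, R", "fdomlink_format_error")
  }
  if ("doc_mg_per_L" %in% names(meta)) {
    doc <- meta$doc_mg_per_L
    if (any(!is.na(doc) & doc <= 0)) {
      flk_error("doc_mg_per_L must be positive where present",
                "fdomlink_format_error")
    }
  }
  meta
}

#' @export
print.eem_dataset <- function(x, ...) {
  cat(sprintf("<eem_dataset> %d samples, grid %d em x %d ex\n",
              length(x$eems), length(x$em_nm), length(x$ex_nm)))
  invisible(x)
}

# stack dataset into an em x ex x sample array
eem_array <- function(ds) {
  arr <- array(NA_real_, dim = c(length(ds$em_nm), length(ds$ex_nm),
                                 length(ds$eems)))
  for (s in seq_along(ds$eems)) arr[, , s] <- ds$eems[[s]]$intensity
  dimnames(arr) <- list(NULL, NULL, ds$sample_ids)
  arr
}
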