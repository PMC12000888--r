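#' Subtract a blank (Milli-Q water) EEM
#'
#' Elementwise subtraction of a blank measured on the same grid. Negative
#' results are kept, not clamped, so the step stays invertible; PARAFAC can
#' floor them later via its own option.
#'
#' @param x Sample [eem()].
#' @param blank Blank [eem()] on the identical grid, itself not
#'   blank-subtracted.
#' @return The corrected EEM with flag `blank_subtracted` appended.
#' @export
subtract_blank <- function(x, blank) {
  validate_eem(x); validate_eem(blank)
  if ("blank_subtracted" %in% blank$corrections) {
    flk_error("blank must not itself be blank-subtracted", "fdomlink_state_error")
  }
  check_same_grid(x, blank)
  out <- add_correction(x, "blank_subtracted")
  out$intensity <- x$intensity - blank$intensity
  out
}

check_same_grid <- function(a, b) {
  if (length(a$ex_nm) != length(b$ex_nm) || length(a$em_nm) != length(b$em_nm) ||
      max(abs(a$ex_nm - b$ex_nm)) > WL_TOL || max(abs(a$em_nm - b$em_nm)) > WL_TOL) {
    flk_error(sprintf("grid mismatch between samples '%s' and '%s'",
                      a$sample_id, b$sample_id), "fdomlink_shape_error")
  }
  invisible(TRUE)
}

#' Inner-filter effect correction (absorbance method)
#'
#' Applies the standard absorbance-based correction
#' \deqn{F_{corr}(em, ex) = F_{obs}(em, ex) \times 10^{(A(ex) + A(em))/2}}
#' with absorbance interpolated linearly onto the EEM wavelengths and scaled
#' to a 1 cm path. Absorbance above 1.5 anywhere on the used range makes the
#' correction unreliable; a warning is issued (and recorded on the result as
#' attribute `ife_warning`).
#'
#' @param x [eem()] not yet inner-filter corrected.
#' @param abs_spec [absorbance_spectrum()] covering the full excitation and
#'   emission range of `x`.
#' @return Corrected EEM with flag `ife_corrected`.
#' @export
inner_filter_correct <- function(x, abs_spec) {
  validate_eem(x)
  out <- add_correction(x, "ife_corrected")
  a1cm <- abs_spec$absorbance / abs_spec$pathlength_cm
  a_ex <- interp_checked(abs_spec$wl_nm, a1cm, x$ex_nm, "absorbance")
  a_em <- interp_checked(abs_spec$wl_nm, a1cm, x$em_nm, "absorbance")
  warn <- max(c(a_ex, a_em)) > 1.5
  if (warn) {
    warning(sprintf("sample '%s': absorbance > 1.5 on the used range; %s",
                    x$sample_id, "inner-filter correction unreliable"),
            call. = FALSE)
  }
  factor <- 10 ^ (outer(a_em, a_ex, `+`) / 2)
  out$intensity <- x$intensity * factor
  attr(out, "ife_warning") <- warn
  out
}

#' Raman normalization to Raman units (RU)
#'
#' Divides all intensities by the area of the water Raman scatter peak,
#' computed as the trapezoidal integral of the blank's emission scan at a
#' reference excitation wavelength over an emission band (defaults: ex 350
#' nm, em 371-428 nm, the community convention - the source study names the
#' step but not the band).
#'
#' @param x [eem()] not yet Raman-normalized.
#' @param blank Blank [eem()] whose grid covers `ex_ref` and `em_band`.
#' @param ex_ref Reference excitation wavelength (nm).
#' @param em_band Length-2 numeric, emission integration band (nm).
#' @return List with elements `eem` (normalized, units `"RU"`, flag
#'   `raman_normalized`) and `raman_area` (the divisor).
#' @export
raman_normalize <- function(x, blank, ex_ref = 350, em_band = c(371, 428)) {
  validate_eem(x); validate_eem(blank)
  out <- add_correction(x, "raman_normalized")
  scan <- emission_scan_at(blank, ex_ref)
  area <- trapz_band(blank$em_nm, scan, em_band[1], em_band[2])
  if (!is.finite(area) || area <= 0) {
    flk_error(sprintf("Raman area %g is not positive; check the blank", area),
              "fdomlink_normalization_error")
  }
  out$intensity <- x$intensity / area
  out$units <- "RU"
  list(eem = out, raman_area = area)
}

# emission scan at an arbitrary excitation wavelength, linear in ex
emission_scan_at <- function(x, ex) {
  if (ex < min(x$ex_nm) - WL_TOL || ex > max(x$ex_nm) + WL_TOL) {
    flk_error(sprintf("excitation %g nm outside grid [%g, %g]",
                      ex, min(x$ex_nm), max(x$ex_nm)), "fdomlink_domain_error")
  }
  j <- which(abs(x$ex_nm - ex) <= WL_TOL)
  if (length(j)) return(x$intensity[, j[1]])
  hi <- which(x$ex_nm > ex)[1]
  lo <- hi - 1L
  w <- (ex - x$ex_nm[lo]) / (x$ex_nm[hi] - x$ex_nm[lo])
  (1 - w) * x$intensity[, lo] + w * x$intensity[, hi]
}

#' Excise Rayleigh/Raman scatter ridges and interpolate over them
#'
#' Removes first- and second-order Rayleigh and first-order Raman scatter
#' bands and refills them by 1-D linear interpolation along the emission
#' axis. For excitation `ex` (nm) the Raman emission line sits at
#' `1 / (1/ex - 0.00036)`. The physically signal-free sub-Rayleigh region
#' (`em < ex - w_ray1`) is zero-filled, not interpolated.
#'
#' @param x [eem()].
#' @param widths Named list of half-widths in nm:
#'   `rayleigh1` (default 10), `raman1` (default 5), `rayleigh2` (default 10).
#' @return EEM with flag `scatter_excised`; refilled cells are interpolated,
#'   cells outside the declared bands are untouched.
#' @export
excise_and_interpolate_scatter <- function(
    x, widths = list(rayleigh1 = 10, raman1 = 5, rayleigh2 = 10)) {
  validate_eem(x)
  w1 <- widths$rayleigh1 %||% 10
  wr <- widths$raman1 %||% 5
  w2 <- widths$rayleigh2 %||% 10
  if (any(c(w1, wr, w2) < 0)) {
    flk_error("scatter half-widths must be nonnegative", "fdomlink_argument_error")
  }
  out <- add_correction(x, "scatter_excised")
  em <- x$em_nm
  for (j in seq_along(x$ex_nm)) {
    ex <- x$ex_nm[j]
    raman_em <- 1 / (1 / ex - 0.00036)
    ridge <- (abs(em - ex) <= w1) | (abs(em - raman_em) <= wr) |
             (abs(em - 2 * ex) <= w2)
    below <- em < ex - w1 - WL_TOL
    support <- !ridge & !below & !is.na(x$intensity[, j])
    fill <- ridge & !below
    if (any(fill)) {
      if (sum(support) < 2L) {
        flk_error(sprintf(
          "cannot interpolate scatter at excitation %g nm: emission scan fully excised",
          ex), "fdomlink_interpolation_error")
      }
      out$intensity[fill, j] <-
        lin_interp_extrap(em[support], x$intensity[support, j], em[fill])
    }
    out$intensity[below, j] <- 0
  }
  out
}

#' Trim the wavelength grid before PARAFAC
#'
#' Retains emission wavelengths `<= em_max` and excitation wavelengths
#' `>= ex_min`. Defaults reproduce the usual trim for Aqualog data: long
#' emission (> 600 nm, signal-free) and short excitation (< 250 nm, noisy)
#' removed.
#'
#' @param x [eem()].
#' @param em_max Maximum emission wavelength kept (nm), default 600.
#' @param ex_min Minimum excitation wavelength kept (nm), default 250.
#' @return Trimmed EEM with flag `trimmed`.
#' @export
trim_wavelengths <- function(x, em_max = 600, ex_min = 250) {
  validate_eem(x)
  out <- add_correction(x, "trimmed")
  keep_em <- x$em_nm <= em_max + WL_TOL
  keep_ex <- x$ex_nm >= ex_min - WL_TOL
  if (sum(keep_em) < 2L || sum(keep_ex) < 2L) {
    flk_error(sprintf(
      "trim leaves %d emission and %d excitation wavelengths (need >= 2 each)",
      sum(keep_em), sum(keep_ex)), "fdomlink_trim_error")
  }
  out$em_nm <- x$em_nm[keep_em]
  out$ex_nm <- x$ex_nm[keep_ex]
  out$intensity <- x$intensity[keep_em, keep_ex, drop = FALSE]
  out
}

#' Harmonize a list of EEMs onto a shared grid
#'
#' Resamples every EEM by bilinear interpolation onto the intersection of
#' all wavelength ranges, discretized on the coarsest input grid (so EEMs
#' already on that grid are passed through unchanged at shared wavelengths).
#'
#' @param eems List of [eem()] objects with overlapping wavelength ranges.
#' @param meta Optional metadata `data.frame` (see [eem_dataset()]).
#' @return An [eem_dataset()].
#' @export
harmonize_grid <- function(eems, meta = NULL) {
  if (!length(eems)) flk_error("no EEMs given", "fdomlink_argument_error")
  rng <- function(get) c(max(vapply(eems, function(e) min(get(e)), 0)),
                         min(vapply(eems, function(e) max(get(e)), 0)))
  ex_r <- rng(function(e) e$ex_nm); em_r <- rng(function(e) e$em_nm)
  if (ex_r[1] > ex_r[2] + WL_TOL || em_r[1] > em_r[2] + WL_TOL) {
    flk_error("EEM wavelength ranges have empty intersection",
              "fdomlink_domain_error")
  }
  coarsest <- function(get) {
    sp <- vapply(eems, function(e) stats::median(diff(get(e))), 0)
    get(eems[[which.max(sp)]])
  }
  ex_t <- coarsest(function(e) e$ex_nm)
  em_t <- coarsest(function(e) e$em_nm)
  ex_t <- ex_t[ex_t >= ex_r[1] - WL_TOL & ex_t <= ex_r[2] + WL_TOL]
  em_t <- em_t[em_t >= em_r[1] - WL_TOL & em_t <= em_r[2] + WL_TOL]
  if (length(ex_t) < 2L || length(em_t) < 2L) {
    flk_error("shared grid has fewer than 2 wavelengths per axis",
              "fdomlink_domain_error")
  }
  resampled <- lapply(eems, function(e) {
    same <- length(e$ex_nm) == length(ex_t) && length(e$em_nm) == length(em_t) &&
      max(abs(e$ex_nm - ex_t)) <= WL_TOL && max(abs(e$em_nm - em_t)) <= WL_TOL
    if (same) return(e)
    # bilinear = two passes of 1-D linear interpolation
    tmp <- apply(e$intensity, 1, function(row)
      stats::approx(e$ex_nm, row, xout = ex_t, rule = 2)$y)
    tmp <- t(tmp)                            # em(old) x ex(target)
    fin <- apply(tmp, 2, function(col)
      stats::approx(e$em_nm, col, xout = em_t, rule = 2)$y)
    e$ex_nm <- ex_t; e$em_nm <- em_t
    e$intensity <- matrix(fin, length(em_t), length(ex_t))
    e
  })
  eem_dataset(resampled, meta)
}
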