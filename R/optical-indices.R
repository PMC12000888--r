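# bilinear point lookup on an EEM; errors if the wavelengths were trimmed away
eem_at <- function(x, ex, em) {
  scan <- emission_scan_at(x, ex)
  if (em < min(x$em_nm) - WL_TOL || em > max(x$em_nm) + WL_TOL) {
    flk_error(sprintf("emission %g nm outside grid [%g, %g]",
                      em, min(x$em_nm), max(x$em_nm)), "fdomlink_domain_error")
  }
  stats::approx(x$em_nm, scan, xout = em, rule = 2)$y
}

#' Fluorescence index (FI)
#'
#' Ratio of emission intensities at 470 nm and 520 nm under excitation at
#' 370 nm (corrected-instrument convention; the legacy 450/500 pair is
#' available via `em_pair`). FI below ~1.4 indicates predominantly
#' terrestrial FDOM; above ~1.9 endogenous/microbial FDOM.
#'
#' @param x A Raman-normalized [eem()] whose grid covers the wavelengths.
#' @param ex Excitation wavelength, default 370 nm.
#' @param em_pair Numerator/denominator emission wavelengths,
#'   default `c(470, 520)`.
#' @return Scalar FI.
#' @export
fluorescence_index <- function(x, ex = 370, em_pair = c(470, 520)) {
  num <- eem_at(x, ex, em_pair[1])
  den <- eem_at(x, ex, em_pair[2])
  if (!is.finite(den) || den == 0) {
    flk_error("FI undefined: zero denominator intensity",
              "fdomlink_undefined_index_error")
  }
  num / den
}

#' Biological index (BIX)
#'
#' Emission intensity at 380 nm over 430 nm under 310 nm excitation.
#' Higher BIX indicates greater recent biological/autochthonous input.
#'
#' @inheritParams fluorescence_index
#' @return Scalar BIX.
#' @export
biological_index <- function(x, ex = 310, em_pair = c(380, 430)) {
  num <- eem_at(x, ex, em_pair[1])
  den <- eem_at(x, ex, em_pair[2])
  if (!is.finite(den) || den == 0) {
    flk_error("BIX undefined: zero denominator intensity",
              "fdomlink_undefined_index_error")
  }
  num / den
}

#' Humification index (HIX)
#'
#' At 254 nm excitation, the humified band H sums emission over 435-480 nm
#' and the fresh band L over 300-345 nm; `zsolnay` (default) returns `H/L`
#' (unbounded), `ohno` returns `H/(H+L)` (in \[0, 1\]). Band sums use every
#' point of a 1 nm comb interpolated inside the closed bands, making the
#' index grid-independent.
#'
#' @param x An [eem()] covering 254 nm excitation and both emission bands.
#' @param variant `"zsolnay"` or `"ohno"`.
#' @return Scalar HIX.
#' @export
humification_index <- function(x, variant = c("zsolnay", "ohno")) {
  variant <- match.arg(variant)
  scan <- emission_scan_at(x, 254)
  band_sum <- function(lo, hi) {
    if (lo < min(x$em_nm) - WL_TOL || hi > max(x$em_nm) + WL_TOL) {
      flk_error(sprintf("HIX band [%g, %g] outside emission grid", lo, hi),
                "fdomlink_undefined_index_error")
    }
    comb <- seq(lo, hi, by = 1)
    sum(stats::approx(x$em_nm, scan, xout = comb, rule = 2)$y)
  }
  H <- band_sum(435, 480)
  L <- band_sum(300, 345)
  if (variant == "zsolnay") {
    if (L == 0) flk_error("HIX (zsolnay) undefined: L band sums to zero",
                          "fdomlink_undefined_index_error")
    H / L
  } else {
    if (H + L == 0) flk_error("HIX (ohno) undefined: H + L is zero",
                              "fdomlink_undefined_index_error")
    H / (H + L)
  }
}

#' SUVA254: DOC-normalized UV absorbance at 254 nm
#'
#' `(A(254) / pathlength_cm) * 100 / DOC`, in L mg^-1 m^-1. Values above
#' ~4 indicate predominantly hydrophobic (aromatic) DOM, below ~3
#' hydrophilic DOM.
#'
#' @param abs_spec An [absorbance_spectrum()] covering 254 nm.
#' @param doc_mg_per_L DOC concentration, mg/L, > 0.
#' @return Scalar SUVA254.
#' @export
suva254 <- function(abs_spec, doc_mg_per_L) {
  if (!is.numeric(doc_mg_per_L) || !is.finite(doc_mg_per_L) ||
      doc_mg_per_L <= 0) {
    flk_error("DOC must be a positive number", "fdomlink_argument_error")
  }
  a254 <- interp_checked(abs_spec$wl_nm, abs_spec$absorbance, 254, "absorbance")
  (a254 / abs_spec$pathlength_cm) * 100 / doc_mg_per_L
}

#' Absorbance spectral slope over a wavelength band
#'
#' Converts decadic absorbance to the Napierian absorption coefficient
#' `a = 2.303 * A / pathlength_m` and regresses `ln(a)` on wavelength within
#' the band; the slope S (nm^-1) is minus the regression coefficient.
#'
#' @param abs_spec An [absorbance_spectrum()].
#' @param band Length-2 numeric wavelength interval (nm) containing at least
#'   5 grid points with positive absorbance.
#' @return Scalar S in nm^-1.
#' @export
spectral_slope <- function(abs_spec, band) {
  keep <- abs_spec$wl_nm >= band[1] - WL_TOL & abs_spec$wl_nm <= band[2] + WL_TOL
  wl <- abs_spec$wl_nm[keep]
  if (length(wl) < 5L) {
    flk_error(sprintf("need >= 5 points in band [%g, %g], have %d",
                      band[1], band[2], length(wl)), "fdomlink_argument_error")
  }
  a <- 2.303 * abs_spec$absorbance[keep] / (abs_spec$pathlength_cm / 100)
  if (any(a <= 0)) {
    flk_error(paste("non-positive absorbance at",
                    paste(wl[a <= 0], collapse = ", "), "nm"),
              "fdomlink_log_domain_error")
  }
  -unname(stats::coef(stats::lm(log(a) ~ wl))[2])
}

#' Spectral slope ratio SR = S(275-295) / S(350-400)
#'
#' SR increases as DOM molecular weight decreases. A single-exponential
#' spectrum has SR exactly 1.
#'
#' @param abs_spec An [absorbance_spectrum()] covering both bands.
#' @return Scalar SR.
#' @export
slope_ratio <- function(abs_spec) {
  s1 <- spectral_slope(abs_spec, c(275, 295))
  s2 <- spectral_slope(abs_spec, c(350, 400))
  if (s2 == 0) {
    flk_error("SR undefined: S350-400 is zero", "fdomlink_undefined_index_error")
  }
  s1 / s2
}

#' All optical indices for one sample
#'
#' @param x Raman-normalized [eem()].
#' @param abs_spec [absorbance_spectrum()] for the same sample.
#' @param doc_mg_per_L DOC concentration (mg/L); `NA` skips SUVA254.
#' @param hix_variant Passed to [humification_index()].
#' @return One-row `data.frame` with `sample_id`, `FI`, `BIX`, `HIX`,
#'   `SUVA254`, `S275_295`, `S350_400`, `SR`.
#' @export
optical_indices <- function(x, abs_spec, doc_mg_per_L = NA,
                            hix_variant = "zsolnay") {
  data.frame(
    sample_id = x$sample_id,
    FI = fluorescence_index(x),
    BIX = biological_index(x),
    HIX = humification_index(x, hix_variant),
    SUVA254 = if (is.na(doc_mg_per_L)) NA_real_ else
      suva254(abs_spec, doc_mg_per_L),
    S275_295 = spectral_slope(abs_spec, c(275, 295)),
    S350_400 = spectral_slope(abs_spec, c(350, 400)),
    SR = slope_ratio(abs_spec),
    stringsAsFactors = FALSE)
}
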