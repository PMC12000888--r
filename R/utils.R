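# Internal helpers shared across modules.

WL_TOL <- 1e-6  # numeric tolerance (nm) for all wavelength comparisons

flk_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fdomlink_error", "error", "condition")))
}

#' @keywords internal
is_strictly_ascending <- function(x) all(diff(x) > 0)

# linear interpolation with hard coverage check
interp_checked <- function(x, y, xout, what = "value", class = "fdomlink_domain_error") {
  if (min(xout) < min(x) - WL_TOL || max(xout) > max(x) + WL_TOL) {
    flk_error(sprintf("%s coverage gap: need [%g, %g] nm but have [%g, %g] nm",
                      what, min(xout), max(xout), min(x), max(x)), class)
  }
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# trapezoidal integral of y(x) over [a, b], endpoints interpolated
trapz_band <- function(x, y, a, b) {
  if (a < min(x) - WL_TOL || b > max(x) + WL_TOL) {
    flk_error(sprintf("integration band [%g, %g] not covered by [%g, %g]",
                      a, b, min(x), max(x)), "fdomlink_domain_error")
  }
  keep <- x > a + WL_TOL & x < b - WL_TOL
  xs <- c(a, x[keep], b)
  ys <- stats::approx(x, y, xout = xs, rule = 2)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

# linear interpolation with linear (not constant) extrapolation at the ends
lin_interp_extrap <- function(x, y, xout) {
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  hi <- xout > x[n]
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

# columnwise khatri-rao product: col k = kron(u[, k], v[, k])
khatri_rao <- function(u, v) {
  k <- ncol(u)
  stopifnot(ncol(v) == k)
  m <- nrow(u); n <- nrow(v)
  u[rep(seq_len(m), each = n), , drop = FALSE] *
    v[rep(seq_len(n), times = m), , drop = FALSE]
}

# rowwise minima of d[, cols] without apply() overhead
rowmin_cols <- function(d, cols) {
  if (length(cols) == 1L) return(d[, cols])
  do.call(pmin, lapply(cols, function(j) d[, j]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
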