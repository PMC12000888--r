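#' Sloan neutral model predicted occurrence frequency
#'
#' Probability that a taxon with metacommunity mean relative abundance `p`
#' is detected (local relative abundance above the detection limit `d`) in a
#' local community of size `N` with immigration probability `m`, under the
#' stationary beta approximation of the neutral model:
#' `1 - I(d; N m p, N m (1 - p))` with `I` the regularized incomplete beta
#' function.
#'
#' @param p Mean relative abundance(s), each in (0, 1).
#' @param N Community size (reads per sample), > 0.
#' @param m Immigration (migration) probability in (0, 1].
#' @param d Detection limit as a relative abundance, in (0, 1).
#' @return Predicted occurrence frequency in `[0, 1]`, vectorized over `p`.
#' @export
ncm_predict <- function(p, N, m, d) {
  if (any(p <= 0 | p >= 1)) flk_error("p must lie in (0, 1)",
                                      "fdomlink_argument_error")
  if (N <= 0) flk_error("N must be > 0", "fdomlink_argument_error")
  if (m <= 0 || m > 1) flk_error("m must lie in (0, 1]",
                                 "fdomlink_argument_error")
  if (d <= 0 || d >= 1) flk_error("d must lie in (0, 1)",
                                  "fdomlink_argument_error")
  nm <- N * m
  1 - stats::pbeta(d, nm * p, nm * (1 - p))
}

#' Fit the Sloan neutral community model to a feature table
#'
#' Mean relative abundance per ASV is regressed (nonlinear least squares in
#' the single parameter m) against the observed occurrence frequency using
#' the neutral prediction [ncm_predict()]. `N` is the mean sample read
#' total, the detection limit defaults to `1/N`, and m is estimated over a
#' log-spaced candidate grid refined by golden-section search. The 95%
#' confidence band is a Wilson binomial interval around the predicted
#' frequency at n = number of samples; ASVs are partitioned as above /
#' neutral / below by CI exceedance.
#'
#' @param table A [feature_table()] (or counts matrix) with >= 10 ASVs
#'   present in >= 1 sample.
#' @param d Detection limit; default `1/N`.
#' @param conf Confidence level for the band (default 0.95).
#' @return An `ncm_fit`: list with `m`, `N`, `Nm`, `r2`, `d`, `n_samples`,
#'   and per-ASV `data.frame` `asv` (p, freq_obs, freq_pred, ci_low,
#'   ci_high, partition).
#' @export
ncm_fit <- function(table, d = NULL, conf = 0.95) {
  counts <- if (inherits(table, "feature_table")) table$counts else
    as.matrix(table)
  present <- rowSums(counts > 0) > 0
  counts <- counts[present, , drop = FALSE]
  if (nrow(counts) < 10L) {
    flk_error("NCM fit needs >= 10 ASVs present somewhere",
              "fdomlink_argument_error")
  }
  n_samples <- ncol(counts)
  N <- mean(colSums(counts))
  if (is.null(d)) d <- 1 / N
  rel <- sweep(counts, 2, colSums(counts), `/`)
  p <- rowMeans(rel)
  freq <- rowMeans(counts > 0)
  ok <- p > 0 & p < 1
  p <- p[ok]; freq <- freq[ok]
  sst <- sum((freq - mean(freq))^2)
  if (sst == 0) {
    flk_error("degenerate fit: occurrence frequency has no variation",
              "fdomlink_degenerate_fit_error")
  }
  sse_of <- function(m) sum((freq - ncm_predict(p, N, m, d))^2)
  grid <- 10^seq(-5, 0, length.out = 61)
  sses <- vapply(grid, sse_of, 0)
  i <- which.min(sses)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  m_hat <- golden_section(sse_of, lo, hi)
  sse <- sse_of(m_hat)
  pred <- ncm_predict(p, N, m_hat, d)
  ci <- wilson_interval(pred, n_samples, conf)
  partition <- ifelse(freq > ci$high, "above",
                      ifelse(freq < ci$low, "below", "neutral"))
  structure(list(
    m = m_hat, N = N, Nm = N * m_hat, r2 = 1 - sse / sst, d = d,
    n_samples = n_samples, conf = conf,
    asv = data.frame(asv_id = names(p), p = p, freq_obs = freq,
                     freq_pred = pred, ci_low = ci$low, ci_high = ci$high,
                     partition = partition, stringsAsFactors = FALSE,
                     row.names = NULL)),
    class = "ncm_fit")
}

# golden-section minimization on [lo, hi]
golden_section <- function(f, lo, hi, tol = 1e-10, max_iter = 200) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  for (i in seq_len(max_iter)) {
    if (b - a < tol) break
    if (fc < fd) { b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else { a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  (a + b) / 2
}

# Wilson score interval around proportion p at sample size n
wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("<ncm_fit> m = %.4g, N = %.1f, Nm = %.1f, R2 = %.3f (%d ASVs, %d samples)\n",
              x$m, x$N, x$Nm, x$r2, nrow(x$asv), x$n_samples))
  invisible(x)
}

#' Partition tallies of a neutral-model fit
#'
#' @param fit An `ncm_fit`.
#' @return Named integer vector `c(above, neutral, below)` summing to the
#'   number of fitted ASVs.
#' @export
ncm_partition_counts <- function(fit) {
  out <- c(above = sum(fit$asv$partition == "above"),
           neutral = sum(fit$asv$partition == "neutral"),
           below = sum(fit$asv$partition == "below"))
  out
}

#' Write an NCM fit (per-ASV CSV + JSON summary)
#'
#' @param fit An `ncm_fit`.
#' @param dir Output directory.
#' @export
write_ncm_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$asv, file.path(dir, "ncm_per_asv.csv"),
                   row.names = FALSE)
  pc <- ncm_partition_counts(fit)
  jsonlite::write_json(
    list(m = fit$m, N = fit$N, Nm = fit$Nm, r2 = fit$r2, d = fit$d,
         n_samples = fit$n_samples,
         partition_counts = as.list(pc)),
    file.path(dir, "ncm_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
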