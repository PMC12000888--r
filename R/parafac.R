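#' Nonnegative PARAFAC decomposition of an EEM stack
#'
#' Fits a K-component trilinear model to the emission x excitation x sample
#' tensor by hierarchical alternating least squares (HALS) with
#' nonnegativity on all three modes, taking the best of `n_starts` random
#' initializations by SSE. Missing cells (`NA`, e.g. unfilled scatter) are
#' excluded from both the updates and the SSE via expectation-maximization
#' imputation from the current model, which keeps the observed-cell loss
#' monotone non-increasing. Loadings are returned in the unit-maximum
#' convention (each excitation and emission loading column has maximum
#' exactly 1); scores absorb all intensity scale. Components are ordered by
#' ascending emission peak wavelength.
#'
#' @param ds An [eem_dataset()].
#' @param K Number of components (>= 1, <= every tensor dimension).
#' @param n_starts Random initializations (default 5).
#' @param max_iter Maximum ALS iterations per start (default 2500).
#' @param tol Relative SSE change convergence threshold (default 1e-8).
#' @param seed Integer RNG seed; the fit is deterministic given it.
#' @param normalize_samples Scale each sample slab to unit sum of squares
#'   before fitting to balance leverage between dim and bright samples
#'   (default `TRUE`); scores are un-normalized afterwards.
#' @param floor_negatives Clamp negative intensities (from blank
#'   subtraction) to 0 before fitting (default `TRUE`).
#' @return A `parafac_model`: list with `n_components`, `ex_loadings`
#'   (n_ex x K), `em_loadings` (n_em x K), `scores` (n_samples x K),
#'   `explained_variance`, `n_iterations`, `converged`, `sse`, `seed`,
#'   plus the grid (`ex_nm`, `em_nm`) and `sample_ids`.
#' @export
fit_parafac <- function(ds, K, n_starts = 5, max_iter = 2500, tol = 1e-8,
                        seed = 1, normalize_samples = TRUE,
                        floor_negatives = TRUE) {
  stopifnot(inherits(ds, "eem_dataset"))
  X <- eem_array(ds)
  dims <- dim(X)
  if (K < 1) flk_error("K must be >= 1", "fdomlink_argument_error")
  if (K > min(dims)) {
    flk_error(sprintf("K = %d exceeds smallest tensor dimension %d",
                      K, min(dims)), "fdomlink_rank_error")
  }
  if (dims[3] < K) flk_error("need at least K samples", "fdomlink_rank_error")
  if (floor_negatives) X[X < 0] <- 0
  norms <- rep(1, dims[3])
  if (normalize_samples) {
    for (s in seq_len(dims[3])) {
      ns <- sqrt(sum(X[, , s]^2, na.rm = TRUE))
      if (ns > 0) { norms[s] <- ns; X[, , s] <- X[, , s] / ns }
    }
  }
  obs <- !is.na(X)
  total_ss <- sum(X[obs]^2)
  if (total_ss == 0) flk_error("all-zero tensor", "fdomlink_argument_error")

  best <- NULL
  set.seed(as.integer(seed))
  for (st in seq_len(n_starts)) {
    fit <- parafac_als_single(X, obs, K, max_iter, tol)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }

  A <- best$A; B <- best$B; C <- best$C   # em, ex, sample factors
  # unit-maximum loading convention: scale into scores
  for (k in seq_len(K)) {
    ma <- max(A[, k]); mb <- max(B[, k])
    if (ma > 0) A[, k] <- A[, k] / ma else ma <- 1
    if (mb > 0) B[, k] <- B[, k] / mb else mb <- 1
    C[, k] <- C[, k] * ma * mb
  }
  C <- C * norms                          # undo per-sample normalization
  ord <- order(apply(A, 2, function(a) ds$em_nm[which.max(a)]),
               apply(B, 2, function(b) ds$ex_nm[which.max(b)]))
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]
  colnames(A) <- colnames(B) <- colnames(C) <- paste0("C", seq_len(K))
  rownames(C) <- ds$sample_ids
  structure(list(
    n_components = K, ex_loadings = B, em_loadings = A, scores = C,
    explained_variance = 1 - best$sse / total_ss,
    n_iterations = best$iter, converged = best$converged, sse = best$sse,
    seed = seed, ex_nm = ds$ex_nm, em_nm = ds$em_nm,
    sample_ids = ds$sample_ids, sample_norms = norms,
    normalize_samples = normalize_samples, loss_trace = best$trace),
    class = "parafac_model")
}

# one HALS run from a fresh random start; X may contain NA at !obs
parafac_als_single <- function(X, obs, K, max_iter, tol) {
  dims <- dim(X)
  I <- dims[1]; J <- dims[2]; S <- dims[3]
  any_missing <- !all(obs)
  A <- matrix(stats::runif(I * K, 0.1, 1), I, K)
  B <- matrix(stats::runif(J * K, 0.1, 1), J, K)
  C <- matrix(stats::runif(S * K, 0.1, 1), S, K)
  Ximp <- X
  if (any_missing) Ximp[!obs] <- mean(X[obs])
  X1 <- matrix(Ximp, I, J * S)
  X2 <- matrix(aperm(Ximp, c(2, 1, 3)), J, I * S)
  X3 <- matrix(aperm(Ximp, c(3, 1, 2)), S, I * J)
  sse_prev <- Inf; converged <- FALSE; it <- 0
  trace <- numeric(0)
  hals_update <- function(F_, P, G) {
    for (k in seq_len(K)) {
      gkk <- G[k, k]
      if (gkk < 1e-12) {               # dead component: reseed small
        F_[, k] <- stats::runif(nrow(F_), 0, 1e-3)
        next
      }
      F_[, k] <- pmax(0, F_[, k] + (P[, k] - F_ %*% G[, k]) / gkk)
    }
    F_
  }
  for (it in seq_len(max_iter)) {
    G <- crossprod(B) * crossprod(C)
    A <- hals_update(A, X1 %*% khatri_rao(C, B), G)
    G <- crossprod(A) * crossprod(C)
    B <- hals_update(B, X2 %*% khatri_rao(C, A), G)
    G <- crossprod(A) * crossprod(B)
    C <- hals_update(C, X3 %*% khatri_rao(B, A), G)
    Xhat1 <- A %*% t(khatri_rao(C, B))          # I x (J*S)
    if (any_missing) {
      Xhat <- array(Xhat1, dims)
      Ximp[!obs] <- Xhat[!obs]
      X1 <- matrix(Ximp, I, J * S)
      X2 <- matrix(aperm(Ximp, c(2, 1, 3)), J, I * S)
      X3 <- matrix(aperm(Ximp, c(3, 1, 2)), S, I * J)
      sse <- sum((X[obs] - Xhat[obs])^2)
    } else {
      sse <- sum((X1 - Xhat1)^2)
    }
    trace <- c(trace, sse)
    if (is.finite(sse_prev) &&
        (sse_prev - sse) <= tol * max(sse_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    sse_prev <- sse
  }
  list(A = A, B = B, C = C, sse = sse, iter = it, converged = converged,
       trace = trace)
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf(
    "<parafac_model> K = %d, %d samples, EV = %.4f, %s in %d iterations\n",
    x$n_components, nrow(x$scores), x$explained_variance,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Tucker congruence coefficient
#'
#' Cosine similarity `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`, the standard
#' loading-matching and split-half validation metric; lies in `[-1, 1]`.
#'
#' @param a,b Numeric vectors of equal length with nonzero norms.
#' @return Scalar congruence.
#' @export
tucker_congruence <- function(a, b) {
  if (length(a) != length(b)) {
    flk_error("vectors differ in length", "fdomlink_shape_error")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    flk_error("congruence undefined for a zero vector",
              "fdomlink_undefined_similarity_error")
  }
  sum(a * b) / (na * nb)
}

# greedy matching of components between two loading sets by the product of
# ex- and em-congruence; ties broken by component index
match_components <- function(exA, emA, exB, emB) {
  K <- ncol(exA)
  cong <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    cong[i, j] <- tucker_congruence(exA[, i], exB[, j]) *
                  tucker_congruence(emA[, i], emB[, j])
  }
  match <- integer(K); used <- logical(K)
  for (step in seq_len(K)) {
    m <- cong
    m[, used] <- -Inf
    m[match != 0, ] <- -Inf
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    match[ij[1]] <- ij[2]; used[ij[2]] <- TRUE
  }
  match
}

#' Scan PARAFAC model orders
#'
#' Fits one model per K with a shared seed policy and reports fit
#' diagnostics including the core consistency (CORCONDIA) computed from the
#' Tucker core of the fitted factors.
#'
#' @param ds An [eem_dataset()].
#' @param K_range Integer vector of component numbers, default `4:8`.
#' @param ... Passed to [fit_parafac()] (`n_starts`, `tol`, `seed`, ...).
#' @return `data.frame` with columns `K`, `explained_variance`,
#'   `core_consistency`, `sse`, `converged`.
#' @export
model_order_scan <- function(ds, K_range = 4:8, ...) {
  if (!length(K_range)) flk_error("empty K range", "fdomlink_argument_error")
  rows <- lapply(K_range, function(K) {
    m <- tryCatch(fit_parafac(ds, K, ...), error = function(e) {
      flk_error(sprintf("K = %d: %s", K, conditionMessage(e)),
                "fdomlink_fit_error")
    })
    data.frame(K = K, explained_variance = m$explained_variance,
               core_consistency = core_consistency(m, ds),
               sse = m$sse, converged = m$converged)
  })
  do.call(rbind, rows)
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Computes the least-squares Tucker core of the data given the fitted
#' factors and measures its distance from the ideal superdiagonal, as
#' `100 * (1 - sum((G - T)^2) / K)`. Near 100 indicates an appropriate
#' trilinear model; values drop sharply past the true rank.
#'
#' @param model A `parafac_model`.
#' @param ds The [eem_dataset()] it was fitted to.
#' @return Scalar, at most 100 (can be negative).
#' @export
core_consistency <- function(model, ds) {
  X <- eem_array(ds)
  if (model$normalize_samples) {
    for (s in seq_len(dim(X)[3])) X[, , s] <- X[, , s] / model$sample_norms[s]
  }
  X[X < 0] <- 0
  if (anyNA(X)) {   # impute from the model for the diagnostic
    Xhat <- parafac_reconstruct(model, normalized = TRUE)
    X[is.na(X)] <- Xhat[is.na(X)]
  }
  A <- model$em_loadings; B <- model$ex_loadings
  C <- model$scores / model$sample_norms
  K <- model$n_components
  dims <- dim(X)
  # mode products with pseudo-inverses via least squares
  G <- qr.coef(qr(A), matrix(X, dims[1], dims[2] * dims[3]))       # K x (J S)
  G <- array(G, c(K, dims[2], dims[3]))
  G <- qr.coef(qr(B), matrix(aperm(G, c(2, 1, 3)), dims[2], K * dims[3]))
  G <- aperm(array(G, c(K, K, dims[3])), c(2, 1, 3))               # K K S
  G <- qr.coef(qr(C), matrix(aperm(G, c(3, 1, 2)), dims[3], K * K))
  G <- aperm(array(G, c(K, K, K)), c(2, 3, 1))
  Tgt <- array(0, c(K, K, K))
  for (k in seq_len(K)) Tgt[k, k, k] <- 1
  100 * (1 - sum((G - Tgt)^2) / K)
}

parafac_reconstruct <- function(model, normalized = FALSE) {
  C <- model$scores
  if (normalized) C <- C / model$sample_norms
  X1 <- model$em_loadings %*% t(khatri_rao(C, model$ex_loadings))
  array(X1, c(nrow(model$em_loadings), nrow(model$ex_loadings), nrow(C)))
}

#' Split-half validation of a PARAFAC model
#'
#' Randomly partitions the samples into halves `n_splits` times, fits each
#' half independently, matches components greedily by Tucker congruence and
#' passes when every matched excitation and emission congruence reaches
#' `threshold`.
#'
#' @param ds An [eem_dataset()] with at least `2 * K` samples.
#' @param K Number of components.
#' @param n_splits Number of independent random halvings (default 2).
#' @param threshold Minimum congruence (default 0.95).
#' @param seed RNG seed.
#' @param halves Optional list of two sample index vectors to use as a fixed
#'   split (diagnostic use, e.g. contrasting suspected sub-populations);
#'   overrides the random scheme and forces `n_splits = 1`.
#' @param ... Passed to [fit_parafac()].
#' @return A `split_half_report`: `data.frame` `results` with per-split,
#'   per-component `congruence_ex` / `congruence_em`, and logical `pass`.
#' @export
split_half_validate <- function(ds, K, n_splits = 2, threshold = 0.95,
                                seed = 1, halves = NULL, ...) {
  n <- length(ds$eems)
  if (n < 2 * K) {
    flk_error(sprintf("split-half needs >= %d samples, have %d", 2 * K, n),
              "fdomlink_validation_error")
  }
  if (!is.null(halves)) n_splits <- 1L
  set.seed(as.integer(seed))
  split_seeds <- sample.int(2^31 - 2, n_splits * 3)
  rows <- list()
  for (sp in seq_len(n_splits)) {
    if (is.null(halves)) {
      set.seed(split_seeds[3 * sp - 2])
      perm <- sample.int(n)
      h1 <- sort(perm[seq_len(n %/% 2)])
      h2 <- sort(perm[(n %/% 2 + 1):n])
    } else {
      h1 <- halves[[1]]; h2 <- halves[[2]]
    }
    ds1 <- eem_dataset(ds$eems[h1], ds$meta)
    ds2 <- eem_dataset(ds$eems[h2], ds$meta)
    m1 <- fit_parafac(ds1, K, seed = split_seeds[3 * sp - 1], ...)
    m2 <- fit_parafac(ds2, K, seed = split_seeds[3 * sp], ...)
    match <- match_components(m1$ex_loadings, m1$em_loadings,
                              m2$ex_loadings, m2$em_loadings)
    for (k in seq_len(K)) {
      rows[[length(rows) + 1]] <- data.frame(
        split = sp, component = k, matched = match[k],
        congruence_ex = tucker_congruence(m1$ex_loadings[, k],
                                          m2$ex_loadings[, match[k]]),
        congruence_em = tucker_congruence(m1$em_loadings[, k],
                                          m2$em_loadings[, match[k]]))
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, threshold = threshold,
                 pass = all(pmin(results$congruence_ex,
                                 results$congruence_em) >= threshold)),
            class = "split_half_report")
}

#' @export
print.split_half_report <- function(x, ...) {
  cat(sprintf("<split_half_report> %s (min congruence %.4f, threshold %g)\n",
              if (x$pass) "PASS" else "FAIL",
              min(x$results$congruence_ex, x$results$congruence_em),
              x$threshold))
  invisible(x)
}

#' Fmax scores (maximum component fluorescence per sample)
#'
#' Under the unit-maximum loading convention Fmax equals the raw score;
#' computed explicitly as `score * max(ex loading) * max(em loading)` so the
#' quantity is independent of the scaling convention.
#'
#' @param model A `parafac_model`.
#' @return n_samples x K matrix in the intensity units of the input (RU for
#'   Raman-normalized data).
#' @export
fmax_scores <- function(model) {
  sweep(model$scores, 2,
        apply(model$ex_loadings, 2, max) * apply(model$em_loadings, 2, max),
        `*`)
}

#' Per-sample percent composition of components
#'
#' @param fmax Nonnegative matrix of Fmax values (samples x components) with
#'   positive row sums.
#' @return Matrix of percentages; each row sums to 100.
#' @export
percent_composition <- function(fmax) {
  fmax <- as.matrix(fmax)
  if (any(fmax < 0)) {
    flk_error("Fmax values must be nonnegative", "fdomlink_argument_error")
  }
  rs <- rowSums(fmax)
  if (any(rs <= 0)) {
    flk_error(sprintf("undefined composition: zero Fmax row (sample %d)",
                      which(rs <= 0)[1]), "fdomlink_undefined_composition_error")
  }
  sweep(fmax, 1, rs, `/`) * 100
}

#' Default component classification rules
#'
#' Literature-conventional peak-position rules mapping a component's
#' excitation/emission maxima to a fluorophore class. Override any boundary
#' and pass the result to [classify_components()].
#'
#' @return Named list of rule boundaries (nm).
#' @export
classification_rules <- function() {
  list(tyrosine_em_max = 320,     # em peak below -> tyrosine-like
       tryptophan_em_max = 380,   # em peak below -> tryptophan-like
       humic_ex_split = 260)      # ex peak below -> terrestrial, else microbial
}

classify_peak <- function(ex_peak, em_peak, rules = classification_rules()) {
  if (!is.finite(ex_peak) || !is.finite(em_peak)) return("unclassified")
  if (em_peak < rules$tyrosine_em_max) return("tyrosine-like")
  if (em_peak < rules$tryptophan_em_max) return("tryptophan-like")
  if (ex_peak < rules$humic_ex_split) return("terrestrial humic-like")
  "microbial humic-like"
}

#' Classify fitted components by peak position
#'
#' Peak positions are the loading maxima on the model grid; labels follow
#' [classification_rules()] (tyrosine-like, tryptophan-like, terrestrial or
#' microbial humic-like).
#'
#' @param model A `parafac_model`.
#' @param rules Rule list, see [classification_rules()].
#' @return `data.frame` with `component`, `ex_peak_nm`, `em_peak_nm`,
#'   `label`.
#' @export
classify_components <- function(model, rules = classification_rules()) {
  K <- model$n_components
  ex_peak <- model$ex_nm[apply(model$ex_loadings, 2, which.max)]
  em_peak <- model$em_nm[apply(model$em_loadings, 2, which.max)]
  data.frame(component = colnames(model$scores) %||% paste0("C", seq_len(K)),
             ex_peak_nm = ex_peak, em_peak_nm = em_peak,
             label = vapply(seq_len(K), function(k)
               classify_peak(ex_peak[k], em_peak[k], rules), ""),
             stringsAsFactors = FALSE)
}

#' Match fitted components against a reference spectral library
#'
#' Offline analogue of an OpenFluor query: each fitted component is scored
#' against every library entry by the product of excitation and emission
#' Tucker congruence after resampling the library spectra to the model grid.
#'
#' @param model A `parafac_model`.
#' @param library `data.frame` with columns `id`, `axis` (`"ex"`/`"em"`),
#'   `wl_nm`, `loading` describing reference loading pairs.
#' @return `data.frame` with `component`, `best_match`, `congruence`.
#' @export
match_reference <- function(model, library) {
  if (is.null(library) || !nrow(library)) {
    flk_error("empty reference library", "fdomlink_argument_error")
  }
  ids <- unique(library$id)
  scores <- matrix(NA_real_, model$n_components, length(ids),
                   dimnames = list(NULL, ids))
  for (id in ids) {
    le <- library[library$id == id & library$axis == "ex", ]
    lm_ <- library[library$id == id & library$axis == "em", ]
    rex <- stats::approx(le$wl_nm, le$loading, xout = model$ex_nm, rule = 2)$y
    rem <- stats::approx(lm_$wl_nm, lm_$loading, xout = model$em_nm, rule = 2)$y
    for (k in seq_len(model$n_components)) {
      scores[k, id] <- tucker_congruence(model$ex_loadings[, k], rex) *
                       tucker_congruence(model$em_loadings[, k], rem)
    }
  }
  best <- apply(scores, 1, which.max)
  data.frame(component = colnames(model$scores), best_match = ids[best],
             congruence = scores[cbind(seq_along(best), best)],
             stringsAsFactors = FALSE)
}

#' Serialize a PARAFAC model to a directory
#'
#' Writes loadings and scores as CSV and diagnostics as JSON.
#'
#' @param model A `parafac_model`.
#' @param dir Output directory (created if needed).
#' @export
write_parafac_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(ex_nm = model$ex_nm, model$ex_loadings),
                   file.path(dir, "ex_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(em_nm = model$em_nm, model$em_loadings),
                   file.path(dir, "em_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = model$sample_ids, model$scores),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  diag <- list(n_components = model$n_components,
               explained_variance = model$explained_variance,
               sse = model$sse, n_iterations = model$n_iterations,
               converged = model$converged, seed = model$seed)
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
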