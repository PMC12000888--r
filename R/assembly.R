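#' Cophenetic (patristic) distances between phylogeny tips
#'
#' Sum of branch lengths along the path between every tip pair.
#'
#' @param tree A rooted `ape::phylo` with branch lengths and unique,
#'   non-empty tip labels.
#' @return Symmetric tip x tip distance matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  check_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    flk_error("tree must be an ape 'phylo' object", "fdomlink_tree_error")
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    flk_error("tree needs nonnegative branch lengths", "fdomlink_tree_error")
  }
  lbl <- tree$tip.label
  if (is.null(lbl) || any(!nzchar(lbl)) || anyDuplicated(lbl)) {
    flk_error("tree tips must be uniquely and non-emptily labelled",
              "fdomlink_tree_error")
  }
  invisible(tree)
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For communities x and y (relative abundances over their supports) and a
#' taxon distance matrix d:
#' \deqn{0.5 [ \sum_i x_i \min_j d(i,j) + \sum_j y_j \min_i d(j,i) ]}
#' with the minimum over the other community's support (a shared taxon has
#' distance 0 to itself). Unweighted uses equal weights over the support.
#'
#' @param x,y Named numeric vectors of abundances (taxa in `rownames(d)`);
#'   internally normalized to sum 1 over their positive support.
#' @param d Symmetric taxon distance matrix.
#' @param weighted Abundance-weighted (default `TRUE`).
#' @return Scalar betaMNTD.
#' @export
beta_mntd <- function(x, y, d, weighted = TRUE) {
  sx <- names(x)[x > 0]; sy <- names(y)[y > 0]
  if (!length(sx) || !length(sy)) {
    flk_error("betaMNTD undefined for an empty community",
              "fdomlink_undefined_error")
  }
  missing <- setdiff(c(sx, sy), rownames(d))
  if (length(missing)) {
    flk_error(paste("taxa absent from distance matrix:",
                    paste(utils::head(missing, 5), collapse = ", ")),
              "fdomlink_argument_error")
  }
  wx <- if (weighted) x[sx] / sum(x[sx]) else rep(1 / length(sx), length(sx))
  wy <- if (weighted) y[sy] / sum(y[sy]) else rep(1 / length(sy), length(sy))
  dm <- d[sx, sy, drop = FALSE]
  0.5 * (sum(wx * apply(dm, 1, min)) + sum(wy * apply(dm, 2, min)))
}

# all-pairs betaMNTD given taxa x sample weight matrix and supports;
# D[t, s] = distance from taxon t to its nearest taxon in sample s
all_pairs_bmntd <- function(d, W, supports) {
  n <- ncol(W)
  D <- vapply(supports, function(sup) rowmin_cols(d, sup),
              numeric(nrow(d)))
  B <- crossprod(W, D)          # B[i, j] = sum_t W[t,i] * D[t, j]
  0.5 * (B + t(B))
}

#' Beta nearest taxon index (betaNTI) for all sample pairs
#'
#' Computes observed betaMNTD for every sample pair, then a null
#' distribution by shuffling tip labels across the whole phylogeny
#' (equivalently jointly permuting rows and columns of the cophenetic
#' matrix) `n_null` times, recomputing all pairs per draw. The z-score
#' `betaNTI = (obs - null mean) / null sd` is conventionally read as
#' deterministic assembly when |betaNTI| > 2. Pairs with zero null standard
#' deviation are flagged `NA` rather than fabricated. Deterministic given
#' `seed`.
#'
#' @param table A [feature_table()] whose ASVs are all tips of `tree`.
#' @param tree Rooted `phylo` with branch lengths.
#' @param n_null Null draws (default 999); with `null = "exhaustive"` the
#'   full permutation set is enumerated instead (small trees only).
#' @param weighted Abundance-weighted betaMNTD (default `TRUE`).
#' @param seed RNG seed.
#' @param null `"sample"` (default) or `"exhaustive"`.
#' @return A `beta_nti_result`: list of symmetric matrices `bmntd_obs`,
#'   `null_mean`, `null_sd`, `bnti`, plus `n_null`, `seed`, `sample_ids`.
#' @export
beta_nti <- function(table, tree, n_null = 999, weighted = TRUE, seed = 1,
                     null = c("sample", "exhaustive")) {
  null <- match.arg(null)
  counts <- table$counts
  if (ncol(counts) < 2L) flk_error("need >= 2 samples", "fdomlink_argument_error")
  check_tree(tree)
  missing <- setdiff(rownames(counts), tree$tip.label)
  if (length(missing)) {
    flk_error(paste("ASVs missing from tree:",
                    paste(utils::head(missing, 5), collapse = ", ")),
              "fdomlink_tree_error")
  }
  d <- cophenetic_distances(tree)[rownames(counts), rownames(counts)]
  nt <- nrow(counts)
  W <- sweep(counts, 2, colSums(counts), `/`)
  if (!weighted) {
    W <- (counts > 0) * 1
    W <- sweep(W, 2, colSums(W), `/`)
  }
  supports <- lapply(seq_len(ncol(counts)), function(s) which(counts[, s] > 0))
  if (any(!lengths(supports))) {
    flk_error("betaMNTD undefined for an empty community",
              "fdomlink_undefined_error")
  }
  obs <- all_pairs_bmntd(d, W, supports)

  perms <- if (null == "exhaustive") {
    all_permutations(nt)
  } else {
    set.seed(as.integer(seed))
    lapply(seq_len(n_null), function(i) sample.int(nt))
  }
  sum1 <- matrix(0, ncol(counts), ncol(counts))
  sum2 <- sum1
  for (perm in perms) {
    b <- all_pairs_bmntd(d[perm, perm], W, supports)
    sum1 <- sum1 + b
    sum2 <- sum2 + b * b
  }
  nn <- length(perms)
  null_mean <- sum1 / nn
  null_sd <- sqrt(pmax(sum2 / nn - null_mean^2, 0) * nn / max(1, nn - 1))
  bnti <- (obs - null_mean) / null_sd
  bnti[null_sd <= .Machine$double.eps^0.5] <- NA_real_
  diag(bnti) <- NA_real_
  ids <- colnames(counts)
  dimnames(obs) <- dimnames(null_mean) <- dimnames(null_sd) <-
    dimnames(bnti) <- list(ids, ids)
  structure(list(bmntd_obs = obs, null_mean = null_mean, null_sd = null_sd,
                 bnti = bnti, n_null = nn, seed = seed, weighted = weighted,
                 sample_ids = ids),
            class = "beta_nti_result")
}

all_permutations <- function(n) {
  if (n > 8L) flk_error("exhaustive null limited to <= 8 taxa",
                        "fdomlink_argument_error")
  rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  rec(seq_len(n))
}

#' @export
print.beta_nti_result <- function(x, ...) {
  b <- x$bnti[upper.tri(x$bnti)]
  cat(sprintf("<beta_nti_result> %d samples, %d nulls; betaNTI median %.2f, %d/%d pairs |betaNTI| > 2\n",
              length(x$sample_ids), x$n_null, stats::median(b, na.rm = TRUE),
              sum(abs(b) > 2, na.rm = TRUE), sum(!is.na(b))))
  invisible(x)
}

#' Stochastic/deterministic partition of betaNTI values
#'
#' Percentages of pairs with `|betaNTI| < threshold` (stochastic assembly)
#' and the complement (deterministic); values exactly at the threshold count
#' as deterministic.
#'
#' @param bnti Numeric vector (or `beta_nti_result`, whose upper-triangle
#'   finite values are used) of betaNTI values.
#' @param threshold Default 2.
#' @return Named numeric `c(pct_stochastic, pct_deterministic)`.
#' @export
assembly_fractions <- function(bnti, threshold = 2) {
  if (inherits(bnti, "beta_nti_result")) bnti <- bnti$bnti[upper.tri(bnti$bnti)]
  bnti <- bnti[is.finite(bnti)]
  if (!length(bnti)) flk_error("no finite betaNTI values",
                               "fdomlink_argument_error")
  st <- 100 * sum(abs(bnti) < threshold) / length(bnti)
  c(pct_stochastic = st, pct_deterministic = 100 - st)
}

#' Write a betaNTI result as long-format CSV
#'
#' Columns: sample_i, sample_j, bmntd, null_mean, null_sd, bnti.
#'
#' @param x A `beta_nti_result`.
#' @param path Output CSV path.
#' @export
write_beta_nti_csv <- function(x, path) {
  ut <- which(upper.tri(x$bnti), arr.ind = TRUE)
  out <- data.frame(sample_i = x$sample_ids[ut[, 1]],
                    sample_j = x$sample_ids[ut[, 2]],
                    bmntd = x$bmntd_obs[ut], null_mean = x$null_mean[ut],
                    null_sd = x$null_sd[ut], bnti = x$bnti[ut])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
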