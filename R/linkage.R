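#' Aggregate an ASV table at a taxonomic rank
#'
#' Counts are summed within each rank label (ASVs not covered by the
#' taxonomy are pooled as `"Unassigned"`) and converted to per-sample
#' relative abundances.
#'
#' @param table A [feature_table()] with taxonomy.
#' @param rank Rank column name, e.g. `"phylum"` or `"genus"`.
#' @return Matrix, taxa x samples, columns summing to 1.
#' @export
aggregate_taxa <- function(table, rank) {
  tax <- table$taxonomy
  if (is.null(tax) || !rank %in% names(tax)) {
    flk_error(sprintf("rank '%s' absent from taxonomy", rank),
              "fdomlink_argument_error")
  }
  labels <- rep("Unassigned", nrow(table$counts))
  names(labels) <- rownames(table$counts)
  hit <- intersect(rownames(tax), rownames(table$counts))
  lab <- as.character(tax[hit, rank])
  lab[is.na(lab) | !nzchar(lab)] <- "Unassigned"
  labels[hit] <- lab
  agg <- rowsum(table$counts, group = labels)
  sweep(agg, 2, colSums(agg), `/`)
}

#' Taxa x DOM Spearman correlation map
#'
#' Spearman rho and p for every (taxon, DOM variable) pair over shared
#' samples, with Benjamini-Hochberg q computed across the whole table.
#'
#' @param taxa Matrix, taxa x samples (e.g. from [aggregate_taxa()]).
#' @param dom Matrix, DOM components/indices x samples.
#' @return A `linkage_table`: long `data.frame` with `taxon`, `dom_var`,
#'   `rho`, `p`, `q`.
#' @export
spearman_map <- function(taxa, dom) {
  shared <- intersect(colnames(taxa), colnames(dom))
  if (length(shared) < 5L) {
    flk_error(sprintf("need >= 5 shared samples, have %d", length(shared)),
              "fdomlink_argument_error")
  }
  taxa <- taxa[, shared, drop = FALSE]; dom <- dom[, shared, drop = FALSE]
  grid <- expand.grid(taxon = rownames(taxa), dom_var = rownames(dom),
                      stringsAsFactors = FALSE)
  res <- t(vapply(seq_len(nrow(grid)), function(r) {
    ct <- suppressWarnings(stats::cor.test(
      taxa[grid$taxon[r], ], dom[grid$dom_var[r], ], method = "spearman",
      exact = length(shared) < 10))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  out <- cbind(grid, data.frame(rho = res[, 1], p = res[, 2],
                                q = stats::p.adjust(res[, 2], "BH")))
  class(out) <- c("linkage_table", class(out))
  out
}

#' Mantel-style correlation between |betaNTI| and FDOM component distance
#'
#' For each DOM component, the pairwise Euclidean distance in the (1-D)
#' component value, `D_c(i, j) = |v_c(i) - v_c(j)|`, is correlated
#' (Spearman) with the |betaNTI| matrix over the upper triangle.
#' Significance comes from a Mantel permutation: sample labels of the
#' distance matrix are permuted jointly over rows and columns, and
#' `p = (1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_perm)`. A naive pairwise
#' p treating pairs as independent is also reported (`p_naive`,
#' anti-conservative). Reproducible given `seed`.
#'
#' @param bnti A `beta_nti_result` (or a symmetric betaNTI matrix); its
#'   absolute values are used. Pairs with undefined betaNTI are dropped.
#' @param dom Matrix, components x samples, sample names matching `bnti`.
#' @param n_perm Permutations (default 999).
#' @param seed RNG seed.
#' @return `data.frame` with one row per component: `component`, `rho`,
#'   `p_perm`, `p_naive`, `n_permutations`, `seed`.
#' @export
bnti_fdom_correlation <- function(bnti, dom, n_perm = 999, seed = 1) {
  bm <- if (inherits(bnti, "beta_nti_result")) bnti$bnti else as.matrix(bnti)
  dom <- as.matrix(dom)
  shared <- intersect(colnames(bm), colnames(dom))
  if (length(shared) < 5L) {
    flk_error("need >= 5 aligned samples", "fdomlink_argument_error")
  }
  bm <- abs(bm[shared, shared])
  dom <- dom[, shared, drop = FALSE]
  n <- length(shared)
  ut <- upper.tri(bm)
  set.seed(as.integer(seed))
  perms <- lapply(seq_len(n_perm), function(i) sample.int(n))
  rows <- lapply(rownames(dom), function(comp) {
    v <- dom[comp, ]
    D <- abs(outer(v, v, `-`))
    if (all(D[ut] == D[ut][1])) {
      flk_error(sprintf("component '%s' has a zero-variance distance matrix",
                        comp), "fdomlink_undefined_correlation_error")
    }
    keep <- ut & is.finite(bm)
    x <- bm[keep]
    rho_obs <- stats::cor(x, D[keep], method = "spearman")
    rx <- rank(x)
    exceed <- 0L
    for (perm in perms) {
      Dp <- D[perm, perm]
      if (stats::sd(Dp[keep]) == 0) next
      rho_p <- stats::cor(rx, rank(Dp[keep]))
      if (abs(rho_p) >= abs(rho_obs) - 1e-12) exceed <- exceed + 1L
    }
    ct <- suppressWarnings(stats::cor.test(x, D[keep], method = "spearman"))
    data.frame(component = comp, rho = rho_obs,
               p_perm = (1 + exceed) / (1 + n_perm),
               p_naive = ct$p.value, n_permutations = n_perm, seed = seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
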