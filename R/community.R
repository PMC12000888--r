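#' ASV feature table with optional taxonomy
#'
#' Counts are stored as an ASV x sample matrix of nonnegative integers.
#' Taxonomy, when present, is a `data.frame` keyed by ASV id with rank
#' columns (a subset of kingdom...genus/species).
#'
#' @param counts Nonnegative integer matrix, ASVs in rows, samples in
#'   columns, with unique dimnames.
#' @param taxonomy Optional `data.frame` with rownames a subset of the ASV
#'   ids.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    flk_error("counts must have ASV rownames and sample colnames",
              "fdomlink_format_error")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    flk_error("ASV and sample ids must be unique", "fdomlink_format_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    flk_error("counts must be nonnegative integers", "fdomlink_format_error")
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    extra <- setdiff(rownames(taxonomy), rownames(counts))
    if (length(extra)) taxonomy <- taxonomy[rownames(taxonomy) %in% rownames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d ASVs x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else
                sprintf(", taxonomy for %d ASVs", nrow(x$taxonomy))))
  invisible(x)
}

#' Read a feature table from TSV (ASVs in rows) or BIOM
#'
#' @param path Table path; `.biom` files are read via the biomformat
#'   package when installed, anything else as TSV with ASV ids in the first
#'   column and sample ids in the header.
#' @param taxonomy_path Optional taxonomy TSV: first column ASV id, either a
#'   single semicolon-separated 7-rank string column (named e.g. `Taxon`) or
#'   one column per rank.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, taxonomy_path = NULL) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      flk_error("reading BIOM requires the biomformat package",
                "fdomlink_format_error")
    }
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                             check.names = FALSE)
    counts <- as.matrix(tab)
  }
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy_tsv(taxonomy_path)
  feature_table(counts, taxonomy)
}

#' Read a taxonomy TSV into a rank table
#'
#' Accepts either one column per rank or a single semicolon-separated
#' lineage string which is split into kingdom...species.
#'
#' @param path TSV path, first column the ASV id.
#' @return `data.frame` of ranks with ASV rownames.
#' @export
read_taxonomy_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 1L && any(grepl(";", tab[[1]], fixed = TRUE))) {
    rn <- rownames(tab)
    parts <- strsplit(tab[[1]], ";", fixed = TRUE)
    tab <- as.data.frame(t(vapply(parts, function(p) {
      p <- trimws(p)
      length(p) <- 7L
      p
    }, character(7))), stringsAsFactors = FALSE)
    names(tab) <- c("kingdom", "phylum", "class", "order", "family", "genus",
                    "species")
    rownames(tab) <- rn
  }
  tab
}

#' Chao1 richness estimator
#'
#' `S_obs + F1^2 / (2 F2)` with singletons F1 and doubletons F2; when
#' F2 = 0 the bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`.
#'
#' @param counts Nonnegative integer vector of one sample's ASV counts.
#' @return Scalar Chao1 estimate (>= observed richness).
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

check_counts <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts))) {
    flk_error("counts must be nonnegative integers", "fdomlink_argument_error")
  }
  if (sum(counts) == 0) {
    flk_error("diversity undefined for an all-zero sample",
              "fdomlink_undefined_diversity_error")
  }
  invisible(counts)
}

#' Shannon diversity
#'
#' `H = -sum(p log_base p)` over taxa with p > 0. Default base 2.
#'
#' @param counts Nonnegative counts with positive total.
#' @param base Logarithm base (default 2).
#' @return Scalar H.
#' @export
shannon <- function(counts, base = 2) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Gini-Simpson diversity `1 - sum(p^2)`
#'
#' @param counts Nonnegative counts with positive total.
#' @return Scalar in `[0, 1)`.
#' @export
simpson <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  1 - sum(p^2)
}

#' Pielou evenness `J = H / log_base(S_obs)`
#'
#' @inheritParams shannon
#' @return Scalar in `[0, 1]`; undefined (error) for a single observed
#'   taxon.
#' @export
pielou <- function(counts, base = 2) {
  check_counts(counts)
  s <- sum(counts > 0)
  if (s < 2L) {
    flk_error("Pielou evenness undefined for a single taxon",
              "fdomlink_undefined_diversity_error")
  }
  shannon(counts, base) / log(s, base = base)
}

#' Alpha diversity table for every sample of a feature table
#'
#' @param table A [feature_table()].
#' @param base Log base for Shannon/Pielou (default 2).
#' @return `data.frame` with `sample_id`, `chao1`, `shannon`, `simpson`,
#'   `pielou`, `observed`.
#' @export
alpha_diversity <- function(table, base = 2) {
  counts <- table$counts
  do.call(rbind, lapply(colnames(counts), function(s) {
    v <- counts[, s]
    data.frame(sample_id = s, chao1 = chao1(v), shannon = shannon(v, base),
               simpson = simpson(v),
               pielou = if (sum(v > 0) > 1) pielou(v, base) else NA_real_,
               observed = sum(v > 0), stringsAsFactors = FALSE)
  }))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = sum|x - y| / sum(x + y)`; symmetric with zero diagonal.
#'
#' @param table A [feature_table()] or an ASV x sample matrix, >= 2 samples.
#' @return Symmetric sample x sample matrix.
#' @export
bray_curtis <- function(table) {
  x <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  n <- ncol(x)
  if (n < 2L) flk_error("need >= 2 samples", "fdomlink_argument_error")
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- sum(x[, i] + x[, j])
    if (tot == 0) {
      flk_error(sprintf("distance undefined between all-zero samples %s and %s",
                        colnames(x)[i], colnames(x)[j]),
                "fdomlink_undefined_distance_error")
    }
    d[i, j] <- d[j, i] <- sum(abs(x[, i] - x[, j])) / tot
  }
  d
}

#' Nonmetric multidimensional scaling (NMDS)
#'
#' Minimizes Kruskal stress-1 by iterative majorization with monotone
#' regression (vegan's `monoMDS` engine, global model), taking the best of
#' `n_starts` random configurations plus a metric-scaling start;
#' deterministic given `seed`.
#'
#' @param d Distance matrix (matrix or `dist`).
#' @param k Embedding dimension (default 2), < number of samples.
#' @param n_starts Random starts (default 20).
#' @param max_iter Iterations per start (default 500).
#' @param seed RNG seed.
#' @return List with `points` (n x k), `stress` (Kruskal stress-1 in
#'   \[0, 1\]), `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 500, seed = 1) {
  dm <- stats::as.dist(d)
  n <- attr(dm, "Size")
  if (k >= n) flk_error("k must be below the number of samples",
                        "fdomlink_dimension_error")
  set.seed(as.integer(seed))
  best <- vegan::monoMDS(dm, k = k, model = "global", maxit = max_iter)
  for (s in seq_len(n_starts)) {
    init <- matrix(stats::rnorm(n * k), n, k)
    fit <- vegan::monoMDS(dm, y = init, k = k, model = "global",
                          maxit = max_iter)
    if (fit$stress < best$stress) best <- fit
  }
  list(points = best$points, stress = best$stress,
       converged = best$maxits >= best$iters)
}

#' Two-group / multi-group location comparison
#'
#' Welch t-test, Mann-Whitney (Wilcoxon rank-sum), or one-way ANOVA
#' (equal-variance F test) with a two-sided p-value. The degenerate case of
#' zero within-group variance with equal means returns statistic 0, p 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param test `"welch_t"`, `"mann_whitney"` or `"anova"`.
#' @return List with `statistic`, `p_value`, `test`.
#' @export
group_compare <- function(values, groups,
                          test = c("welch_t", "mann_whitney", "anova")) {
  test <- match.arg(test)
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) flk_error("need >= 2 groups", "fdomlink_test_error")
  if (test %in% c("welch_t", "anova") && any(sizes < 2L)) {
    flk_error("each group needs >= 2 members", "fdomlink_test_error")
  }
  if (test == "welch_t" && length(sizes) != 2L) {
    flk_error("t-test needs exactly 2 groups", "fdomlink_test_error")
  }
  res <- switch(test,
    welch_t = tryCatch({
      ht <- stats::t.test(values ~ groups)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    }, error = function(e) degenerate_compare(values, groups)),
    mann_whitney = {
      ht <- suppressWarnings(stats::wilcox.test(values ~ groups))
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    anova = tryCatch({
      ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
      if (is.na(ht$p.value)) degenerate_compare(values, groups)
      else list(statistic = unname(ht$statistic), p_value = ht$p.value)
    }, error = function(e) degenerate_compare(values, groups))
  )
  c(res, list(test = test))
}

degenerate_compare <- function(values, groups) {
  means <- tapply(values, groups, mean)
  if (max(means) - min(means) == 0) list(statistic = 0, p_value = 1)
  else list(statistic = Inf, p_value = 0)
}

#' Rarefy (subsample) a feature table to even depth
#'
#' Draws `depth` reads per sample without replacement. Off by default in
#' every pipeline stage; provided as a utility.
#'
#' @param table A [feature_table()].
#' @param depth Reads per sample; samples below `depth` are dropped.
#' @param seed RNG seed.
#' @return A rarefied [feature_table()].
#' @export
subsample <- function(table, depth, seed = 1) {
  counts <- table$counts
  keep <- colSums(counts) >= depth
  if (!any(keep)) flk_error("no sample reaches the requested depth",
                            "fdomlink_argument_error")
  counts <- counts[, keep, drop = FALSE]
  set.seed(as.integer(seed))
  out <- apply(counts, 2, function(v) {
    drawn <- sample(rep.int(seq_along(v), v), depth)
    tabulate(drawn, nbins = length(v))
  })
  rownames(out) <- rownames(counts)
  feature_table(out, table$taxonomy)
}
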