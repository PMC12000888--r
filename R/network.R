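#' Prevalence/abundance filter for network input
#'
#' Keeps ASVs present in at least `min_prevalence` of samples AND with mean
#' relative abundance at least `min_mean_rel_abund`.
#'
#' @param table A [feature_table()].
#' @param min_prevalence Fraction of samples in `[0, 1]`, default 0.5.
#' @param min_mean_rel_abund Mean relative abundance threshold in `[0, 1]`,
#'   default 0.
#' @return Filtered [feature_table()].
#' @export
prevalence_filter <- function(table, min_prevalence = 0.5,
                              min_mean_rel_abund = 0) {
  if (min_prevalence < 0 || min_prevalence > 1 ||
      min_mean_rel_abund < 0 || min_mean_rel_abund > 1) {
    flk_error("thresholds must lie in [0, 1]", "fdomlink_argument_error")
  }
  counts <- table$counts
  prev <- rowMeans(counts > 0)
  rel <- sweep(counts, 2, pmax(1, colSums(counts)), `/`)
  keep <- prev >= min_prevalence & rowMeans(rel) >= min_mean_rel_abund
  if (!any(keep)) flk_error("no ASV survives the prevalence filter",
                            "fdomlink_empty_table_error")
  feature_table(counts[keep, , drop = FALSE], table$taxonomy)
}

#' Build a Spearman co-occurrence network
#'
#' Computes all pairwise Spearman correlations among the rows of `features`
#' (taxa, DOM components, environmental variables over shared samples),
#' two-sided p-values (t approximation for n >= 10, exact distribution for
#' smaller n via `cor.test`), Benjamini-Hochberg q-values across all tested
#' pairs, and keeps an edge when `|rho| >= rho_min` and `q <= q_max`.
#' Constant variables are skipped (their pairs untested) and recorded.
#' Isolated nodes are retained with degree 0.
#'
#' @param features Numeric matrix, variables x samples, with rownames.
#' @param kinds Character vector per variable from
#'   `c("taxon", "dom_component", "environment")`.
#' @param rho_min Minimum absolute correlation (default 0.6).
#' @param q_max Maximum BH q (default 0.05).
#' @return A `cooc_network`: list with `nodes` (`data.frame` id, kind),
#'   `edges` (`data.frame` i, j, rho, p, q, sign; i < j canonical),
#'   `skipped` (constant variables), `params`.
#' @export
build_network <- function(features, kinds = NULL, rho_min = 0.6,
                          q_max = 0.05) {
  features <- as.matrix(features)
  n <- ncol(features); v <- nrow(features)
  if (n < 4L) flk_error("need >= 4 samples", "fdomlink_argument_error")
  if (v < 2L) flk_error("need >= 2 variables", "fdomlink_argument_error")
  if (is.null(rownames(features))) rownames(features) <- paste0("V", seq_len(v))
  if (is.null(kinds)) kinds <- rep("taxon", v)
  if (!all(kinds %in% c("taxon", "dom_component", "environment"))) {
    flk_error("unknown node kind", "fdomlink_argument_error")
  }
  const <- apply(features, 1, function(x) stats::sd(x) == 0)
  pairs <- which(upper.tri(matrix(0, v, v)), arr.ind = TRUE)
  keep_pair <- !const[pairs[, 1]] & !const[pairs[, 2]]
  pairs <- pairs[keep_pair, , drop = FALSE]
  rho <- p <- rep(NA_real_, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ct <- suppressWarnings(stats::cor.test(
      features[pairs[r, 1], ], features[pairs[r, 2], ],
      method = "spearman", exact = n < 10))
    rho[r] <- unname(ct$estimate); p[r] <- ct$p.value
  }
  q <- stats::p.adjust(p, method = "BH")
  sel <- !is.na(rho) & abs(rho) >= rho_min & q <= q_max
  edges <- data.frame(
    i = rownames(features)[pairs[sel, 1]],
    j = rownames(features)[pairs[sel, 2]],
    rho = rho[sel], p = p[sel], q = q[sel],
    sign = ifelse(rho[sel] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  structure(list(
    nodes = data.frame(id = rownames(features), kind = kinds,
                       stringsAsFactors = FALSE),
    edges = edges,
    skipped = rownames(features)[const],
    params = list(rho_min = rho_min, q_max = q_max, n_samples = n)),
    class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d nodes, %d edges (%d +, %d -)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("i", "j")], directed = FALSE,
                                vertices = net$nodes$id)
}

#' Topology metrics of a co-occurrence network
#'
#' Average degree is `2 E / N` over all nodes (isolated included); average
#' path length is the mean unweighted shortest-path length over all
#' connected ordered pairs within the largest connected component (reported
#' `NA` with `apl_note` for an edgeless network, where it is undefined).
#' Modularity (optional) uses greedy agglomeration on the absolute-weight
#' graph.
#'
#' @param net A `cooc_network`.
#' @param modularity Compute modularity (default `TRUE`).
#' @return A `data.frame`-like list with `n_nodes`, `n_edges`, `n_positive`,
#'   `n_negative`, `average_degree`, `average_path_length`, `n_components`,
#'   `modularity`, `apl_note`.
#' @export
network_metrics <- function(net, modularity = TRUE) {
  g <- as_igraph(net)
  n_nodes <- igraph::vcount(g); n_edges <- igraph::ecount(g)
  comp <- igraph::components(g)
  apl <- NA_real_; apl_note <- NA_character_
  if (n_edges == 0L) {
    apl_note <- "undefined: edgeless network"
  } else {
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    dm <- igraph::distances(sub)
    apl <- mean(dm[row(dm) != col(dm)])
  }
  mod <- NA_real_
  if (modularity && n_edges > 0L) {
    gw <- igraph::set_edge_attr(g, "weight", value = abs(net$edges$rho))
    mod <- igraph::modularity(igraph::cluster_fast_greedy(gw))
  }
  list(n_nodes = n_nodes, n_edges = n_edges,
       n_positive = sum(net$edges$sign == "positive"),
       n_negative = sum(net$edges$sign == "negative"),
       average_degree = 2 * n_edges / n_nodes,
       average_path_length = apl,
       n_components = comp$no, modularity = mod, apl_note = apl_note)
}

#' Write a network as edge-list CSV, GraphML and metrics JSON
#'
#' @param net A `cooc_network`.
#' @param dir Output directory.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(net$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  g <- as_igraph(net)
  if (nrow(net$edges)) {
    g <- igraph::set_edge_attr(g, "rho", value = net$edges$rho)
    g <- igraph::set_edge_attr(g, "sign", value = net$edges$sign)
  }
  g <- igraph::set_vertex_attr(g, "kind", value = net$nodes$kind)
  igraph::write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  m <- network_metrics(net)
  m$apl_note <- NULL
  jsonlite::write_json(c(m, net$params), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
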