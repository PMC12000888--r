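test_that("prevalence_filter keeps exactly the qualifying ASVs", {
  set.seed(40)
  counts <- matrix(rpois(200, 2), 20, 10,
                   dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
  counts[1, ] <- c(5, 8, 0, 0, 0, 0, 0, 0, 0, 0)   # prevalence 0.2
  ft <- feature_table(counts)
  expect_identical(prevalence_filter(ft, 0, 0)$counts, ft$counts)
  expect_false("t1" %in% rownames(prevalence_filter(ft, 0.5)$counts))

  # brute-force row scan oracle
  rel <- sweep(counts, 2, colSums(counts), `/`)
  keep <- rowMeans(counts > 0) >= 0.4 & rowMeans(rel) >= 0.01
  expect_equal(nrow(prevalence_filter(ft, 0.4, 0.01)$counts), sum(keep))

  expect_error(prevalence_filter(ft, 1, 1),
               class = "fdomlink_empty_table_error")
  expect_error(prevalence_filter(ft, 2), class = "fdomlink_argument_error")
})

test_that("build_network edges follow rho and q thresholds", {
  x <- seq_len(12)
  feats <- rbind(a = x, b = x^3, c = 12:1)        # monotone up, up, down
  net <- build_network(feats, rho_min = 0.6, q_max = 0.05)
  ab <- net$edges[net$edges$i == "a" & net$edges$j == "b", ]
  expect_equal(ab$rho, 1)
  expect_identical(ab$sign, "positive")
  ac <- net$edges[net$edges$i == "a" & net$edges$j == "c", ]
  expect_identical(ac$sign, "negative")

  # rank closed form: rho(x=(1,2,3), y=(3,1,2)) = -0.5, below threshold
  expect_equal(suppressWarnings(cor(1:3, c(3, 1, 2), method = "spearman")),
               -0.5)
  f2 <- rbind(a = c(1, 2, 3, 4), b = c(3, 1, 2, 4))
  n2 <- build_network(f2, rho_min = 0.6)
  expect_true(all(abs(n2$edges$rho) >= 0.6))

  # constant variables are skipped, not errored
  f3 <- rbind(a = x, flat = rep(1, 12))
  n3 <- build_network(f3)
  expect_identical(n3$skipped, "flat")
  expect_equal(nrow(n3$edges), 0L)
  expect_equal(nrow(n3$nodes), 2L)               # isolated nodes retained

  expect_error(build_network(feats[, 1:3]), class = "fdomlink_argument_error")
})

test_that("network metrics match closed forms and the BFS oracle", {
  tri <- list(nodes = data.frame(id = c("a", "b", "c"), kind = "taxon"),
              edges = data.frame(i = c("a", "a", "b"), j = c("b", "c", "c"),
                                 rho = 1, p = 0, q = 0, sign = "positive"),
              skipped = character(0), params = list())
  class(tri) <- "cooc_network"
  m <- network_metrics(tri, modularity = FALSE)
  expect_equal(m$average_degree, 2)
  expect_equal(m$average_path_length, 1)

  path <- tri
  path$edges <- data.frame(i = c("a", "b"), j = c("b", "c"), rho = 1, p = 0,
                           q = 0, sign = "positive")
  mp <- network_metrics(path, modularity = FALSE)
  expect_equal(mp$average_degree, 4 / 3)
  expect_equal(mp$average_path_length, 4 / 3, tolerance = 1e-12)

  # seeded random graphs: APL equals the all-pairs BFS oracle exactly
  for (s in 1:50) {
    set.seed(s)
    nodes <- paste0("n", 1:20)
    pairs <- t(combn(nodes, 2))
    sel <- runif(nrow(pairs)) < 0.12
    if (!any(sel)) next
    ed <- data.frame(i = pairs[sel, 1], j = pairs[sel, 2], rho = 1, p = 0,
                     q = 0, sign = "positive", stringsAsFactors = FALSE)
    net <- list(nodes = data.frame(id = nodes, kind = "taxon"), edges = ed,
                skipped = character(0), params = list())
    class(net) <- "cooc_network"
    expect_equal(network_metrics(net, modularity = FALSE)$average_path_length,
                 bfs_apl(ed, nodes), tolerance = 1e-12)
  }

  # metrics invariant to node relabeling
  rel <- tri
  map <- c(a = "x", b = "y", c = "z")
  rel$nodes$id <- unname(map[rel$nodes$id])
  rel$edges$i <- unname(map[rel$edges$i]); rel$edges$j <- unname(map[rel$edges$j])
  expect_equal(network_metrics(rel, modularity = FALSE)$average_path_length,
               m$average_path_length)

  edgeless <- tri
  edgeless$edges <- tri$edges[0, ]
  me <- network_metrics(edgeless)
  expect_true(is.na(me$average_path_length))
  expect_match(me$apl_note, "undefined")
})

test_that("edge set is invariant to sample reordering and sign bookkeeping", {
  set.seed(41)
  feats <- matrix(rnorm(8 * 15), 8, 15,
                  dimnames = list(paste0("v", 1:8), NULL))
  feats[2, ] <- feats[1, ] + rnorm(15, sd = 0.05)
  n1 <- build_network(feats, rho_min = 0.5)
  n2 <- build_network(feats[, sample(15)], rho_min = 0.5)
  expect_equal(n1$edges[order(n1$edges$i, n1$edges$j), c("i", "j", "rho")],
               n2$edges[order(n2$edges$i, n2$edges$j), c("i", "j", "rho")])
  expect_equal(sum(n1$edges$sign == "negative"), sum(n1$edges$rho < 0))
})

test_that("false-edge count is controlled on independent noise", {
  # 30 independent variables, default thresholds; expectation over seeds
  false_edges <- vapply(1:100, function(s) {
    set.seed(s + 500)
    feats <- matrix(rnorm(30 * 25), 30, 25,
                    dimnames = list(paste0("v", 1:30), NULL))
    nrow(build_network(feats)$edges)
  }, 0)
  n_pairs <- choose(30, 2)
  expect_lte(mean(false_edges), 0.05 * n_pairs)
})

test_that("network serialization writes edges, graphml and metrics", {
  x <- seq_len(12)
  net <- build_network(rbind(a = x, b = 2 * x, c = rnorm(12)),
                       kinds = c("taxon", "dom_component", "environment"))
  dir <- withr::local_tempdir()
  write_network(net, dir)
  expect_true(file.exists(file.path(dir, "network.graphml")))
  js <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(js$n_edges, nrow(net$edges))
})
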