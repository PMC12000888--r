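# shared fixture builders (all in-code; nothing read from disk)

# small EEM on an exact grid with a supplied fill function f(em, ex)
make_eem <- function(f = function(em, ex) 1, ex = seq(250, 300, 10),
                     em = seq(300, 400, 20), id = "t1", ...) {
  vals <- outer(em, ex, function(m, x) {
    r <- f(m, x)
    if (length(r) == 1L) rep(r, length(m)) else r   # allow constant f
  })
  eem(id, ex, em, vals, ...)
}

# congruence after matching a fitted model against generator truth:
# for each true component, the best min(ex, em) congruence across fitted ones
recovery_congruence <- function(model, truth) {
  K <- ncol(truth$ex_loadings)
  vapply(seq_len(K), function(j) {
    max(vapply(seq_len(model$n_components), function(k) {
      min(tucker_congruence(model$ex_loadings[, k], truth$ex_loadings[, j]),
          tucker_congruence(model$em_loadings[, k], truth$em_loadings[, j]))
    }, 0))
  }, 0)
}

# brute-force betaMNTD by direct enumeration over taxon pairs
bmntd_brute <- function(x, y, d, weighted = TRUE) {
  sx <- names(x)[x > 0]; sy <- names(y)[y > 0]
  wx <- if (weighted) x[sx] / sum(x[sx]) else rep(1 / length(sx), length(sx))
  wy <- if (weighted) y[sy] / sum(y[sy]) else rep(1 / length(sy), length(sy))
  s1 <- 0
  for (i in seq_along(sx)) {
    s1 <- s1 + wx[i] * min(vapply(sy, function(j) d[sx[i], j], 0))
  }
  s2 <- 0
  for (j in seq_along(sy)) {
    s2 <- s2 + wy[j] * min(vapply(sx, function(i) d[sy[j], i], 0))
  }
  unname(0.5 * (s1 + s2))
}

# independent all-pairs shortest-path oracle (breadth-first search)
bfs_apl <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    adj[[edges$i[r]]] <- c(adj[[edges$i[r]]], edges$j[r])
    adj[[edges$j[r]]] <- c(adj[[edges$j[r]]], edges$i[r])
  }
  dist_from <- function(src) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (dist[v] > dist[u] + 1) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
    dist
  }
  dm <- t(vapply(nodes, dist_from, numeric(length(nodes))))
  # largest component = nodes of the most frequent finite-distance row set
  comp_id <- apply(is.finite(dm), 1, function(r) paste(which(r), collapse = ","))
  big <- names(which.max(table(comp_id)))
  members <- which(comp_id == big)
  if (length(members) < 2) return(NA_real_)
  sub <- dm[members, members]
  mean(sub[row(sub) != col(sub)])
}
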