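# Independent brute-force oracles, deliberately naive: plain loops and the
# Floyd-Warshall recurrence, no igraph.

# adjacency matrix from an edge tibble over a fixed node vector
bf_adjacency <- function(nodes, edges) {
  a <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    u <- edges[[1]][i]; v <- edges[[2]][i]
    if (u == v) next
    a[u, v] <- 1L; a[v, u] <- 1L
  }
  a
}

bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# number of shortest paths between every pair (for betweenness)
bf_path_counts <- function(a, d) {
  n <- nrow(a)
  cnt <- matrix(0, n, n)
  diag(cnt) <- 1
  for (len in sort(unique(d[is.finite(d) & d > 0]))) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (d[i, j] == len) {
        if (len == 1) cnt[i, j] <- 1
        else {
          # sum path counts through neighbors of j one step closer to i
          nb <- which(a[, j] == 1)
          cnt[i, j] <- sum(cnt[i, nb[d[i, nb] == len - 1]])
        }
      }
    }
  }
  cnt
}

bf_betweenness <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  cnt <- bf_path_counts(a, d)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t]) || cnt[s, t] == 0) next
      through <- if (d[s, v] + d[v, t] == d[s, t]) cnt[s, v] * cnt[v, t] else 0
      tot <- tot + through / cnt[s, t]
    }
    btw[v] <- tot
  }
  if (n > 2) btw <- btw * 2 / ((n - 1) * (n - 2))
  stats::setNames(btw, rownames(a))
}

bf_closeness <- function(a) {
  d <- bf_distances(a)
  diag(d) <- Inf
  apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    if (length(reach) == 0) 0 else length(reach) / sum(reach)
  })
}

bf_avg_shortest_path <- function(a) {
  d <- bf_distances(a)
  diag(d) <- Inf
  apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    if (length(reach) == 0) NA_real_ else mean(reach)
  })
}

bf_topological_coefficient <- function(a) {
  n <- nrow(a)
  tc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a[i, ])
    if (k == 0) next
    js <- c()
    for (m in seq_len(n)) {
      if (m == i) next
      shared <- sum(a[i, ] == 1 & a[m, ] == 1)
      if (shared > 0) js <- c(js, (shared + a[i, m]) / k)
    }
    tc[i] <- if (length(js)) mean(js) else 0
  }
  stats::setNames(tc, rownames(a))
}

# one-line restatement of the differentially-regulated-link formula
drl_oracle <- function(bc, bn, sc, sn, cc) (bc - bn) / sqrt(sc^2 + sn^2) + cc

# random simple graph as an edge tibble over nodes v1..vn
random_edge_tbl <- function(n_nodes, p) {
  nodes <- paste0("v", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
}
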