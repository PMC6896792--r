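# Independent brute-force oracles. These deliberately avoid the code paths
# they check: betweenness by exhaustive simple-path enumeration, the
# topological coefficient by explicit neighbour-set arithmetic, the
# hypergeometric tail by a choose() sum, and BH by the literal step-up rule.

# all simple paths between s and t as integer vectors (adjacency list nb)
enumerate_simple_paths <- function(nb, s, t) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in nb[[v]]) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

# normalized betweenness by enumerating all shortest paths per pair
brute_betweenness <- function(graph) {
  n <- igraph::vcount(graph)
  nb <- lapply(seq_len(n), function(v) {
    as.integer(igraph::neighbors(graph, v))
  })
  bc <- numeric(n)
  if (n >= 3L) {
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        paths <- enumerate_simple_paths(nb, s, t)
        if (!length(paths)) next
        len <- lengths(paths)
        shortest <- paths[len == min(len)]
        sigma <- length(shortest)
        for (p in shortest) {
          interior <- p[-c(1L, length(p))]
          bc[interior] <- bc[interior] + 1 / sigma
        }
      }
    }
    bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  setNames(bc, igraph::V(graph)$name)
}

# topological coefficient from neighbour sets
brute_topological_coefficient <- function(graph) {
  n <- igraph::vcount(graph)
  nb <- lapply(seq_len(n), function(v) {
    as.integer(igraph::neighbors(graph, v))
  })
  tc <- numeric(n)
  for (v in seq_len(n)) {
    if (length(nb[[v]]) < 2L) next
    J <- c()
    for (m in seq_len(n)) {
      if (m == v) next
      shared <- length(intersect(nb[[v]], nb[[m]]))
      if (shared == 0L) next
      J <- c(J, shared + as.integer(m %in% nb[[v]]))
    }
    if (length(J)) tc[v] <- mean(J) / length(nb[[v]])
  }
  setNames(tc, igraph::V(graph)$name)
}

# P(X >= x) by direct summation of hypergeometric mass terms
brute_hyper_tail <- function(x, n, K, M) {
  i <- x:min(n, K)
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}

# literal BH step-up
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# random connected labelled graph on <= max_n nodes
random_connected_graph <- function(seed, max_n = 8L) {
  set.seed(seed)
  repeat {
    n <- sample(3:max_n, 1L)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.8))
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# small named star/ring/complete helpers
named_star <- function(k) {
  g <- igraph::make_star(k + 1L, mode = "undirected")
  igraph::V(g)$name <- c("center", paste0("leaf", seq_len(k)))
  g
}
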