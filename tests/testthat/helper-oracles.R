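# Independent brute-force oracles. These share no code with the package
# implementations they check: distances come from a hand-rolled BFS, PLI from
# an explicit sign count, and the graph metrics from direct enumeration.

# PLI by explicit counting of positive / negative / tied wrapped differences.
oracle_pli <- function(px, py) {
  pos <- 0L; neg <- 0L
  for (s in seq_along(px)) {
    d <- px[s] - py[s]
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    if (d > 0 && d < pi) pos <- pos + 1L
    else if (d < 0) neg <- neg + 1L
    # d == 0 or d == pi: tie, contributes 0
  }
  abs(pos - neg) / length(px)
}

# Single-source BFS hop distances on a binary adjacency matrix.
oracle_bfs <- function(adj, src) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(adj[u, ] != 0)) {
        if (is.infinite(dist[v])) { dist[v] <- dist[u] + 1; nxt <- c(nxt, v) }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_distances <- function(adj) {
  t(vapply(seq_len(nrow(adj)), function(s) oracle_bfs(adj, s),
           numeric(nrow(adj))))
}

# Betweenness by exhaustive enumeration of every simple path between every
# pair, keeping only the shortest ones.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  through <- matrix(0, n, 0)
  bc <- numeric(n)
  all_paths <- function(u, target, visited) {
    if (u == target) return(list(visited))
    out <- list()
    for (v in which(adj[u, ] != 0)) {
      if (!(v %in% visited))
        out <- c(out, all_paths(v, target, c(visited, v)))
    }
    out
  }
  for (h in seq_len(n - 1)) for (j in (h + 1):n) {
    paths <- all_paths(h, j, h)
    if (!length(paths)) next
    lens <- vapply(paths, length, 0L)
    short <- paths[lens == min(lens)]
    g_hj <- length(short)
    for (i in seq_len(n)) {
      if (i == h || i == j) next
      g_hj_i <- sum(vapply(short, function(p) i %in% p, TRUE))
      bc[i] <- bc[i] + g_hj_i / g_hj
    }
  }
  2 * bc / ((n - 1) * (n - 2))
}

# Clustering coefficient by direct triangle counting.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] != 0) links <- links + 1
    cc[i] <- 2 * links / (k * (k - 1))
  }
  cc
}

oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) next
    out[i] <- oracle_efficiency(adj[nb, nb, drop = FALSE])
  }
  out
}

oracle_global_efficiency <- function(adj) oracle_efficiency(adj)

# Random symmetric binary adjacency with zero diagonal.
random_adjacency <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

# Named helpers for standard small graphs.
complete_graph <- function(n) {
  adj <- matrix(1, n, n); diag(adj) <- 0; adj
}
star_graph <- function(n) {
  adj <- matrix(0, n, n); adj[1, 2:n] <- 1; adj[2:n, 1] <- 1; adj
}
path_graph <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) { adj[i, i + 1] <- 1; adj[i + 1, i] <- 1 }
  adj
}
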