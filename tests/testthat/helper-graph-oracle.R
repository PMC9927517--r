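# Brute-force graph-metric oracles, independent of igraph: explicit triangle
# counting, Floyd-Warshall all-pairs shortest paths, shortest-path counting by
# dynamic programming, and the modularity formula applied to a membership.

oracle_degree <- function(adj) rowSums(adj > 0)

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    triangles <- 0
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k))
      if (adj[nb[a], nb[b]] > 0) triangles <- triangles + 1
    2 * triangles / (k * (k - 1))
  }, numeric(1))
}

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    members <- which(is.finite(d[v, ]))
    if (length(members) == 1) return(0)
    (length(members) - 1) / sum(d[v, setdiff(members, v)])
  }, numeric(1))
}

# number of shortest s->t paths, from the distance matrix, by recursion on
# distance: nsp(s, t) = sum over neighbours u of s with d(u, t) = d(s, t) - 1
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  nsp <- function(s, t) {
    if (s == t) return(1)
    if (!is.finite(d[s, t])) return(0)
    sum(vapply(which(adj[s, ] > 0), function(u)
      if (d[u, t] == d[s, t] - 1) nsp(u, t) else 0, numeric(1)))
  }
  outer(seq_len(n), seq_len(n), Vectorize(nsp))
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  np <- oracle_path_counts(adj, d)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        btw[v] <- btw[v] + np[s, v] * np[v, t] / np[s, t]
    }
  }
  btw
}

# Q = sum_c (e_c - a_c^2): e_c fraction of edges inside community c, a_c
# fraction of edge ends attached to c
oracle_modularity <- function(adj, membership) {
  m <- sum(adj > 0) / 2
  deg <- rowSums(adj > 0)
  comms <- unique(membership)
  sum(vapply(comms, function(c) {
    inside <- which(membership == c)
    e_c <- sum(adj[inside, inside] > 0) / 2 / m
    a_c <- sum(deg[inside]) / (2 * m)
    e_c - a_c^2
  }, numeric(1)))
}
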