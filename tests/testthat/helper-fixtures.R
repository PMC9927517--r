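# Small in-code fixtures shared across test files.

toy_table <- function(counts = NULL, kingdom = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(10L, 5L, 0L,
                       2L, 8L, 4L,
                       0L, 1L, 6L), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("ASV", 1:3), paste0("s", 1:3)))
  }
  feature_table(counts, kingdom = kingdom)
}

toy_metadata <- function(ids, site = "A", genotype = "wild") {
  data.frame(sample_id = ids,
             site = rep_len(site, length(ids)),
             genotype = rep_len(genotype, length(ids)),
             replicate = seq_along(ids), stringsAsFactors = FALSE)
}

# a feature_table sampled multinomially from given per-sample probabilities
table_from_prob <- function(prob, reads, seed = 1L, kingdom = NULL) {
  withr::with_seed(seed, {
    counts <- apply(prob, 2, function(p) stats::rmultinom(1, reads, p)[, 1])
    dimnames(counts) <- dimnames(prob)
    if (is.null(rownames(counts))) rownames(counts) <- paste0("ASV", seq_len(nrow(counts)))
    if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    feature_table(counts, kingdom = kingdom)
  })
}

# build a cooccurrence_network directly from an adjacency matrix (for graph
# metric tests): every present edge is given rho = +0.9, adjusted p = 0
network_from_adjacency <- function(adj, kingdom = NULL) {
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- sprintf("N%02d", seq_len(n))
  rho <- matrix(0, n, n, dimnames = list(ids, ids))
  p <- matrix(1, n, n, dimnames = list(ids, ids))
  rho[adj > 0] <- 0.9
  p[adj > 0] <- 1e-12
  diag(rho) <- 1; diag(p) <- 0
  if (!is.null(kingdom)) names(kingdom) <- ids
  build_network(list(rho = rho, p = p, n = 30), kingdom = kingdom)
}

random_adjacency <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p_edge)
    adj <- adj + t(adj)
    rownames(adj) <- colnames(adj) <- sprintf("N%02d", seq_len(n))
    adj
  })
}
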