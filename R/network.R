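#' Pairwise Spearman correlation and p-value matrices
#'
#' All-pairs Spearman rank correlations between taxa across samples, with
#' two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Taxa with zero rank variance (constant across samples) get `NA`
#' correlations and are never eligible for edges.
#'
#' @param relabund taxon-by-sample relative-abundance matrix (taxa should
#'   already be rare-filtered; see [filter_rare()])
#' @return list with `rho` and `p` (taxa x taxa symmetric matrices,
#'   `diag(rho) = 1`), and `n` (number of samples)
#' @export
spearman_matrix <- function(relabund) {
  n <- ncol(relabund)
  if (n < 5) stop("need >= 5 samples for correlation screening", call. = FALSE)
  constant <- apply(relabund, 1, function(r) length(unique(r)) == 1)
  rho <- suppressWarnings(stats::cor(t(relabund), method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0   # |rho| = 1 -> infinite t
  diag(p) <- 0
  list(rho = rho, p = p, n = n)
}

#' Build a thresholded co-occurrence network
#'
#' Edges are taxon pairs with |rho| above `rho_min` AND multiplicity-adjusted
#' p below `p_max`; the adjustment (Benjamini-Hochberg by default) is applied
#' across all candidate pairs of the build. Isolated taxa are dropped, edges
#' are stored with canonical `i < j` ordering, and each edge carries its
#' sign and kingdom class (BB, BF, FF) when kingdom labels are available.
#'
#' @param corr result of [spearman_matrix()]
#' @param kingdom optional named per-taxon kingdom vector
#' @param rho_min absolute-correlation threshold in `[0, 1)` (default 0.6)
#' @param p_max adjusted-p threshold in `(0, 1]` (default 0.01)
#' @param correction p-value adjustment passed to [stats::p.adjust()];
#'   `"BH"` by default, `"none"` tests the raw p against `p_max`
#' @return a `cooccurrence_network`: list with `nodes` (data.frame: id,
#'   kingdom), `edges` (data.frame: from, to, rho, p, p_adjusted, sign,
#'   class) and `graph` (an [igraph::graph] with a `sign` edge attribute)
#' @export
build_network <- function(corr, kingdom = NULL, rho_min = 0.6, p_max = 0.01,
                          correction = "BH") {
  if (rho_min < 0 || rho_min >= 1) stop("`rho_min` must be in [0, 1)", call. = FALSE)
  if (p_max <= 0 || p_max > 1) stop("`p_max` must be in (0, 1]", call. = FALSE)
  rho <- corr$rho
  ids <- rownames(rho)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  cand <- data.frame(i = idx[, 1], j = idx[, 2],
                     rho = rho[idx], p = corr$p[idx])
  cand <- cand[!is.na(cand$rho), , drop = FALSE]
  cand$p_adjusted <- stats::p.adjust(cand$p, method = correction)
  keep <- abs(cand$rho) > rho_min & cand$p_adjusted < p_max
  edges <- cand[keep, , drop = FALSE]
  # canonical edge representation: from < to by taxon ID, rows sorted
  a <- ids[edges$i]; b <- ids[edges$j]
  swap <- a > b
  from <- ifelse(swap, b, a); to <- ifelse(swap, a, b)
  cls <- if (!is.null(kingdom) && nrow(edges)) {
    k1 <- kingdom[from]; k2 <- kingdom[to]
    ifelse(k1 == k2, ifelse(k1 == "bacteria", "BB", "FF"), "BF")
  } else rep(NA_character_, nrow(edges))
  edge_df <- data.frame(from = as.character(from), to = as.character(to),
                        rho = edges$rho, p = edges$p,
                        p_adjusted = edges$p_adjusted,
                        sign = ifelse(edges$rho > 0, 1L, -1L),
                        class = cls, stringsAsFactors = FALSE)
  edge_df <- edge_df[order(edge_df$from, edge_df$to), , drop = FALSE]
  rownames(edge_df) <- NULL
  node_ids <- sort(unique(c(edge_df$from, edge_df$to)))
  node_kingdom <- if (!is.null(kingdom)) unname(kingdom[node_ids]) else
    rep(NA_character_, length(node_ids))
  g <- igraph::graph_from_data_frame(
    edge_df[, c("from", "to", "rho", "sign")],
    directed = FALSE,
    vertices = data.frame(name = node_ids, kingdom = node_kingdom))
  structure(list(nodes = data.frame(id = node_ids, kingdom = node_kingdom,
                                    stringsAsFactors = FALSE),
                 edges = edge_df, graph = g,
                 thresholds = list(rho_min = rho_min, p_max = p_max,
                                   correction = correction)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|rho| > ", x$thresholds$rho_min, ", ",
      x$thresholds$correction, " p < ", x$thresholds$p_max, ")\n", sep = "")
  invisible(x)
}

local_clustering <- function(g) {
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  cc
}

component_closeness <- function(g) {
  # normalized within each connected component: (n_comp - 1) / sum of
  # shortest-path distances to the other members
  n <- igraph::vcount(g)
  comp <- igraph::components(g)$membership
  d <- igraph::distances(g)
  vapply(seq_len(n), function(v) {
    members <- which(comp == comp[v])
    if (length(members) == 1) return(0)
    (length(members) - 1) / sum(d[v, setdiff(members, v)])
  }, numeric(1))
}

#' Topology, stability and modularity summary of a network
#'
#' Node and whole-network metrics on the unweighted, unsigned skeleton:
#' average degree 2E/N, mean local clustering coefficient (nodes of degree
#' < 2 count as 0), modularity of the partition found by deterministic
#' greedy modularity maximization ([igraph::cluster_fast_greedy()]), and
#' the stability proportions of positive and negative edges with per-class
#' (BB/BF/FF) edge counts. An empty network summarizes to zeros with a
#' warning.
#'
#' @param net a [build_network()] result
#' @return a `network_summary` list
#' @export
summarize_network <- function(net) {
  empty <- nrow(net$edges) == 0
  if (empty) warning("empty network; summary is all zeros")
  n_nodes <- nrow(net$nodes)
  n_edges <- nrow(net$edges)
  class_counts <- c(BB = 0L, BF = 0L, FF = 0L)
  if (!empty && !all(is.na(net$edges$class))) {
    tab <- table(factor(net$edges$class, levels = c("BB", "BF", "FF")))
    class_counts <- stats::setNames(as.integer(tab), names(tab))
  }
  if (empty) {
    return(structure(list(n_nodes = 0L, n_edges = 0L, average_degree = 0,
                          average_clustering = 0, modularity = 0,
                          proportion_positive = 0, proportion_negative = 0,
                          class_counts = class_counts, membership = integer(0),
                          algorithm = "fast_greedy"),
                     class = "network_summary"))
  }
  g <- net$graph
  comm <- igraph::cluster_fast_greedy(g)
  structure(list(
    n_nodes = as.integer(n_nodes),
    n_edges = as.integer(n_edges),
    average_degree = 2 * n_edges / n_nodes,
    average_clustering = mean(local_clustering(g)),
    modularity = igraph::modularity(g, igraph::membership(comm)),
    proportion_positive = mean(net$edges$sign > 0),
    proportion_negative = mean(net$edges$sign < 0),
    class_counts = class_counts,
    membership = stats::setNames(as.integer(igraph::membership(comm)),
                                 igraph::V(g)$name),
    algorithm = "fast_greedy"),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> ", x$n_nodes, " nodes, ", x$n_edges, " edges\n",
      "  average degree ", round(x$average_degree, 3),
      ", clustering ", round(x$average_clustering, 3),
      ", modularity ", round(x$modularity, 3), "\n",
      "  edges: ", round(100 * x$proportion_positive, 1), "% positive, ",
      round(100 * x$proportion_negative, 1), "% negative\n", sep = "")
  invisible(x)
}

#' Node centralities and ranked hub report
#'
#' Degree, closeness (normalized within connected components) and
#' betweenness on the unweighted skeleton. Hubs are ranked by degree, ties
#' broken by closeness, then lexicographic taxon ID, so reports are
#' deterministic.
#'
#' @param net a [build_network()] result
#' @param k number of top hubs to flag (default 10)
#' @return data.frame per node: `id`, `kingdom`, `degree`, `closeness`,
#'   `betweenness`, `hub_rank` (NA outside the top `k`)
#' @export
network_hubs <- function(net, k = 10) {
  if (nrow(net$edges) == 0) stop("network is empty", call. = FALSE)
  g <- net$graph
  deg <- igraph::degree(g)
  clo <- component_closeness(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  out <- data.frame(id = igraph::V(g)$name, kingdom = igraph::V(g)$kingdom,
                    degree = as.integer(deg), closeness = clo,
                    betweenness = unname(btw), stringsAsFactors = FALSE)
  ord <- order(-out$degree, -out$closeness, out$id)
  out <- out[ord, , drop = FALSE]
  out$hub_rank <- NA_integer_
  out$hub_rank[seq_len(min(k, nrow(out)))] <- seq_len(min(k, nrow(out)))
  rownames(out) <- NULL
  out
}

#' Compare two networks' summary metrics and node-level distributions
#'
#' Reports per-metric differences (a minus b) and two-sided Wilcoxon
#' rank-sum p-values comparing the node-level degree and local-clustering
#' distributions of the two networks.
#'
#' @param net_a,net_b [build_network()] results, both non-empty
#' @return list with `summary_a`, `summary_b`, `differences` (named vector),
#'   `degree_p`, `clustering_p`
#' @export
compare_networks <- function(net_a, net_b) {
  if (nrow(net_a$edges) == 0 || nrow(net_b$edges) == 0)
    stop("both networks must be non-empty", call. = FALSE)
  sa <- summarize_network(net_a)
  sb <- summarize_network(net_b)
  metrics <- c("n_nodes", "n_edges", "average_degree", "average_clustering",
               "modularity", "proportion_positive", "proportion_negative")
  diffs <- vapply(metrics, function(m) as.numeric(sa[[m]]) - as.numeric(sb[[m]]),
                  numeric(1))
  deg_a <- igraph::degree(net_a$graph); deg_b <- igraph::degree(net_b$graph)
  cc_a <- local_clustering(net_a$graph); cc_b <- local_clustering(net_b$graph)
  wt <- function(u, v) {
    if (length(u) == length(v) && all(sort(u) == sort(v))) return(1)
    suppressWarnings(stats::wilcox.test(u, v)$p.value)
  }
  list(summary_a = sa, summary_b = sb, differences = diffs,
       degree_p = wt(deg_a, deg_b), clustering_p = wt(cc_a, cc_b))
}

#' Write network edge and node tables
#'
#' Edge list TSV (source, target, rho, adjusted p, sign, class) and node
#' table TSV (id, kingdom, degree, clustering, closeness, betweenness,
#' module) for downstream visualization tools.
#'
#' @param net a [build_network()] result
#' @param edge_path,node_path output TSV paths
#' @export
write_network <- function(net, edge_path, node_path) {
  e <- net$edges
  utils::write.table(
    data.frame(source = e$from, target = e$to, rho = e$rho,
               adjusted_p = e$p_adjusted, sign = e$sign, class = e$class),
    edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(e)) {
    s <- summarize_network(net)
    hubs <- network_hubs(net, k = 10)
    hubs$module <- s$membership[hubs$id]
    hubs$clustering <- local_clustering(net$graph)[match(hubs$id, igraph::V(net$graph)$name)]
    utils::write.table(
      hubs[, c("id", "kingdom", "degree", "clustering", "closeness",
               "betweenness", "module")],
      node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(edge_path, node_path))
}
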