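#' Between-sample mean nearest-taxon phylogenetic distance
#'
#' Abundance-weighted beta-MNTD: for each pair of samples (k, l),
#' `0.5 * (sum_i f_ik * min_j d_ij + sum_j f_jl * min_i d_ij)` where f are
#' relative abundances, the min runs over taxa present in the other sample,
#' and d is patristic distance. Shared taxa contribute distance 0. With
#' `weighted = FALSE` every present taxon gets weight 1/richness instead.
#'
#' @param x a [feature_table()]
#' @param tree phylogeny covering all taxa, with branch lengths
#' @param weighted abundance-weight the taxon contributions (default TRUE)
#' @return symmetric sample-by-sample matrix with zero diagonal
#' @export
beta_mntd <- function(x, tree, weighted = TRUE) {
  stopifnot(inherits(x, "feature_table"))
  missing <- setdiff(taxon_ids(x), tree$tip.label)
  if (length(missing))
    stop("tree is missing taxa: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree needs non-negative branch lengths", call. = FALSE)
  D <- stats::cophenetic(tree)[taxon_ids(x), taxon_ids(x)]
  F_ <- community_weights(x, weighted)
  bmntd_from_dist(D, F_)
}

community_weights <- function(x, weighted) {
  if (weighted) return(relative_abundance(x))
  pa <- (x$counts > 0) * 1
  sweep(pa, 2, colSums(pa), "/")
}

# beta-MNTD for all sample pairs given a taxon distance matrix and a
# taxon-by-sample weight matrix whose columns sum to 1.
bmntd_from_dist <- function(D, F_) {
  present <- lapply(seq_len(ncol(F_)), function(s) which(F_[, s] > 0))
  # N[t, s] = distance from taxon t to its nearest taxon present in sample s
  N <- vapply(present, function(idx) {
    if (length(idx) == 1) D[, idx] else do.call(pmin, lapply(idx, function(j) D[, j]))
  }, numeric(nrow(D)))
  A <- crossprod(F_, N)            # A[k, l] = sum_i F[i,k] * N[i,l]
  out <- 0.5 * (A + t(A))
  diag(out) <- 0
  dimnames(out) <- list(colnames(F_), colnames(F_))
  out
}

#' Beta nearest-taxon index against a tip-shuffle null
#'
#' Standardized effect size of beta-MNTD: taxon labels are shuffled across
#' the tips of the whole tree `n_null` times (one shared shuffle sequence
#' for all sample pairs), beta-MNTD recomputed under each shuffle, and
#' `betaNTI = (observed - null mean) / null SD` per pair. |betaNTI| > 2 is
#' the conventional evidence for selection: > +2 heterogeneous selection,
#' < -2 homogeneous selection. Pairs with zero null SD are reported as
#' `NA` with a warning.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip shuffles (default 999)
#' @param seed integer seed for the shuffle sequence
#' @return a `beta_nti_result`: list with `bnti` (sample-by-sample matrix,
#'   `NA` diagonal), `bmntd_obs`, `n_null`
#' @export
beta_nti <- function(x, tree, weighted = TRUE, n_null = 999, seed = 1L) {
  stopifnot(inherits(x, "feature_table"))
  missing <- setdiff(taxon_ids(x), tree$tip.label)
  if (length(missing))
    stop("tree is missing taxa: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  D <- stats::cophenetic(tree)[taxon_ids(x), taxon_ids(x)]
  F_ <- community_weights(x, weighted)
  obs <- bmntd_from_dist(D, F_)
  n_t <- nrow(D)
  sum_null <- matrix(0, ncol(F_), ncol(F_))
  sumsq_null <- matrix(0, ncol(F_), ncol(F_))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_t)
      b <- bmntd_from_dist(D[perm, perm], F_)
      sum_null <- sum_null + b
      sumsq_null <- sumsq_null + b * b
    }
  })
  mu <- sum_null / n_null
  sdv <- sqrt(pmax(sumsq_null / n_null - mu^2, 0) * n_null / (n_null - 1))
  bnti <- (obs - mu) / sdv
  bnti[sdv == 0] <- NA_real_
  diag(bnti) <- NA_real_
  if (any(is.na(bnti[upper.tri(bnti)])))
    warning("zero null SD for ", sum(is.na(bnti[upper.tri(bnti)])),
            " pair(s); betaNTI undefined there")
  structure(list(bnti = bnti, bmntd_obs = obs, n_null = as.integer(n_null)),
            class = "beta_nti_result")
}
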