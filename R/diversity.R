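#' Shannon diversity per sample
#'
#' Natural-log Shannon index H = -sum(p * ln p) on per-sample relative
#' abundances, computed through [vegan::diversity()].
#'
#' @param x a [feature_table()]
#' @return named numeric vector, one H per sample, in `[0, ln S]`
#' @export
shannon_index <- function(x) {
  ra <- relative_abundance(x)
  vegan::diversity(t(ra), index = "shannon")
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on per-sample relative abundances via [vegan::vegdist()], so
#' entries lie in `[0, 1]` regardless of sequencing depth.
#'
#' @param x a [feature_table()]
#' @return a `dist` object labelled by sample IDs
#' @export
bray_curtis <- function(x) {
  if (n_samples(x) < 2) stop("need >= 2 samples", call. = FALSE)
  ra <- relative_abundance(x)
  vegan::vegdist(t(ra), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centred
#' -0.5*D^2 matrix. Negative eigenvalues (from the non-Euclidean part of
#' Bray-Curtis) are reported but excluded from the proportion-explained
#' denominator; no Cailliez correction is applied. If fewer than `k`
#' positive eigenvalues exist the embedding is truncated with a warning.
#'
#' @param d a `dist` of pairwise sample dissimilarities
#' @param k number of ordination axes requested
#' @return list with `points` (samples x k coordinates), `eig` (all
#'   eigenvalues, descending) and `prop_explained` (per returned axis)
#' @export
pcoa_ordination <- function(d, k = 2) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = min(k, n - 1), eig = TRUE)
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > pos) {
    warning("only ", pos, " positive eigenvalue(s); returning ", pos, " axes")
    k <- pos
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eig = eig,
       prop_explained = eig[seq_len(k)] / sum(eig[eig > 0]))
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance via [vegan::adonis2()]
#' with free permutation of sample labels (no strata): pseudo-F from the
#' between/within partition of squared distances, p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' @param d a `dist` over samples
#' @param metadata metadata aligned to the distance labels (see
#'   [align_metadata()])
#' @param factor_name metadata column to test (must have >= 2 levels)
#' @param n_permutations number of label permutations (default 999)
#' @param seed integer seed for the permutation stream
#' @return list with `factor`, `R2`, `pseudo_F`, `p_value`, `n_permutations`
#' @export
permanova <- function(d, metadata, factor_name, n_permutations = 999, seed = 1L) {
  labels <- attr(d, "Labels")
  if (!factor_name %in% names(metadata))
    stop("metadata has no column '", factor_name, "'", call. = FALSE)
  md <- metadata[match(labels, metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id)))
    stop("metadata does not cover all samples in the distance matrix", call. = FALSE)
  f <- factor(md[[factor_name]])
  if (nlevels(droplevels(f)) < 2)
    stop("factor '", factor_name, "' has fewer than 2 levels", call. = FALSE)
  df <- data.frame(.group = droplevels(f))
  fit <- withr::with_seed(as.integer(seed),
    vegan::adonis2(d ~ .group, data = df, permutations = n_permutations))
  list(factor = factor_name,
       R2 = fit$R2[1],
       pseudo_F = fit$F[1],
       p_value = fit$`Pr(>F)`[1],
       n_permutations = as.integer(n_permutations))
}
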