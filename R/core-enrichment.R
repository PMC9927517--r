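#' Identify core microbiome taxa
#'
#' Core taxa are ASVs present in a required fraction of samples (100% by
#' default) with mean relative abundance above a floor (0.1% by default) —
#' the standard prevalence-abundance definition of a host-associated core.
#' Prevalence is the fraction of samples with a nonzero count; abundance is
#' the mean of per-sample relative abundances. The rule is a strict AND, and
#' raising either threshold can only shrink the core set.
#'
#' @param x a [feature_table()]
#' @param prevalence_min required prevalence in `(0, 1]` (default 1: present
#'   in every sample)
#' @param abundance_min mean relative abundance must exceed this value
#'   (default 0.001, i.e. 0.1%)
#' @return data.frame with columns `taxon_id`, `kingdom` (if available),
#'   `prevalence`, `mean_relabund`, restricted to the core taxa
#' @export
core_taxa <- function(x, prevalence_min = 1.0, abundance_min = 0.001) {
  stopifnot(inherits(x, "feature_table"))
  if (prevalence_min <= 0 || prevalence_min > 1)
    stop("`prevalence_min` must be in (0, 1]", call. = FALSE)
  if (abundance_min <= 0 || abundance_min > 1)
    stop("`abundance_min` must be in (0, 1]", call. = FALSE)
  prev <- rowMeans(x$counts > 0)
  mean_ra <- rowMeans(relative_abundance(x))
  keep <- prev >= prevalence_min & mean_ra > abundance_min
  out <- data.frame(taxon_id = taxon_ids(x)[keep],
                    prevalence = unname(prev[keep]),
                    mean_relabund = unname(mean_ra[keep]),
                    stringsAsFactors = FALSE)
  if (!is.null(x$kingdom))
    out <- cbind(out[1], kingdom = unname(x$kingdom[keep]), out[-1])
  out
}

#' Classify taxa enriched between two groups
#'
#' Two-group differential relative abundance with the published decision
#' rule |log2 fold change| > 2 AND Benjamini-Hochberg FDR < 0.01. The fold
#' change is the ratio of pseudocount-shifted group mean relative
#' abundances; significance comes from a two-sided Wilcoxon rank-sum test
#' on per-sample relative abundances, BH-adjusted across taxa. (This is a
#' nonparametric stand-in for a negative-binomial GLM fit; the thresholds,
#' not the test statistic, define the published classification.)
#'
#' @param x a [feature_table()]
#' @param metadata aligned metadata (see [align_metadata()])
#' @param group_factor metadata column with exactly two levels; each level
#'   needs >= 3 samples for the rank-sum test to be defined
#' @param lfc_min absolute log2 fold-change threshold (default 2)
#' @param fdr_max BH-adjusted p threshold (default 0.01)
#' @param pseudocount added to both group means before the ratio; default
#'   is half the smallest nonzero taxon mean relative abundance
#' @return data.frame per taxon: `taxon_id`, `log2fc` (first level over the
#'   second, with a `wild` level always the numerator),
#'   `p_value`, `p_adjusted`, `class` in `<level1>_enriched`,
#'   `<level2>_enriched`, `unchanged`
#' @export
enrichment <- function(x, metadata, group_factor = "genotype",
                       lfc_min = 2, fdr_max = 0.01, pseudocount = NULL) {
  md <- align_metadata(x, metadata)
  f <- droplevels(factor(md[[group_factor]]))
  if (nlevels(f) != 2)
    stop("`", group_factor, "` must have exactly two levels", call. = FALSE)
  # orient the fold change wild-over-cultivated when those labels are in play
  if ("wild" %in% levels(f)) f <- stats::relevel(f, "wild")
  if (any(table(f) < 3))
    stop("each group needs >= 3 samples for the rank-sum test", call. = FALSE)
  lv <- levels(f)
  ra <- relative_abundance(x)
  g1 <- ra[, f == lv[1], drop = FALSE]
  g2 <- ra[, f == lv[2], drop = FALSE]
  m1 <- rowMeans(g1)
  m2 <- rowMeans(g2)
  if (is.null(pseudocount)) {
    nz <- rowMeans(ra)
    nz <- nz[nz > 0]
    pseudocount <- if (length(nz)) min(nz) / 2 else 1e-6
  }
  log2fc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  p <- vapply(seq_len(nrow(ra)), function(i) {
    if (all(g1[i, ] == g1[i, 1]) && all(g2[i, ] == g2[i, 1]) &&
        g1[i, 1] == g2[i, 1]) return(1)
    suppressWarnings(stats::wilcox.test(g1[i, ], g2[i, ])$p.value)
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  cls <- rep("unchanged", nrow(ra))
  sig <- abs(log2fc) > lfc_min & padj < fdr_max
  cls[sig & log2fc > 0] <- paste0(lv[1], "_enriched")
  cls[sig & log2fc < 0] <- paste0(lv[2], "_enriched")
  data.frame(taxon_id = taxon_ids(x), log2fc = log2fc, p_value = p,
             p_adjusted = padj, class = cls, stringsAsFactors = FALSE)
}
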