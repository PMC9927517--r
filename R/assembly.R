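#' Partition sample pairs among five assembly processes
#'
#' The two-step null-model decision rule: a pair with betaNTI above `+nti_cut`
#' is assigned to heterogeneous selection and below `-nti_cut` to homogeneous
#' selection; among the remaining (|betaNTI| <= cut) pairs, Raup-Crick above
#' `+rc_cut` indicates dispersal limitation (acting with drift), below
#' `-rc_cut` homogenizing dispersal, and anything else undominated drift.
#' Pairs with missing betaNTI are excluded from the denominator and counted.
#'
#' @param bnti sample-by-sample betaNTI matrix (see [beta_nti()])
#' @param rc aligned Raup-Crick matrix (see [raup_crick_bray()])
#' @param nti_cut selection threshold on |betaNTI| (default 2)
#' @param rc_cut dispersal threshold on |RC| (default 0.95)
#' @return a `process_fractions`: list with `fractions` (named, sums to 1),
#'   `counts`, `n_pairs`, `n_excluded`
#' @export
partition_processes <- function(bnti, rc, nti_cut = 2, rc_cut = 0.95) {
  if (is.list(bnti) && !is.null(bnti$bnti)) bnti <- bnti$bnti
  if (!all(dim(bnti) == dim(rc)) ||
      !identical(dimnames(bnti)[[1]], dimnames(rc)[[1]]))
    stop("betaNTI and RC matrices are not aligned", call. = FALSE)
  ut <- upper.tri(bnti)
  b <- bnti[ut]; r <- rc[ut]
  excluded <- is.na(b)
  b <- b[!excluded]; r <- r[!excluded]
  cls <- ifelse(b > nti_cut, "heterogeneous_selection",
         ifelse(b < -nti_cut, "homogeneous_selection",
         ifelse(!is.na(r) & r > rc_cut, "dispersal_limitation",
         ifelse(!is.na(r) & r < -rc_cut, "homogenizing_dispersal", "drift"))))
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "drift")
  counts <- table(factor(cls, levels = lev))
  structure(list(fractions = as.numeric(counts) / length(cls),
                 counts = stats::setNames(as.integer(counts), lev),
                 n_pairs = length(cls), n_excluded = sum(excluded)),
            class = "process_fractions")
}

#' @export
print.process_fractions <- function(x, ...) {
  cat("<process_fractions> over", x$n_pairs, "pairs",
      if (x$n_excluded) paste0("(", x$n_excluded, " excluded)"), "\n")
  fr <- stats::setNames(x$fractions, names(x$counts))
  for (nm in names(fr))
    cat(sprintf("  %-24s %5.1f%%\n", nm, 100 * fr[nm]))
  invisible(x)
}

#' Levins' niche breadth per taxon
#'
#' `B_i = 1 / sum_j P_ij^2` where `P_ij` is the proportion of taxon i's
#' total abundance found in sample j. B ranges from 1 (confined to one
#' sample) to the number of samples (perfectly even occupancy). The
#' community-level breadth `Bcom` is the mean over the included taxa.
#' All-zero taxa are excluded with a warning.
#'
#' @param x a [feature_table()]
#' @return a `niche_breadth`: list with `taxa` (data.frame: taxon_id, B)
#'   and `Bcom`
#' @export
niche_breadth <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  tot <- rowSums(x$counts)
  drop <- tot == 0
  if (any(drop))
    warning("excluding ", sum(drop), " all-zero taxon/taxa from niche breadth")
  m <- x$counts[!drop, , drop = FALSE]
  P <- m / rowSums(m)
  B <- 1 / rowSums(P^2)
  structure(list(taxa = data.frame(taxon_id = rownames(m), B = unname(B),
                                   stringsAsFactors = FALSE),
                 Bcom = mean(B)),
            class = "niche_breadth")
}
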