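#' Abundance-based Raup-Crick (Bray-Curtis) null dissimilarity
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity to
#' a stochastic-assembly null: each null community keeps its sample's
#' observed richness and read total, draws that many taxa without
#' replacement with probability proportional to occupancy across all
#' samples, seeds each drawn taxon with one read and allocates the rest
#' multinomially in proportion to the taxa's overall relative abundances.
#' `RC = ((#null < obs) + 0.5 * (#null = obs)) / n_null`, rescaled to
#' `(RC - 0.5) * 2` so values lie in [-1, 1]. RC > 0.95 flags communities
#' less similar than expected by chance (dispersal limitation plus drift);
#' RC < -0.95 flags homogenizing dispersal.
#'
#' @param x a [feature_table()] with >= 2 samples
#' @param n_null null draws per pair (default 999)
#' @param seed integer seed
#' @return symmetric sample-by-sample matrix in [-1, 1], `NA` diagonal
#' @export
raup_crick_bray <- function(x, n_null = 999, seed = 1L) {
  stopifnot(inherits(x, "feature_table"))
  counts <- x$counts
  n_s <- ncol(counts)
  if (n_s < 2) stop("need >= 2 samples", call. = FALSE)
  rich <- colSums(counts > 0)
  zero <- colnames(counts)[rich == 0]
  if (length(zero))
    stop("sample(s) with richness 0: ", paste(zero, collapse = ", "), call. = FALSE)
  occupancy <- rowSums(counts > 0)
  pool_ra <- rowSums(counts) / sum(counts)
  totals <- colSums(counts)
  ra <- relative_abundance(x)
  n_t <- nrow(counts)

  null_community <- function(richness, reads) {
    drawn <- sample.int(n_t, richness, prob = occupancy)
    com <- numeric(n_t)
    com[drawn] <- 1
    extra <- reads - richness
    if (extra > 0) {
      w <- pool_ra[drawn]
      if (sum(w) == 0) w <- rep(1, length(drawn))
      com[drawn] <- com[drawn] + stats::rmultinom(1, extra, w)[, 1]
    }
    com / sum(com)
  }
  bc <- function(u, v) sum(abs(u - v)) / sum(u + v)

  out <- matrix(NA_real_, n_s, n_s, dimnames = list(colnames(counts), colnames(counts)))
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_s - 1)) {
      for (l in seq((k + 1), n_s)) {
        obs <- bc(ra[, k], ra[, l])
        null_bc <- vapply(seq_len(n_null), function(r)
          bc(null_community(rich[k], totals[k]), null_community(rich[l], totals[l])),
          numeric(1))
        rc <- (sum(null_bc < obs) + 0.5 * sum(null_bc == obs)) / n_null
        out[k, l] <- out[l, k] <- (rc - 0.5) * 2
      }
    }
  })
  out
}
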