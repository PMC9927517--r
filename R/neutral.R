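#' Fit the Sloan neutral community model
#'
#' Relates each ASV's occurrence frequency (fraction of samples where it is
#' detected) to its mean relative abundance p under the neutral expectation
#' that local relative abundances follow Beta(Nm*p, Nm*(1-p)). The predicted
#' detection frequency at detection limit d is `1 - pbeta(d, Nm*p, Nm*(1-p))`;
#' Nm is fitted by bounded least squares (golden-section search on log Nm)
#' against the observed frequencies. R-squared is `1 - SSres/SStot` of that
#' fit. Each taxon is then classified against the 95% Wilson score interval
#' around its predicted frequency at n = number of samples: `above` (more
#' frequent than neutrality predicts, i.e. selected for / widely dispersed),
#' `within`, or `below`. The migration rate is `m = Nm / N` with N the mean
#' per-sample read depth.
#'
#' @param x a [feature_table()] with >= 10 samples
#' @param detection_limit abundance below which a taxon is considered
#'   undetected; default `1/N`, the single-read limit
#' @return a `neutral_fit`: list with `m`, `Nm`, `N`, `R2`,
#'   `detection_limit`, `fraction_above`, `fraction_below`,
#'   `fraction_deviating`, and `taxa` (per-ASV data.frame: taxon_id,
#'   mean_relabund, obs_freq, pred_freq, lower, upper, partition)
#' @export
fit_neutral <- function(x, detection_limit = NULL) {
  stopifnot(inherits(x, "feature_table"))
  n_s <- n_samples(x)
  if (n_s < 10)
    stop("neutral fit needs >= 10 samples (got ", n_s, ")", call. = FALSE)
  N <- mean(colSums(x$counts))
  d <- if (is.null(detection_limit)) 1 / N else detection_limit
  ra <- relative_abundance(x)
  p <- rowMeans(ra)
  freq <- rowMeans(x$counts > 0)
  keep <- p > 0 & freq > 0
  p <- p[keep]; freq <- freq[keep]
  ids <- taxon_ids(x)[keep]
  pred_at <- function(Nm) 1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
  sse <- function(logNm) sum((freq - pred_at(exp(logNm)))^2)
  opt <- stats::optimize(sse, interval = log(c(1e-3, 1e9)))
  if (!is.finite(opt$objective))
    stop("neutral fit failed: objective non-finite at optimum (log Nm = ",
         round(opt$minimum, 3), ")", call. = FALSE)
  Nm <- exp(opt$minimum)
  pred <- pred_at(Nm)
  sstot <- sum((freq - mean(freq))^2)
  R2 <- if (sstot > 0) 1 - opt$objective / sstot else NA_real_
  ci <- wilson_interval(pred, n_s)
  partition <- ifelse(freq > ci$upper, "above",
                      ifelse(freq < ci$lower, "below", "within"))
  fr_above <- mean(partition == "above")
  fr_below <- mean(partition == "below")
  structure(list(
    m = Nm / N, Nm = Nm, N = N, R2 = R2, detection_limit = d,
    fraction_above = fr_above, fraction_below = fr_below,
    fraction_deviating = fr_above + fr_below,
    taxa = data.frame(taxon_id = ids, mean_relabund = unname(p),
                      obs_freq = unname(freq), pred_freq = unname(pred),
                      lower = unname(ci$lower), upper = unname(ci$upper),
                      partition = unname(partition), stringsAsFactors = FALSE)),
    class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("<neutral_fit> Nm = ", signif(x$Nm, 4), " (m = ", signif(x$m, 4),
      ", N = ", round(x$N, 1), ")\n",
      "  R2 = ", if (is.na(x$R2)) "NA (no frequency variance)" else round(x$R2, 3),
      "; ", round(100 * x$fraction_deviating, 1),
      "% of taxa deviate from neutrality (",
      round(100 * x$fraction_above, 1), "% above, ",
      round(100 * x$fraction_below, 1), "% below)\n", sep = "")
  invisible(x)
}

wilson_interval <- function(p_hat, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}
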