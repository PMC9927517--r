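#' Construct a validated ASV feature table
#'
#' The central data container of the package: a taxon-by-sample matrix of
#' non-negative integer read counts, with an optional per-taxon kingdom label
#' (`"bacteria"` or `"fungi"`) used by the inter-kingdom network stage.
#'
#' @param counts integer matrix, taxa in rows, samples in columns. Row and
#'   column names are required and must be unique: they are the ASV and sample
#'   identifiers used throughout the pipeline.
#' @param kingdom optional character vector of per-taxon kingdom labels,
#'   values in `c("bacteria", "fungi")`, recycled never; length must equal
#'   `nrow(counts)`.
#' @return an object of class `feature_table`: a list with elements `counts`
#'   (integer matrix) and `kingdom` (character vector or `NULL`).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 9L), nrow = 3,
#'             dimnames = list(paste0("ASV", 1:3), c("s1", "s2")))
#' ft <- feature_table(m, kingdom = c("bacteria", "bacteria", "fungi"))
#' n_taxa(ft)
#' @export
feature_table <- function(counts, kingdom = NULL) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have row (taxon) and column (sample) names", call. = FALSE)
  dup_t <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_t))
    stop("duplicate taxon ID(s): ", paste(unique(dup_t), collapse = ", "), call. = FALSE)
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s))
    stop("duplicate sample ID(s): ", paste(unique(dup_s), collapse = ", "), call. = FALSE)
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (!is.null(kingdom)) {
    if (length(kingdom) != nrow(counts))
      stop("`kingdom` must have one label per taxon", call. = FALSE)
    bad <- setdiff(unique(kingdom), c("bacteria", "fungi"))
    if (length(bad))
      stop("unknown kingdom label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    kingdom <- as.character(kingdom)
    names(kingdom) <- rownames(counts)
  }
  structure(list(counts = counts, kingdom = kingdom), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$counts), " taxa x ", ncol(x$counts), " samples\n", sep = "")
  if (!is.null(x$kingdom)) {
    tab <- table(x$kingdom)
    cat("  kingdoms: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("  total reads: ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`
#' @export
n_taxa <- function(x) nrow(x$counts)

#' @rdname feature_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' @rdname feature_table
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Subset a feature table by taxa or samples
#'
#' Order of the retained rows/columns follows the `taxa`/`samples` argument;
#' kingdom labels are carried along.
#'
#' @param x a `feature_table`
#' @param taxa character or logical or integer index of taxa to keep
#' @param samples character or logical or integer index of samples to keep
#' @export
subset_table <- function(x, taxa = NULL, samples = NULL) {
  counts <- x$counts
  kingdom <- x$kingdom
  if (!is.null(taxa)) {
    counts <- counts[taxa, , drop = FALSE]
    if (!is.null(kingdom)) kingdom <- kingdom[rownames(counts)]
  }
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  feature_table(counts, kingdom = unname(kingdom))
}

#' Per-sample relative abundances
#'
#' Divides every sample (column) by its total read count.
#'
#' @param x a `feature_table` or a non-negative numeric matrix with dimnames.
#' @return a numeric taxon-by-sample matrix whose columns each sum to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "feature_table")) x$counts else x
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "), call. = FALSE)
  sweep(m, 2, tot, "/")
}

#' Remove rare taxa by mean relative abundance
#'
#' Drops ASVs whose mean per-sample relative abundance falls below a floor;
#' used before network construction to mitigate zero inflation. The default
#' floor of 0.01% (1e-4) is the conventional rare-ASV cut-off for
#' co-occurrence analysis. The mean is taken over per-sample fractions, so
#' the filter is depth-independent. Idempotent: the retained taxa keep mean
#' relative abundances at or above the threshold after refiltering.
#'
#' @param x a `feature_table`
#' @param min_mean_relabund keep taxa with mean relative abundance >= this
#'   value; must lie in `[0, 1)`.
#' @return a `feature_table` with the retained taxa in their original order.
#' @export
filter_rare <- function(x, min_mean_relabund = 1e-4) {
  stopifnot(inherits(x, "feature_table"))
  if (!is.numeric(min_mean_relabund) || length(min_mean_relabund) != 1 ||
      min_mean_relabund < 0 || min_mean_relabund >= 1)
    stop("`min_mean_relabund` must be a single value in [0, 1)", call. = FALSE)
  mean_ra <- rowMeans(relative_abundance(x))
  subset_table(x, taxa = mean_ra >= min_mean_relabund)
}

#' Rarefy a feature table to even depth
#'
#' Seeded subsampling without replacement to a common per-sample depth, for
#' sensitivity checks. All package statistics operate on relative abundances
#' by default, so rarefaction is optional.
#'
#' @param x a `feature_table`
#' @param depth target reads per sample; samples below `depth` are dropped
#'   with a warning.
#' @param seed integer seed controlling the subsample.
#' @export
rarefy_table <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "feature_table"))
  tot <- colSums(x$counts)
  keep <- tot >= depth
  if (!all(keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth)
  m <- x$counts[, keep, drop = FALSE]
  out <- withr::with_seed(seed, {
    apply(m, 2, function(col) {
      drawn <- sample(rep.int(seq_along(col), col), depth)
      tabulate(drawn, nbins = length(col))
    })
  })
  rownames(out) <- rownames(m)
  feature_table(out, kingdom = unname(x$kingdom))
}
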