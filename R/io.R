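#' Read and write the pipeline's tab-separated artifacts
#'
#' All tables are plain TSV, UTF-8. The feature table has ASVs in rows with
#' the header cell `#ASV_ID`, sample IDs as the remaining header fields and
#' integer counts in the body. Taxonomy files carry `#ASV_ID`, `kingdom`
#' and `genus` columns; metadata files carry `sample_id`, `site`, `genotype`
#' and `replicate`. Row and column order is preserved exactly, so a
#' write/read round trip reproduces the object.
#'
#' @param path file path
#' @param taxonomy optional path to a taxonomy TSV whose `kingdom` column is
#'   attached to the table.
#' @return `read_feature_table`: a [feature_table()].
#' @name tables_io
NULL

#' @rdname tables_io
#' @export
read_feature_table <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs an ID column and >=1 sample", call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path, call. = FALSE)
  bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer count for ASV ", ids[bad[1, 1]], ", sample ",
         colnames(m)[bad[1, 2]], call. = FALSE)
  rownames(m) <- ids
  kingdom <- NULL
  if (!is.null(taxonomy)) {
    tax <- read_taxonomy(taxonomy)
    missing <- setdiff(ids, tax$taxon_id)
    if (length(missing))
      stop("taxonomy missing ASV(s): ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    kingdom <- tax$kingdom[match(ids, tax$taxon_id)]
  }
  feature_table(m, kingdom = kingdom)
}

#' @rdname tables_io
#' @param x object to write
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(`#ASV_ID` = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tables_io
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  names(df)[1] <- "taxon_id"
  dup <- df$taxon_id[duplicated(df$taxon_id)]
  if (length(dup))
    stop("duplicate ASV ID(s) in taxonomy: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname tables_io
#' @export
write_taxonomy <- function(x, path) {
  df <- x
  names(df)[1] <- "#ASV_ID"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' @param path TSV with columns `sample_id`, `site`, `genotype`, `replicate`.
#' @return data.frame with `site` and `genotype` as factors.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata a metadata data.frame to validate in place
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "site", "genotype", "replicate")
  missing <- setdiff(need, names(metadata))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup))
    stop("duplicate sample ID(s) in metadata: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  metadata$site <- factor(metadata$site)
  metadata$genotype <- factor(metadata$genotype)
  metadata
}

#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align metadata rows to a feature table's samples
#'
#' Reorders metadata rows to match the table's sample order and errors,
#' naming the offending IDs, if the two do not describe the same samples.
#'
#' @param x a `feature_table`
#' @param metadata a metadata data.frame with a `sample_id` column
#' @export
align_metadata <- function(x, metadata) {
  metadata <- validate_metadata(metadata)
  extra <- setdiff(metadata$sample_id, sample_ids(x))
  missing <- setdiff(sample_ids(x), metadata$sample_id)
  if (length(extra) || length(missing))
    stop("metadata/sample mismatch; missing from metadata: [",
         paste(missing, collapse = ", "), "], absent from table: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  metadata[match(sample_ids(x), metadata$sample_id), , drop = FALSE]
}

#' Read a phylogenetic tree with named tips
#'
#' Thin wrapper over [ape::read.tree()] that checks for the branch lengths
#' the phylogenetic null models require.
#'
#' @param path Newick file
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; beta-MNTD requires them", call. = FALSE)
  tree
}
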