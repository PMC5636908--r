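#' Feature-by-gene molecule count matrix
#'
#' The central container of the workflow: nonnegative integer molecule
#' counts for every array feature and gene, carrying per-feature array
#' coordinates and (optionally) a tissue flag.
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids
#'   as character), genes in columns.
#' @param features data.frame of feature metadata with at least
#'   `feature_id`; typically also `barcode`, `x`, `y`, grid coordinates.
#' @param tissue Optional logical vector (or feature-id subset) marking
#'   features under tissue.
#' @return Object of class `st_counts`.
#' @export
st_counts <- function(counts, features, tissue = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (nrow(counts) != nrow(features))
    stop("counts and features disagree on feature number", call. = FALSE)
  if (anyDuplicated(features$feature_id) || anyDuplicated(colnames(counts)))
    stop("feature ids and gene names must be unique", call. = FALSE)
  rownames(counts) <- as.character(features$feature_id)
  if (!is.null(tissue) && !is.logical(tissue))
    tissue <- features$feature_id %in% tissue
  structure(list(counts = counts, features = features, tissue = tissue),
            class = "st_counts")
}

#' @export
print.st_counts <- function(x, ...) {
  cat(sprintf("st_counts: %d features x %d genes, %d molecules%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              if (!is.null(x$tissue))
                sprintf(" (%d features under tissue)", sum(x$tissue))
              else ""))
  invisible(x)
}

#' @export
dim.st_counts <- function(x) dim(x$counts)

.subset_features <- function(m, keep) {
  st_counts(m$counts[keep, , drop = FALSE],
            m$features[keep, , drop = FALSE],
            if (!is.null(m$tissue)) m$tissue[keep])
}

#' Restrict a count matrix to features under tissue
#'
#' @param m An [st_counts()] matrix.
#' @param mask Vector of feature ids judged under tissue, or `NULL` to use
#'   the matrix's own tissue flag.
#' @return The restricted `st_counts`; the gene axis is unchanged.
#' @export
select_under_tissue <- function(m, mask = NULL) {
  stopifnot(inherits(m, "st_counts"))
  if (is.null(mask)) {
    if (is.null(m$tissue)) stop("no tissue mask available", call. = FALSE)
    return(.subset_features(m, m$tissue))
  }
  unknown <- setdiff(mask, m$features$feature_id)
  if (length(unknown) > 0)
    stop("unknown feature id(s) in mask: ",
         paste(utils::head(unknown), collapse = ", "), call. = FALSE)
  .subset_features(m, m$features$feature_id %in% mask)
}

#' Filter features by number of expressed genes
#'
#' Keeps features expressing (count > 0) at least `min_genes` genes — the
#' workflow uses 500 for the feature-level heatmap and 100 for spatial
#' visualization and embedding.
#'
#' @param m An `st_counts`.
#' @param min_genes Minimum number of genes with positive count.
#' @return Filtered `st_counts`.
#' @export
filter_features_by_genes <- function(m, min_genes) {
  stopifnot(inherits(m, "st_counts"), min_genes >= 0)
  .subset_features(m, rowSums(m$counts > 0) >= min_genes)
}

#' Aggregate a section to sample level
#'
#' Sums molecule counts over all features (all spatial barcodes), giving
#' the per-gene totals a homogenized bulk measurement of the same section
#' would see.
#'
#' @param m An `st_counts`.
#' @return Named numeric vector of per-gene totals.
#' @export
aggregate_sample <- function(m) {
  stopifnot(inherits(m, "st_counts"))
  colSums(m$counts)
}

#' Per-group feature summaries
#'
#' For each feature group: the mean number of unique transcripts (molecule
#' count sum) and unique genes (genes with positive count) per feature,
#' with standard errors. "Unique transcripts" are post-deduplication
#' molecule counts; "unique genes" are genes with nonzero count.
#'
#' @param m An `st_counts`.
#' @param groups Named list of feature-id vectors, or a factor/character
#'   vector of group labels aligned with the features.
#' @return data.frame: `group`, `n`, `mean_transcripts`, `se_transcripts`,
#'   `mean_genes`, `se_genes`, `se_defined` (FALSE for singleton groups,
#'   whose s.e. is reported as 0).
#' @export
per_feature_summaries <- function(m, groups) {
  stopifnot(inherits(m, "st_counts"))
  if (!is.list(groups)) {
    stopifnot(length(groups) == nrow(m$counts))
    groups <- split(m$features$feature_id, groups)
  }
  tx <- rowSums(m$counts)
  ng <- rowSums(m$counts > 0)
  ids <- m$features$feature_id
  rows <- lapply(names(groups), function(g) {
    idx <- match(groups[[g]], ids)
    if (length(idx) == 0 || anyNA(idx))
      stop("empty or unknown group: ", g, call. = FALSE)
    n <- length(idx)
    se <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else 0
    data.frame(group = g, n = n,
               mean_transcripts = mean(tx[idx]),
               se_transcripts = se(tx[idx]),
               mean_genes = mean(ng[idx]),
               se_genes = se(ng[idx]),
               se_defined = n > 1)
  })
  do.call(rbind, rows)
}

#' Write / read a count matrix
#'
#' Two plain-text formats: `"tsv"` — a dense table with feature metadata
#' columns followed by one column per gene; `"mtx"` — a MatrixMarket
#' coordinate file plus `.features.tsv` / `.genes.tsv` sidecars. Both
#' round-trip losslessly.
#'
#' @param m An `st_counts`.
#' @param path Destination path (for `"mtx"`, the `.mtx` path; sidecars
#'   are derived from it).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "mtx")) {
  stopifnot(inherits(m, "st_counts"))
  format <- match.arg(format)
  meta <- m$features
  if (!is.null(m$tissue)) meta$tissue <- m$tissue
  if (format == "tsv") {
    df <- cbind(meta, as.data.frame(m$counts, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), path)
    utils::write.table(meta, paste0(path, ".features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(colnames(m$counts), paste0(path, ".genes.tsv"))
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
    meta_cols <- intersect(
      c("feature_id", "barcode", "x", "y", "grid_col", "grid_row", "tissue"),
      names(df))
    counts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
    storage.mode(counts) <- "integer"
    st_counts(counts, df[, setdiff(meta_cols, "tissue"), drop = FALSE],
              tissue = if ("tissue" %in% meta_cols) df$tissue)
  } else {
    counts <- as.matrix(Matrix::readMM(path))
    meta <- utils::read.table(paste0(path, ".features.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    colnames(counts) <- readLines(paste0(path, ".genes.tsv"))
    st_counts(counts, meta[, setdiff(names(meta), "tissue"), drop = FALSE],
              tissue = if ("tissue" %in% names(meta)) meta$tissue)
  }
}
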