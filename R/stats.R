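#' Median-of-ratios size factors
#'
#' The DESeq-style normalization estimator: the size factor of a column
#' unit (sample or feature) is the median, over genes whose geometric mean
#' across units is positive, of the ratio of that unit's count to the
#' gene's geometric mean.
#'
#' @param counts Numeric matrix, units in rows and genes in columns (the
#'   transpose of the usual genes-by-samples table is accepted via
#'   `units_in_rows`).
#' @param units_in_rows If `TRUE` (default) rows are the normalization
#'   units.
#' @param type `"ratio"` (strict estimator; errors when no gene is
#'   positive in every unit) or `"poscounts"` (geometric means over
#'   positive counts only, with per-unit medians over that unit's positive
#'   genes — usable on zero-rich feature-level matrices, where strict
#'   reference genes essentially never exist). The two coincide on
#'   zero-free tables.
#' @return Positive numeric vector of per-unit size factors.
#' @export
size_factors <- function(counts, units_in_rows = TRUE,
                         type = c("ratio", "poscounts")) {
  type <- match.arg(type)
  m <- if (units_in_rows) counts else t(counts)
  if (type == "ratio") {
    loggeo <- colMeans(log(m))        # -Inf when any unit has a zero
    use <- is.finite(loggeo)
    if (!any(use))
      stop("no reference genes: every gene has a zero count in some unit",
           call. = FALSE)
    sf <- apply(m[, use, drop = FALSE], 1, function(row)
      exp(stats::median(log(row) - loggeo[use])))
  } else {
    lm <- log(m)
    lm[!is.finite(lm)] <- NA
    npos <- colSums(!is.na(lm))
    # geometric mean over positive counts, zeros excluded from the mean
    loggeo <- colSums(lm, na.rm = TRUE) / pmax(npos, 1)
    use <- npos > 0
    if (!any(use))
      stop("no reference genes: the matrix is all zero", call. = FALSE)
    sf <- apply(lm[, use, drop = FALSE], 1, function(lrow) {
      r <- (lrow - loggeo[use])[!is.na(lrow)]
      if (length(r) == 0) NA_real_ else exp(stats::median(r))
    })
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor; unit without usable reference counts",
         call. = FALSE)
  sf
}

#' Pseudocount-log normalization
#'
#' Divides each unit's counts by its size factor, adds a pseudocount and
#' takes logarithms: `value = log_base(pseudocount + count/size_factor)`.
#' The natural log is the default base.
#'
#' @param counts Units-by-genes numeric matrix.
#' @param sf Per-unit size factors ([size_factors()]); `NULL` estimates
#'   them from `counts`.
#' @param pseudocount Added before the log (default 1).
#' @param base Log base (default `exp(1)`).
#' @return Matrix of normalized log values, same dimensions.
#' @export
normalize_log <- function(counts, sf = NULL, pseudocount = 1,
                          base = exp(1)) {
  if (is.null(sf)) sf <- size_factors(counts)
  stopifnot(length(sf) == nrow(counts), all(sf > 0))
  log(pseudocount + counts / sf, base = base)
}

#' Pairwise sample correlation
#'
#' The section-level comparison: both matrices are aggregated over all
#' spatial barcodes to per-gene totals, genes expressed in neither sample
#' are removed, the resulting two-sample table is size-factor normalized
#' and pseudocount-log transformed, and the Pearson correlation over genes
#' is returned.
#'
#' @param a,b Two [st_counts()] matrices (or named per-gene total vectors)
#'   sharing a gene axis.
#' @param pseudocount,base Passed to [normalize_log()].
#' @return Pearson correlation coefficient.
#' @export
pairwise_correlation <- function(a, b, pseudocount = 1, base = exp(1)) {
  va <- if (inherits(a, "st_counts")) aggregate_sample(a) else a
  vb <- if (inherits(b, "st_counts")) aggregate_sample(b) else b
  genes <- intersect(names(va), names(vb))
  if (length(genes) == 0) stop("no shared genes", call. = FALSE)
  va <- va[genes]; vb <- vb[genes]
  keep <- va > 0 | vb > 0
  tab <- rbind(va[keep], vb[keep])
  norm <- normalize_log(tab, size_factors(tab), pseudocount, base)
  if (stats::sd(norm[1, ]) == 0 || stats::sd(norm[2, ]) == 0)
    stop("degenerate sample: constant normalized profile", call. = FALSE)
  stats::cor(norm[1, ], norm[2, ])
}

#' PCA on the top expressed genes
#'
#' Normalizes a samples-by-genes table of aggregated counts, restricts it
#' to the `n_top` genes with the highest mean normalized value, and runs a
#' centered (unscaled) principal component analysis via singular value
#' decomposition.
#'
#' @param counts Samples-by-genes aggregated count matrix (>= 2 samples).
#' @param n_top Number of top expressed genes to keep (default 1000).
#' @param pseudocount,base Passed to [normalize_log()].
#' @return List with `scores` (samples x PCs), `loadings` (genes x PCs),
#'   `var_frac` (variance fractions summing to 1) and `genes` (the genes
#'   used).
#' @export
pca_top_expressed <- function(counts, n_top = 1000, pseudocount = 1,
                              base = exp(1)) {
  if (nrow(counts) < 2) stop("need at least two samples", call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene_", seq_len(ncol(counts)))
  norm <- normalize_log(counts, size_factors(counts), pseudocount, base)
  if (ncol(norm) < n_top) {
    warning(sprintf("only %d genes available; using all", ncol(norm)))
    n_top <- ncol(norm)
  }
  mean_expr <- colMeans(norm)
  ord <- order(-mean_expr, colnames(norm))
  genes <- colnames(norm)[ord[seq_len(n_top)]]
  p <- stats::prcomp(norm[, genes, drop = FALSE], center = TRUE,
                     scale. = FALSE)
  list(scores = p$x, loadings = p$rotation,
       var_frac = p$sdev^2 / sum(p$sdev^2), genes = genes)
}

#' Top-variance genes across features
#'
#' Ranks genes by descending variance of their normalized values across
#' features, the selection behind the feature-level expression heatmap
#' (typically preceded by the >= 500 expressed-genes feature filter).
#' Ties break lexicographically by gene name.
#'
#' @param norm Features-by-genes normalized matrix ([normalize_log()]).
#' @param n_top Number of genes to return (default 1000; capped at the
#'   gene count).
#' @return Character vector of gene names, most variable first.
#' @export
top_variance_genes <- function(norm, n_top = 1000) {
  v <- apply(norm, 2, stats::var)
  ord <- order(-v, colnames(norm))
  colnames(norm)[ord[seq_len(min(n_top, ncol(norm)))]]
}

#' Thresholded differential expression between two feature groups
#'
#' A negative-binomial Wald test with method-of-moments dispersion, applied
#' to size-factor-normalized counts, with Benjamini-Hochberg correction.
#' Per gene: group means of normalized counts `mA`, `mB`;
#' `log2FC = log2((mA+1)/(mB+1))` (the +1 shrinkage avoids division by
#' zero); the Wald statistic contrasts `log(mA+1)` and `log(mB+1)` with
#' delta-method standard errors under NB variance `v = m + alpha m^2`,
#' where `alpha` is a moment estimate pooled across both groups. A gene is
#' flagged as differentially expressed iff `|log2FC| > 1` and adjusted
#' p < 0.01.
#'
#' @param m An [st_counts()] matrix.
#' @param group_a,group_b Disjoint feature-id sets (>= 2 features each).
#' @param lfc_threshold,alpha_threshold The DE thresholds (defaults 1 and
#'   0.01).
#' @return data.frame: `gene`, `log2fc`, `pvalue`, `padj`, `de_flag`.
#' @export
differential_expression <- function(m, group_a, group_b,
                                    lfc_threshold = 1,
                                    alpha_threshold = 0.01) {
  stopifnot(inherits(m, "st_counts"))
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint", call. = FALSE)
  ia <- match(group_a, m$features$feature_id)
  ib <- match(group_b, m$features$feature_id)
  if (anyNA(ia) || anyNA(ib)) stop("unknown feature id", call. = FALSE)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 features for dispersion estimation",
         call. = FALSE)
  # features are the normalization units; the positive-counts variant
  # handles their zero-rich count profiles
  sf <- size_factors(m$counts[c(ia, ib), , drop = FALSE],
                     type = "poscounts")
  normed <- m$counts[c(ia, ib), , drop = FALSE] / sf
  A <- normed[seq_along(ia), , drop = FALSE]
  B <- normed[length(ia) + seq_along(ib), , drop = FALSE]
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, stats::var); vB <- apply(B, 2, stats::var)
  # pooled method-of-moments NB dispersion alpha: var = mu + alpha mu^2
  num <- (nA - 1) * (vA - mA) + (nB - 1) * (vB - mB)
  den <- (nA - 1) * mA^2 + (nB - 1) * mB^2
  alpha <- ifelse(den > 0, pmax(0, num / den), 0)
  varA <- mA + alpha * mA^2
  varB <- mB + alpha * mB^2
  se <- sqrt(varA / (nA * (mA + 1)^2) + varB / (nB * (mB + 1)^2))
  z <- ifelse(se > 0, (log(mA + 1) - log(mB + 1)) / se, 0)
  pvalue <- ifelse(mA == 0 & mB == 0, 1, 2 * stats::pnorm(-abs(z)))
  log2fc <- log2((mA + 1) / (mB + 1))
  padj <- stats::p.adjust(pvalue, method = "BH")
  data.frame(gene = colnames(m$counts), log2fc = log2fc, pvalue = pvalue,
             padj = padj,
             de_flag = abs(log2fc) > lfc_threshold & padj < alpha_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
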