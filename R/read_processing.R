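#' Truncate reads at homopolymer stretches
#'
#' Removes everything from the start of the first run of `min_run` or more
#' identical bases to the read end; reads without such a run are returned
#' unchanged. Truncation (rather than discarding the whole read) preserves
#' the informative 5' fragment; reads left shorter than the length filter
#' are removed downstream.
#'
#' @param seq Character vector of reads over `{A,C,G,T,N}`.
#' @param min_run Minimum run length that triggers truncation (default 15).
#' @return Character vector of truncated reads.
#' @export
trim_homopolymer <- function(seq, min_run = 15) {
  pat <- sprintf("([ACGTN])\\1{%d,}", min_run - 1)
  hit <- regexpr(pat, seq)
  out <- seq
  found <- hit > 0
  out[found] <- substr(seq[found], 1L, hit[found] - 1L)
  out
}

#' Quality-trim read 3' ends (BWA rule)
#'
#' Implements the read-trimming rule of the BWA aligner: scanning from the
#' 3' end, the read is cut before position `p*` where `p*` maximizes
#' `sum_{i=p..L}(Q - q_i)`, provided that maximum is positive; otherwise the
#' read is unchanged. Ties resolve to the latest position (shortest trim),
#' as in BWA's strict-improvement scan.
#'
#' @param seq Character vector of reads.
#' @param qual Character vector of Phred+33 quality strings, same lengths.
#' @param Q Quality threshold (default 20).
#' @return List with trimmed `seq` and `qual` character vectors.
#' @export
quality_trim <- function(seq, qual, Q = 20) {
  if (length(seq) != length(qual) || any(nchar(seq) != nchar(qual)))
    stop("sequence/quality length mismatch", call. = FALSE)
  n <- length(seq)
  if (n == 0) return(list(seq = seq, qual = qual))
  lens <- nchar(seq)
  L <- max(lens)
  # pad with phred = Q: padding contributes 0 to every suffix sum
  qm <- matrix(Q, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    if (lens[i] > 0) qm[i, seq_len(lens[i])] <- utf8ToInt(qual[i]) - 33L
  }
  d <- Q - qm
  # suffix sums S[, p] = sum_{i >= p} d[, i], computed right to left
  S <- d
  if (L > 1) for (p in (L - 1):1) S[, p] <- d[, p] + S[, p + 1]
  best <- do.call(pmax, as.data.frame(S))
  cut <- max.col(S, ties.method = "last")
  keep_len <- ifelse(best > 0, cut - 1L, lens)
  keep_len <- pmin(keep_len, lens)
  list(seq = substr(seq, 1L, keep_len), qual = substr(qual, 1L, keep_len))
}

#' Minimum-length read filter
#'
#' @param seq Character vector of reads.
#' @param min_len Minimum retained length (default 28).
#' @return Logical vector: `TRUE` = keep.
#' @export
length_filter <- function(seq, min_len = 28) {
  nchar(seq) >= min_len
}

#' Build a k-mer contaminant index
#'
#' @param contaminants Named character vector of contaminant sequences
#'   (an rRNA stand-in).
#' @param k K-mer size (default 21, must be >= 11).
#' @param theta Fraction of a read's k-mers that must hit the index for the
#'   read to be discarded (default 0.5, in (0,1]).
#' @return Object of class `contaminant_index`.
#' @export
contaminant_index <- function(contaminants, k = 21, theta = 0.5) {
  if (k < 11) stop("k must be >= 11", call. = FALSE)
  if (theta <= 0 || theta > 1) stop("theta must lie in (0,1]", call. = FALSE)
  kmers <- unique(unlist(lapply(contaminants, seq_kmers, k = k),
                         use.names = FALSE))
  structure(list(kmers = kmers, k = k, theta = theta),
            class = "contaminant_index")
}

#' Contaminant filter
#'
#' Discards a read when at least a fraction `theta` of its k-mers occur in
#' the contaminant index.
#'
#' @param seq Character vector of reads, each at least `k` long.
#' @param index A [contaminant_index()].
#' @return Logical vector: `TRUE` = keep (not contaminant).
#' @export
contaminant_filter <- function(seq, index) {
  stopifnot(inherits(index, "contaminant_index"))
  if (any(nchar(seq) < index$k))
    stop("read shorter than k; apply the length filter first", call. = FALSE)
  k <- index$k
  lens <- nchar(seq)
  K <- max(lens) - k + 1L
  hits <- numeric(length(seq))
  tot <- lens - k + 1L
  for (p in seq_len(K)) {
    valid <- lens >= p + k - 1L
    if (!any(valid)) break
    kms <- substr(seq[valid], p, p + k - 1L)
    hits[valid] <- hits[valid] + (kms %in% index$kmers)
  }
  hits / tot < index$theta
}

#' Build a k-mer gene index over a transcriptome
#'
#' Maps every transcript k-mer to the set of genes containing it; the
#' intersection-style voting of [assign_gene()] runs against this index,
#' standing in for spliced genome alignment plus annotation-overlap
#' counting.
#'
#' @param transcriptome Named character vector of transcript sequences.
#' @param k K-mer size (default 21).
#' @return Object of class `gene_index` with fields `kmer` (character),
#'   `gene_id` (integer; 0 marks k-mers shared by several genes), `multi`
#'   (list of gene-id sets for shared k-mers), `genes` (gene names), `k`.
#' @export
gene_index <- function(transcriptome, k = 21) {
  genes <- names(transcriptome)
  if (is.null(genes)) stop("transcriptome must be named", call. = FALSE)
  dt <- data.table::rbindlist(lapply(seq_along(transcriptome), function(i) {
    data.table::data.table(kmer = seq_kmers(transcriptome[[i]], k),
                           gid = i)
  }))
  dt <- unique(dt)
  n_by_kmer <- dt[, list(n = .N), by = "kmer"]
  single <- n_by_kmer[n_by_kmer$n == 1L, "kmer"]
  multi_kmers <- n_by_kmer[n_by_kmer$n > 1L, "kmer"]
  single_dt <- dt[dt$kmer %in% single$kmer]
  multi <- list()
  gid <- single_dt$gid
  kmer <- single_dt$kmer
  if (nrow(multi_kmers) > 0) {
    mdt <- dt[dt$kmer %in% multi_kmers$kmer]
    msets <- split(mdt$gid, mdt$kmer)
    kmer <- c(kmer, names(msets))
    gid <- c(gid, rep(0L, length(msets)))
    multi <- unname(msets)
    attr(multi, "kmer") <- names(msets)
  }
  structure(list(kmer = kmer, gene_id = as.integer(gid), multi = multi,
                 genes = genes, k = k),
            class = "gene_index")
}

# gene ids per k-mer matrix for a batch of reads; returns n x K integer
# matrix (NA = k-mer absent from index or offset beyond read end; 0 = k-mer
# shared by several genes)
.kmer_gene_matrix <- function(seq, index) {
  k <- index$k
  lens <- nchar(seq)
  K <- max(lens) - k + 1L
  n <- length(seq)
  m <- matrix(NA_integer_, n, K)
  for (p in seq_len(K)) {
    valid <- lens >= p + k - 1L
    if (!any(valid)) break
    kms <- substr(seq[valid], p, p + k - 1L)
    m[valid, p] <- index$gene_id[match(kms, index$kmer)]
  }
  m
}

#' Assign reads to genes by k-mer voting
#'
#' Emulates intersection-nonempty annotation semantics on the k-mer level:
#' k-mers absent from the index contribute nothing; if the intersection of
#' the nonempty per-k-mer gene sets is a single gene the read is assigned
#' to it; reads with no informative k-mer are `unassigned`; conflicting or
#' multi-gene evidence yields `ambiguous`. Both `unassigned` and
#' `ambiguous` reads are discarded downstream.
#'
#' @param seq Character vector of reads, each at least `k` long.
#' @param index A [gene_index()].
#' @return Character vector: a gene name, `"unassigned"`, or `"ambiguous"`
#'   per read.
#' @export
assign_gene <- function(seq, index) {
  stopifnot(inherits(index, "gene_index"))
  if (any(nchar(seq) < index$k))
    stop("read shorter than k", call. = FALSE)
  m <- .kmer_gene_matrix(seq, index)
  if (length(index$multi) == 0) {
    # every informative k-mer names exactly one gene
    cols <- as.data.frame(m)
    lo <- do.call(pmin, c(cols, na.rm = TRUE))
    hi <- do.call(pmax, c(cols, na.rm = TRUE))
    out <- rep("unassigned", length(seq))
    has <- !is.na(lo)
    out[has & lo == hi] <- index$genes[lo[has & lo == hi]]
    out[has & lo != hi] <- "ambiguous"
    out
  } else {
    multi_kmers <- attr(index$multi, "kmer")
    vapply(seq_along(seq), function(i) {
      ids <- m[i, !is.na(m[i, ])]
      if (length(ids) == 0) return("unassigned")
      sets <- lapply(seq_along(ids), function(j) {
        if (ids[j] > 0) return(ids[j])
        kms <- seq_kmers(seq[i], index$k)
        index$multi[[match(kms[which(!is.na(m[i, ]))[j]], multi_kmers)]]
      })
      inter <- Reduce(intersect, sets)
      if (length(inter) == 1) index$genes[inter] else "ambiguous"
    }, character(1))
  }
}

#' Demultiplex forward reads against a barcode reference
#'
#' Looks up the first 18 bases of each forward read by exact match in the
#' barcode reference; on a hit the following 9 bases are the UMI, on a miss
#' the read pair is discarded as a barcode mismatch (no error correction).
#'
#' @param fwd_seq Character vector of forward reads (>= 27 nt).
#' @param reference A barcode reference data.frame from
#'   [read_barcode_reference()] (columns `barcode`, `feature_id`).
#' @return data.frame with `feature_id` (NA on mismatch) and `umi`.
#' @export
demultiplex <- function(fwd_seq, reference) {
  if (!all(c("barcode", "feature_id") %in% names(reference)))
    stop("malformed reference: need barcode and feature_id columns",
         call. = FALSE)
  if (anyDuplicated(reference$barcode))
    stop("malformed reference: duplicate barcodes", call. = FALSE)
  if (any(nchar(fwd_seq) < 27))
    stop("forward reads must be at least 27 nt", call. = FALSE)
  bc <- substr(fwd_seq, 1L, 18L)
  hit <- match(bc, reference$barcode)
  data.frame(feature_id = reference$feature_id[hit],
             umi = substr(fwd_seq, 19L, 27L),
             stringsAsFactors = FALSE)
}

#' Collapse PCR duplicates by UMI
#'
#' Counts, for every (feature, gene) pair, the number of distinct UMI
#' strings among the kept reads: exact-string collapse, no mismatch
#' tolerance.
#'
#' @param reads data.frame/data.table with columns `feature_id`, `gene`,
#'   `umi` of kept reads.
#' @return data.table with `feature_id`, `gene`, `count` (unique
#'   molecules).
#' @export
dedup_umis <- function(reads) {
  dt <- data.table::as.data.table(reads)[, c("feature_id", "gene", "umi")]
  uniq <- unique(dt)
  uniq[, list(count = .N), by = c("feature_id", "gene")]
}
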