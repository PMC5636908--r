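#' Run the full read-processing pipeline
#'
#' Applies the read-level chain in order: homopolymer truncation of the
#' transcript read, BWA-rule quality trimming, minimum-length filter,
#' k-mer contaminant filter, k-mer gene assignment, exact spatial-barcode
#' demultiplexing of the paired forward read, and UMI duplicate collapse,
#' producing a feature-by-gene molecule count matrix over all reference
#' features and all index genes. Every input pair is accounted for exactly
#' once: `input = kept + sum(discarded per stage)`.
#'
#' @param reads A `read_pair_set`, or `NULL` if `fq1`/`fq2` are given.
#' @param reference Barcode reference data.frame
#'   ([read_barcode_reference()]) or path to the reference TSV.
#' @param gene_idx A [gene_index()].
#' @param contam_idx A [contaminant_index()], or `NULL` to skip the
#'   contaminant stage.
#' @param fq1,fq2 FASTQ paths, used when `reads` is `NULL`.
#' @param min_run Homopolymer run threshold (default 15).
#' @param trim_q Quality-trim threshold (default 20).
#' @param min_len Minimum read length after trimming (default 28).
#' @param layout Optional `array_layout`; adds grid coordinates to the
#'   feature metadata of the output matrix.
#' @param keep_fates If `TRUE`, also return the per-read fate table.
#' @return List with `counts` (an [st_counts()] matrix), `stats` (a
#'   `pipeline_stats` list) and, if requested, `fates` (data.table:
#'   read_id, status, gene, feature_id, umi).
#' @export
run_pipeline <- function(reads = NULL, reference, gene_idx,
                         contam_idx = NULL, fq1 = NULL, fq2 = NULL,
                         min_run = 15, trim_q = 20, min_len = 28,
                         layout = NULL, keep_fates = FALSE) {
  if (is.null(reads)) {
    if (is.null(fq1) || is.null(fq2))
      stop("either reads or fq1/fq2 must be given", call. = FALSE)
    reads <- read_fastq_pair(fq1, fq2)
  }
  if (is.character(reference)) reference <- read_barcode_reference(reference)
  stopifnot(inherits(gene_idx, "gene_index"))
  n <- length(reads$id)
  status <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  feature_id <- rep(NA_integer_, n)
  umi <- rep(NA_character_, n)

  # stage 1+2: artifact truncation, then 3'-quality trimming
  seq1 <- trim_homopolymer(reads$rev_seq, min_run)
  qual1 <- substr(reads$rev_qual, 1L, nchar(seq1))
  qt <- quality_trim(seq1, qual1, trim_q)

  # stage 3: length filter
  short <- !length_filter(qt$seq, min_len)
  status[short] <- "short"
  alive <- which(!short)

  # stage 4: contaminant filter
  if (!is.null(contam_idx) && length(alive) > 0) {
    keep <- contaminant_filter(qt$seq[alive], contam_idx)
    status[alive[!keep]] <- "contaminant"
    alive <- alive[keep]
  }

  # stage 5: gene assignment (intersection-nonempty stand-in)
  if (length(alive) > 0) {
    g <- assign_gene(qt$seq[alive], gene_idx)
    status[alive[g == "unassigned"]] <- "unassigned"
    status[alive[g == "ambiguous"]] <- "ambiguous"
    ok <- !(g %in% c("unassigned", "ambiguous"))
    gene[alive[ok]] <- g[ok]
    alive <- alive[ok]
  }

  # stage 6: spatial demultiplexing, exact barcode match
  if (length(alive) > 0) {
    dm <- demultiplex(reads$fwd_seq[alive], reference)
    miss <- is.na(dm$feature_id)
    status[alive[miss]] <- "barcode_mismatch"
    feature_id[alive[!miss]] <- dm$feature_id[!miss]
    umi[alive[!miss]] <- dm$umi[!miss]
    alive <- alive[!miss]
  }
  status[alive] <- "kept"

  # stage 7: UMI duplicate collapse
  kept <- data.table::data.table(feature_id = feature_id[status == "kept"],
                                 gene = gene[status == "kept"],
                                 umi = umi[status == "kept"])
  mol <- dedup_umis(kept)

  counts <- matrix(0L, nrow = nrow(reference), ncol = length(gene_idx$genes),
                   dimnames = list(as.character(reference$feature_id),
                                   gene_idx$genes))
  if (nrow(mol) > 0)
    counts[cbind(match(mol$feature_id, reference$feature_id),
                 match(mol$gene, gene_idx$genes))] <- mol$count

  stage_levels <- c("short", "contaminant", "unassigned", "ambiguous",
                    "barcode_mismatch")
  discarded <- vapply(stage_levels, function(s) sum(status == s), integer(1))
  stats <- structure(list(
    input_pairs = n,
    discarded = discarded,
    kept_pairs = sum(status == "kept"),
    unique_molecules = sum(mol$count)
  ), class = "pipeline_stats")
  stopifnot(stats$input_pairs == stats$kept_pairs + sum(stats$discarded))

  out <- list(
    counts = st_counts(counts, features = .features_meta(reference, layout)),
    stats = stats)
  if (keep_fates)
    out$fates <- data.table::data.table(
      read_id = reads$id, status = status, gene = gene,
      feature_id = feature_id, umi = umi)
  out
}

.features_meta <- function(reference, layout = NULL) {
  f <- data.frame(feature_id = reference$feature_id,
                  barcode = reference$barcode,
                  x = reference$x, y = reference$y,
                  stringsAsFactors = FALSE)
  if (!is.null(layout)) {
    i <- match(f$barcode, layout$features$barcode)
    f$grid_col <- layout$features$grid_col[i]
    f$grid_row <- layout$features$grid_row[i]
  }
  f
}

#' @export
print.pipeline_stats <- function(x, ...) {
  cat(sprintf("pipeline_stats: %d pairs in, %d kept, %d unique molecules\n",
              x$input_pairs, x$kept_pairs, x$unique_molecules))
  for (s in names(x$discarded))
    cat(sprintf("  discarded %-18s %d\n", paste0(s, ":"), x$discarded[[s]]))
  invisible(x)
}

#' Write pipeline stats as TSV
#'
#' @param stats A `pipeline_stats`.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_pipeline_stats <- function(stats, path) {
  df <- data.frame(
    metric = c("input_pairs", paste0("discarded_", names(stats$discarded)),
               "kept_pairs", "unique_molecules"),
    value = c(stats$input_pairs, unname(stats$discarded),
              stats$kept_pairs, stats$unique_molecules))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
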