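#' Sequencing saturation (complexity) curves
#'
#' Estimates library complexity by subsampling raw read pairs before any
#' processing: for each subsample size, `n_reps` uniform without-replacement
#' subsamples are drawn, each is run through the full read-processing
#' pipeline, and the mean number of unique transcripts (molecules) and
#' unique genes per feature is recorded. Means are taken over all reference
#' features (fixed denominator), which makes the expected curve
#' nondecreasing in depth.
#'
#' @param reads A `read_pair_set` (in memory), or `NULL` with `fq1`/`fq2`.
#' @param sizes Integer vector of subsample sizes (read pairs).
#' @param n_reps Replicate subsamples per size (default 1).
#' @param reference,gene_idx,contam_idx,fq1,fq2,... Passed to
#'   [run_pipeline()].
#' @param seed Integer seed for the subsampling.
#' @return List with `replicates` (data.frame: size, rep,
#'   mean_transcripts, mean_genes) and `summary` (per-size means over
#'   replicates).
#' @export
saturation_curve <- function(reads = NULL, sizes, n_reps = 1,
                             reference, gene_idx, contam_idx = NULL,
                             fq1 = NULL, fq2 = NULL, seed = 1, ...) {
  if (is.null(reads)) reads <- read_fastq_pair(fq1, fq2)
  if (is.character(reference)) reference <- read_barcode_reference(reference)
  total <- length(reads$id)
  if (any(sizes > total))
    stop(sprintf("subsample size exceeds the %d available pairs", total),
         call. = FALSE)
  rows <- list()
  withr::with_seed(seed, {
    for (s in sort(sizes)) {
      for (r in seq_len(n_reps)) {
        if (s == 0) {
          rows[[length(rows) + 1]] <-
            data.frame(size = 0L, rep = r, mean_transcripts = 0,
                       mean_genes = 0)
          next
        }
        sub <- subset_reads(reads, sample.int(total, s))
        res <- run_pipeline(sub, reference, gene_idx, contam_idx, ...)
        cts <- res$counts$counts
        rows[[length(rows) + 1]] <- data.frame(
          size = s, rep = r,
          mean_transcripts = mean(rowSums(cts)),
          mean_genes = mean(rowSums(cts > 0)))
      }
    }
  })
  reps <- do.call(rbind, rows)
  summ <- stats::aggregate(
    cbind(mean_transcripts, mean_genes) ~ size, data = reps, FUN = mean)
  list(replicates = reps, summary = summ[order(summ$size), ])
}
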