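FORWARD_LEN <- 31L   # 18 nt barcode + 9 nt UMI + 4 nt capture read-through
REVERSE_LEN <- 121L  # transcript read

#' Simulate paired-end reads from a ground-truth molecule ledger
#'
#' Turns every molecule of the ledger into 1 + Geometric(duplication rate)
#' read pairs. The 31-nt forward read carries the feature's 18-nt spatial
#' barcode, the molecule's 9-nt UMI and a 4-nt poly-T tail (read-through
#' into the capture region); the 121-nt reverse read is a uniformly placed
#' window of the gene's transcript. Per-read artifacts are drawn mutually
#' exclusively at the model's rates: a contaminant reverse sequence (rRNA
#' stand-in), one substitution in the spatial barcode, or an appended
#' poly-A run of at least 15 nt. Reverse-read qualities follow a linear
#' 3'-degradation profile; forward reads are uniformly high quality.
#'
#' @param truth A [simulate_expression()] `ground_truth`.
#' @param layout The `array_layout` whose barcodes the forward reads carry.
#' @param transcriptome Named character vector of transcript sequences
#'   covering every ledger gene (see [synthetic_transcriptome()]).
#' @param contaminants Named character vector of contaminant sequences;
#'   required when the model's contamination rate is positive.
#' @param seed Integer seed.
#' @param qual_max,qual_min,qual_plateau Reverse-read quality profile:
#'   Phred `qual_max` up to cycle `qual_plateau`, then linear decay to
#'   `qual_min` at the last cycle.
#' @return Object of class `read_pair_set`: list with character vectors
#'   `id`, `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual` and a data.table
#'   `truth` tagging each read with its generating `molecule_id`,
#'   `feature_id`, `gene`, `umi` and artifact `class`
#'   (`clean`/`contaminant`/`barcode_error`/`homopolymer`).
#' @export
simulate_reads <- function(truth, layout, transcriptome,
                           contaminants = NULL, seed = 1,
                           qual_max = 37, qual_min = 25, qual_plateau = 60) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(layout, "array_layout"))
  model <- truth$model
  ledger <- truth$ledger
  missing <- setdiff(unique(ledger$gene), names(transcriptome))
  if (length(missing) > 0)
    stop("missing transcript(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (model$contamination > 0 && is.null(contaminants))
    stop("contaminant sequences required at positive contamination rate",
         call. = FALSE)
  barcode_of <- stats::setNames(layout$features$barcode,
                                layout$features$feature_id)

  withr::with_seed(seed, {
    n_mol <- nrow(ledger)
    copies <- if (model$duplication_rate > 0)
      1L + stats::rgeom(n_mol, prob = 1 - model$duplication_rate)
    else rep(1L, n_mol)
    mol <- rep(seq_len(n_mol), copies)
    n_reads <- length(mol)
    feature_id <- ledger$feature_id[mol]
    gene <- ledger$gene[mol]
    umi <- ledger$umi[mol]

    # forward read: barcode + UMI + capture-region read-through
    fwd <- paste0(barcode_of[as.character(feature_id)], umi,
                  strrep("T", FORWARD_LEN - 27L))

    # reverse read: uniform transcript window
    tlen <- nchar(transcriptome)[match(gene, names(transcriptome))]
    wlen <- pmin(REVERSE_LEN, tlen)
    start <- floor(stats::runif(n_reads) * (tlen - wlen + 1)) + 1L
    rev <- substr(transcriptome[match(gene, names(transcriptome))],
                  start, start + wlen - 1L)

    # mutually exclusive per-read artifact classes
    u <- stats::runif(n_reads)
    p1 <- model$contamination
    p2 <- p1 + model$barcode_error_rate
    p3 <- p2 + model$homopolymer_rate
    class <- rep("clean", n_reads)
    class[u < p3] <- "homopolymer"
    class[u < p2] <- "barcode_error"
    class[u < p1] <- "contaminant"

    is_cont <- class == "contaminant"
    if (any(is_cont)) {
      ci <- sample.int(length(contaminants), sum(is_cont), replace = TRUE)
      clen <- nchar(contaminants)[ci]
      cw <- pmin(REVERSE_LEN, clen)
      cs <- floor(stats::runif(sum(is_cont)) * (clen - cw + 1)) + 1L
      rev[is_cont] <- substr(contaminants[ci], cs, cs + cw - 1L)
    }

    is_err <- class == "barcode_error"
    if (any(is_err)) {
      pos <- sample.int(18L, sum(is_err), replace = TRUE)
      tmp <- fwd[is_err]
      old <- substr(tmp, pos, pos)
      shift <- sample.int(3L, sum(is_err), replace = TRUE)
      bases <- c("A", "C", "G", "T")
      new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
      substr(tmp, pos, pos) <- new
      fwd[is_err] <- tmp
    }

    is_hp <- class == "homopolymer"
    if (any(is_hp)) {
      run <- pmin(15L + stats::rgeom(sum(is_hp), prob = 0.3),
                  nchar(rev[is_hp]))
      keep <- nchar(rev[is_hp]) - run
      rev[is_hp] <- paste0(substr(rev[is_hp], 1L, keep), strrep("A", run))
    }

    # qualities: flat high forward; linear 3' decay on the reverse read
    fq <- strrep(rawToChar(as.raw(qual_max + 33L)), FORWARD_LEN)
    fwd_qual <- rep(fq, n_reads)
    cyc <- seq_len(REVERSE_LEN)
    decay <- pmax(0, (cyc - qual_plateau) / (REVERSE_LEN - qual_plateau))
    q <- round(qual_max - (qual_max - qual_min) * decay)
    rq_full <- intToUtf8(q + 33L)
    rev_qual <- substr(rep(rq_full, n_reads), 1L, nchar(rev))
  })

  structure(list(
    id = sprintf("read_%07d", seq_along(mol)),
    fwd_seq = unname(fwd), fwd_qual = unname(fwd_qual),
    rev_seq = unname(rev), rev_qual = unname(rev_qual),
    truth = data.table::data.table(
      read_id = sprintf("read_%07d", seq_along(mol)),
      molecule_id = ledger$molecule_id[mol],
      feature_id = feature_id, gene = gene, umi = umi, class = class)
  ), class = "read_pair_set")
}

#' @export
print.read_pair_set <- function(x, ...) {
  cat(sprintf("read_pair_set: %d read pairs (%d clean)\n",
              length(x$id), sum(x$truth$class == "clean")))
  invisible(x)
}

#' Write a read pair set as two FASTQ files
#'
#' @param reads A `read_pair_set`.
#' @param prefix Output prefix; writes `<prefix>_R1.fastq` (forward) and
#'   `<prefix>_R2.fastq` (reverse), Phred+33.
#' @return The two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_pair_set"))
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  write_one <- function(seqs, quals, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- reads$id
    qq <- Biostrings::PhredQuality(quals)
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(ss, qq), path)
  }
  write_one(reads$fwd_seq, reads$fwd_qual, p1)
  write_one(reads$rev_seq, reads$rev_qual, p2)
  invisible(c(fq1 = p1, fq2 = p2))
}

#' Read a FASTQ pair into a read pair set
#'
#' Reverse reads longer than 121 nt are truncated on input.
#'
#' @param fq1,fq2 Paths to the forward and reverse FASTQ files (Phred+33).
#' @return A `read_pair_set` (without truth tags).
#' @export
read_fastq_pair <- function(fq1, fq2) {
  # Biostrings warns when dropping the (empty) metadata columns on read
  f <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fq1))
  r <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fq2))
  if (length(f) != length(r))
    stop("FASTQ files have different read counts", call. = FALSE)
  rev_seq <- as.character(r)
  rev_qual <- as.character(Biostrings::quality(r))
  over <- nchar(rev_seq) > REVERSE_LEN
  rev_seq[over] <- substr(rev_seq[over], 1L, REVERSE_LEN)
  rev_qual[over] <- substr(rev_qual[over], 1L, REVERSE_LEN)
  structure(list(
    id = sub(" .*", "", names(f)),
    fwd_seq = unname(as.character(f)),
    fwd_qual = unname(as.character(Biostrings::quality(f))),
    rev_seq = unname(rev_seq), rev_qual = unname(rev_qual),
    truth = NULL
  ), class = "read_pair_set")
}

#' Subset a read pair set
#'
#' @param reads A `read_pair_set`.
#' @param idx Integer indices of the read pairs to keep.
#' @return A `read_pair_set` restricted to `idx` (truth tags subset too).
#' @export
subset_reads <- function(reads, idx) {
  structure(list(
    id = reads$id[idx],
    fwd_seq = reads$fwd_seq[idx], fwd_qual = reads$fwd_qual[idx],
    rev_seq = reads$rev_seq[idx], rev_qual = reads$rev_qual[idx],
    truth = if (!is.null(reads$truth)) reads$truth[idx]
  ), class = "read_pair_set")
}
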