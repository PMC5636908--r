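# Shared small fixtures, built once per test run, and independent
# brute-force oracles used to validate the vectorized implementations.

.fix <- new.env(parent = emptyenv())

small_layout <- function() {
  if (is.null(.fix$layout))
    .fix$layout <- generate_layout(spot_geometry(width = 2200, height = 2200),
                                   n_features = 100, n_frame = 40, seed = 3)
  .fix$layout
}

noise_free_model <- function(n_genes = 80, depth_scale = 0.5) {
  expression_model(n_genes = n_genes, depth_scale = depth_scale,
                   duplication_rate = 0, contamination = 0,
                   barcode_error_rate = 0, homopolymer_rate = 0)
}

small_transcriptome <- function() {
  if (is.null(.fix$tx)) {
    genes <- expression_model(n_genes = 80)$genes$gene
    .fix$tx <- synthetic_transcriptome(genes, min_len = 300, max_len = 600,
                                       seed = 11)
  }
  .fix$tx
}

small_contaminants <- function() {
  if (is.null(.fix$contam))
    .fix$contam <- synthetic_contaminants(
      n = 3, len = 800, seed = 12,
      avoid_kmers = unlist(lapply(small_transcriptome(),
                                  stheart:::seq_kmers, k = 21),
                           use.names = FALSE))
  .fix$contam
}

random_dna_vec <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
           collapse = ""), character(1))
}

# --- oracles ---------------------------------------------------------------

# character-by-character scan for the first run of >= min_run equal bases
oracle_trim_homopolymer <- function(seq, min_run = 15) {
  ch <- strsplit(seq, "")[[1]]
  run <- 1L
  for (i in seq_along(ch)) {
    if (i > 1 && ch[i] == ch[i - 1]) run <- run + 1L else run <- 1L
    if (run >= min_run) return(substr(seq, 1L, i - run))
  }
  seq
}

# brute-force maximization over all 3' cut points of sum(Q - q[p..L]);
# ties resolve to the largest p (shortest trim)
oracle_quality_trim <- function(seq, qual, Q = 20) {
  L <- nchar(seq)
  if (L == 0) return(list(seq = seq, qual = qual))
  q <- utf8ToInt(qual) - 33L
  s <- vapply(seq_len(L), function(p) sum(Q - q[p:L]), numeric(1))
  best <- max(s)
  if (best <= 0) return(list(seq = seq, qual = qual))
  p <- max(which(s == best))
  list(seq = substr(seq, 1L, p - 1L), qual = substr(qual, 1L, p - 1L))
}

# dictionary lookup demultiplexer
oracle_demux <- function(fwd, reference) {
  dict <- stats::setNames(reference$feature_id, reference$barcode)
  data.frame(feature_id = unname(dict[substr(fwd, 1, 18)]),
             umi = substr(fwd, 19, 27), stringsAsFactors = FALSE)
}

# hash-set tally of distinct (feature, gene, umi) triples
oracle_dedup <- function(reads) {
  key <- unique(paste(reads$feature_id, reads$gene, reads$umi, sep = "\r"))
  parts <- strsplit(key, "\r", fixed = TRUE)
  df <- data.frame(feature_id = as.integer(sapply(parts, `[`, 1)),
                   gene = sapply(parts, `[`, 2))
  agg <- stats::aggregate(rep(1L, nrow(df)),
                          by = list(feature_id = df$feature_id,
                                    gene = df$gene), FUN = sum)
  names(agg)[3] <- "count"
  agg[order(agg$feature_id, agg$gene), ]
}

random_phred <- function(len, lo = 2, hi = 40) {
  intToUtf8(sample(lo:hi, len, replace = TRUE) + 33L)
}
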