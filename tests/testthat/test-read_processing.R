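test_that("homopolymer truncation follows the >= 15-base run rule", {
  expect_equal(trim_homopolymer(paste0("ACGT", strrep("A", 15), "CGT")),
               "ACGT")
  expect_equal(trim_homopolymer(paste0("ACGT", strrep("A", 14))),
               paste0("ACGT", strrep("A", 14)))
  expect_equal(trim_homopolymer(""), "")
  # planted 16-runs at every position of a 20-nt read: truncation point
  # equals the plant position (exhaustive scan oracle)
  set.seed(1)
  for (pos in 1:5) {
    pre <- paste0(sample(c("A", "C", "G"), pos - 1, replace = TRUE),
                  collapse = "")
    s <- paste0(pre, strrep("T", 16), strrep("G", 4))
    expect_equal(trim_homopolymer(s), pre)
    expect_equal(trim_homopolymer(s), oracle_trim_homopolymer(s))
  }
})

test_that("homopolymer truncation matches the scan oracle on random reads", {
  set.seed(42)
  n <- 3000
  reads <- random_dna_vec(n, 60)
  # plant runs in a third of them
  plant <- seq_len(n) %% 3 == 0
  pos <- sample(1:40, sum(plant), replace = TRUE)
  reads[plant] <- paste0(substr(reads[plant], 1, pos),
                         strrep("A", 16),
                         substr(reads[plant], pos + 1, 44))
  got <- trim_homopolymer(reads)
  want <- vapply(reads, oracle_trim_homopolymer, character(1),
                 USE.NAMES = FALSE)
  expect_identical(got, want)
  # idempotence
  expect_identical(trim_homopolymer(got), got)
})

test_that("quality trimming reproduces the published BWA rule", {
  qual <- intToUtf8(c(40, 40, 2, 2, 2) + 33)
  got <- quality_trim("ACGTA", qual, Q = 20)
  expect_equal(got$seq, "AC")
  # all-high qualities: unchanged
  hi <- quality_trim("ACGTA", "IIIII", Q = 20)
  expect_equal(hi$seq, "ACGTA")
  # uniformly bad: full trim
  lo <- quality_trim("ACGTA", intToUtf8(rep(2 + 33, 5)), Q = 20)
  expect_equal(lo$seq, "")
  expect_error(quality_trim("ACG", "II"), "mismatch")
})

test_that("quality trimming matches the brute-force argmax oracle", {
  set.seed(7)
  n <- 4000
  lens <- sample(1:50, n, replace = TRUE)
  seqs <- vapply(lens, function(L) random_dna_vec(1, L), character(1))
  quals <- vapply(lens, random_phred, character(1))
  got <- quality_trim(seqs, quals, Q = 20)
  want <- mapply(function(s, q) oracle_quality_trim(s, q, Q = 20)$seq,
                 seqs, quals, USE.NAMES = FALSE)
  expect_identical(got$seq, want)
  expect_identical(nchar(got$qual), nchar(got$seq))
  # idempotence: trimming the trimmed read changes nothing
  again <- quality_trim(got$seq, got$qual, Q = 20)
  expect_identical(again$seq, got$seq)
})

test_that("length filter keeps exactly the reads of >= 28 bases", {
  expect_true(length_filter(strrep("A", 28)))
  expect_false(length_filter(strrep("A", 27)))
  expect_false(length_filter(""))
})

test_that("contaminant filter decision flips at the k-mer hit fraction theta", {
  tx <- small_transcriptome()
  contam <- small_contaminants()
  idx <- contaminant_index(contam, k = 21, theta = 0.5)
  # read copied from a contaminant: all k-mers hit
  expect_false(contaminant_filter(substr(contam[[1]], 10, 100), idx))
  # read from the transcriptome: zero hits
  expect_true(contaminant_filter(substr(tx[[1]], 10, 100), idx))
  # chimeric reads with controlled contaminant k-mer fraction: the
  # decision flips where direct k-mer counting says it must
  k <- 21
  for (clen in c(30, 60, 90)) {
    read <- paste0(substr(tx[[2]], 1, 120 - clen),
                   substr(contam[[2]], 1, clen))
    kms <- stheart:::seq_kmers(read, k)
    frac <- mean(kms %in% idx$kmers)
    expect_equal(contaminant_filter(read, idx), frac < 0.5)
  }
  expect_error(contaminant_filter("ACGT", idx), "shorter than k")
})

test_that("gene assignment follows intersection-nonempty semantics", {
  tx <- small_transcriptome()
  gi <- gene_index(tx, k = 21)
  g1 <- names(tx)[1]; g2 <- names(tx)[2]
  # read inside one transcript
  expect_equal(assign_gene(substr(tx[[g1]], 50, 150), gi), g1)
  # foreign sequence: unassigned
  expect_equal(assign_gene(substr(small_contaminants()[[1]], 1, 100), gi),
               "unassigned")
  # chimera with >= k bases from each of two genes: conflicting singletons
  chim <- paste0(substr(tx[[g1]], 1, 60), substr(tx[[g2]], 1, 60))
  expect_equal(assign_gene(chim, gi), "ambiguous")
  # vectorized call agrees with scalar calls
  batch <- c(substr(tx[[g1]], 50, 150), chim,
             substr(small_contaminants()[[1]], 1, 100))
  expect_equal(assign_gene(batch, gi), c(g1, "ambiguous", "unassigned"))
})

test_that("shared k-mers between genes produce set-intersection verdicts", {
  # two genes sharing a 40-nt block: reads inside the block are ambiguous,
  # reads overlapping unique sequence resolve
  set.seed(3)
  shared <- random_dna_vec(1, 40)
  a <- paste0(random_dna_vec(1, 80), shared)
  b <- paste0(shared, random_dna_vec(1, 80))
  gi <- gene_index(c(GA = a, GB = b), k = 21)
  expect_gt(length(gi$multi), 0)
  expect_equal(assign_gene(substr(a, 81, 120), gi), "ambiguous")
  expect_equal(assign_gene(substr(a, 1, 60), gi), "GA")
  expect_equal(assign_gene(substr(b, 30, 90), gi), "GB")
})

test_that("demultiplexing recovers all features bijectively and rejects mismatches", {
  layout <- small_layout()
  tf <- tempfile(); write_barcode_reference(layout, tf)
  ref <- read_barcode_reference(tf)
  umis <- stheart:::iupac_draw("WSNNWSNNV", nrow(ref))
  fwd <- paste0(ref$barcode, umis, "TTTT")
  got <- demultiplex(fwd, ref)
  expect_equal(got$feature_id, ref$feature_id)
  expect_equal(got$umi, umis)
  # matches the dictionary-lookup oracle on shuffled input
  set.seed(2)
  shuf <- sample(fwd)
  expect_equal(demultiplex(shuf, ref), oracle_demux(shuf, ref))
  # one substitution in the barcode: mismatch
  mut <- fwd[1]
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 5, 5))[1]
  expect_true(is.na(demultiplex(mut, ref)$feature_id))
  expect_error(demultiplex("ACGT", ref), "at least 27")
})

test_that("UMI collapse counts distinct triples exactly (hash-set oracle)", {
  r <- data.frame(feature_id = rep(1L, 5), gene = "G",
                  umi = rep("ACCAACCGA", 5))
  expect_equal(dedup_umis(r)$count, 1L)
  r2 <- data.frame(feature_id = rep(1L, 5), gene = "G",
                   umi = paste0("ACCAACCG", c("A", "C", "G", "T", "A")))
  expect_equal(dedup_umis(r2)$count, 4L)
  # random multiset of triples
  set.seed(11)
  n <- 20000
  reads <- data.frame(
    feature_id = sample(1:30, n, replace = TRUE),
    gene = sample(paste0("G", 1:15), n, replace = TRUE),
    umi = stheart:::iupac_draw("WSNNWSNNV", n))
  got <- as.data.frame(dedup_umis(reads))
  got <- got[order(got$feature_id, got$gene), ]
  want <- oracle_dedup(reads)
  expect_equal(got$count, want$count)
  expect_equal(got$feature_id, want$feature_id)
  expect_equal(got$gene, want$gene)
})

test_that("noise-free pipeline inverts the simulator exactly", {
  layout <- small_layout()
  rm <- simulate_region_map(layout, seed = 3)
  truth <- simulate_expression(rm, noise_free_model(), seed = 5)
  reads <- simulate_reads(truth, layout, small_transcriptome(), seed = 6)
  tf <- tempfile(); write_barcode_reference(layout, tf)
  res <- run_pipeline(reads, read_barcode_reference(tf),
                      gene_index(small_transcriptome()), layout = layout)
  expect_identical(res$counts$counts[, colnames(truth$counts)],
                   truth$counts)
  expect_equal(res$stats$kept_pairs, length(reads$id))
})

test_that("an all-errors barcode channel empties the matrix", {
  layout <- small_layout()
  rm <- simulate_region_map(layout, seed = 3)
  model <- noise_free_model(depth_scale = 0.1)
  model$barcode_error_rate <- 1
  truth <- simulate_expression(rm, model, seed = 5)
  reads <- simulate_reads(truth, layout, small_transcriptome(), seed = 6)
  tf <- tempfile(); write_barcode_reference(layout, tf)
  res <- run_pipeline(reads, read_barcode_reference(tf),
                      gene_index(small_transcriptome()))
  expect_true(all(res$counts$counts == 0))
  expect_equal(unname(res$stats$discarded["barcode_mismatch"]),
               length(reads$id))
})

test_that("per-stage discards match the simulator's truth tags", {
  layout <- small_layout()
  rm <- simulate_region_map(layout, seed = 3)
  model <- expression_model(n_genes = 80, depth_scale = 0.3,
                            duplication_rate = 0.3, contamination = 0.08,
                            barcode_error_rate = 0.05,
                            homopolymer_rate = 0.05)
  truth <- simulate_expression(rm, model, seed = 5)
  reads <- simulate_reads(truth, layout, small_transcriptome(),
                          contaminants = small_contaminants(), seed = 6)
  tf <- tempfile(); write_barcode_reference(layout, tf)
  res <- run_pipeline(reads, read_barcode_reference(tf),
                      gene_index(small_transcriptome()),
                      contaminant_index(small_contaminants()),
                      keep_fates = TRUE)
  tags <- reads$truth$class
  fate <- res$fates$status
  # accounting identity
  expect_equal(res$stats$input_pairs,
               res$stats$kept_pairs + sum(res$stats$discarded))
  # contaminant reads are discarded at the contaminant stage
  expect_equal(unname(res$stats$discarded["contaminant"]),
               sum(tags == "contaminant"))
  expect_true(all(fate[tags == "contaminant"] == "contaminant"))
  # barcode errors never land in the matrix (min Hamming 3 > 1 error)
  expect_true(all(fate[tags == "barcode_error"] %in%
                    c("barcode_mismatch", "short")))
  # homopolymer-artifact reads are clipped, not lost (101 nt remain)
  expect_true(all(fate[tags == "homopolymer"] == "kept"))
  # clean reads are all kept
  expect_true(all(fate[tags == "clean"] == "kept"))
})
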