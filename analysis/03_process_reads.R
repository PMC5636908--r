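#!/usr/bin/env Rscript
# Run the read-processing chain on the simulated section: homopolymer and
# quality trimming, length filter, rRNA contaminant filter, k-mer gene
# assignment, exact barcode demultiplexing and UMI collapse, then compare
# the recovered count matrix against the simulator's ground truth.

library(stheart)

read_seqs <- function(path) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  setNames(x[[2]], x[[1]])
}
tx <- read_seqs("scratch/transcriptome.tsv")
contam <- read_seqs("scratch/contaminants.tsv")

res <- run_pipeline(fq1 = "scratch/section1_R1.fastq",
                    fq2 = "scratch/section1_R2.fastq",
                    reference = "results/barcode_reference.tsv",
                    gene_idx = gene_index(tx),
                    contam_idx = contaminant_index(contam))
print(res$stats)
write_pipeline_stats(res$stats, "results/03_pipeline_stats.tsv")
# the full matrix is bulky and regenerable; keep it out of results/
write_matrix(res$counts, "scratch/03_counts.tsv", "tsv")

truth <- read_truth("scratch/section1")
shared <- intersect(colnames(res$counts$counts), colnames(truth$counts))
recovered <- sum(pmin(res$counts$counts[, shared],
                      truth$counts[rownames(res$counts$counts), shared]))
cat(sprintf("recovered %d of %d true molecules (%.1f%%)\n",
            recovered, sum(truth$counts),
            100 * recovered / sum(truth$counts)))
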