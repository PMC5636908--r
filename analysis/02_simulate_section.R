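#!/usr/bin/env Rscript
# Simulate one cardiac tissue section on the designed array: a region map
# with connected cardiomyocyte / fibrous / adipose / pericardial patches,
# ground-truth molecule counts (negative binomial, 5-15 cells per feature,
# six fetal marker genes gated to ~2% of tissue features), and paired-end
# reads with PCR duplication, rRNA contamination, barcode errors and
# poly-A artifacts. FASTQ files land in scratch/ (regenerable), tables in
# results/.

library(stheart)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

layout <- generate_layout(seed = 1)
rmap <- simulate_region_map(layout, seed = 2)
cat("region composition:\n")
print(table(rmap$region))

model <- expression_model(n_genes = 200, depth_scale = 0.2)
truth <- simulate_expression(rmap, model, seed = 3)
print(truth)

tx <- synthetic_transcriptome(model$genes$gene, seed = 11)
contam <- synthetic_contaminants(
  avoid_kmers = unlist(lapply(tx, stheart:::seq_kmers, k = 21),
                       use.names = FALSE))
reads <- simulate_reads(truth, layout, tx, contaminants = contam, seed = 4)
print(reads)

write_truth(truth, "scratch/section1")
write_fastq_pair(reads, "scratch/section1")
writeLines(paste(names(tx), tx, sep = "\t"), "scratch/transcriptome.tsv")
writeLines(paste(names(contam), contam, sep = "\t"),
           "scratch/contaminants.tsv")
write.table(as.data.frame(rmap), "results/02_region_map.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(class = names(table(reads$truth$class)),
                       reads = as.integer(table(reads$truth$class))),
            "results/02_read_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("simulated %d molecules -> %d read pairs\n",
            nrow(truth$ledger), length(reads$id)))
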