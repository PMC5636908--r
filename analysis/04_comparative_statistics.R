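#!/usr/bin/env Rscript
# Comparative statistics over simulated sections: pairwise Pearson
# correlation of consecutive-section replicates vs cross-region pairs,
# PCA on the 1,000 most expressed genes, top-variance gene selection,
# thresholded differential expression between regions, and a sequencing
# saturation curve by read subsampling.

library(stheart)

dir.create("results", showWarnings = FALSE)

layout <- generate_layout(seed = 1)
rmap_a <- simulate_region_map(layout, seed = 2)
# a second "biopsy" with different composition (fibrous-dominated, RAA-like)
rmap_b <- simulate_region_map(layout,
                              weights = c(cardiomyocyte = 0.15,
                                          fibrous = 0.45, adipose = 0.25,
                                          pericardial = 0.05), seed = 12)
model <- expression_model(n_genes = 200, depth_scale = 0.2,
                          duplication_rate = 0, contamination = 0,
                          barcode_error_rate = 0, homopolymer_rate = 0)

section <- function(rmap, seed)
  st_counts(simulate_expression(rmap, model, seed = seed)$counts,
            layout$features, tissue = rmap$feature_id[rmap$tissue])

a1 <- section(rmap_a, 31); a2 <- section(rmap_a, 32)  # consecutive sections
b1 <- section(rmap_b, 33); b2 <- section(rmap_b, 34)

cors <- data.frame(
  pair = c("A1-A2 (replicates)", "B1-B2 (replicates)",
           "A1-B1 (cross-region)", "A2-B2 (cross-region)"),
  pearson_r = c(pairwise_correlation(a1, a2), pairwise_correlation(b1, b2),
                pairwise_correlation(a1, b1), pairwise_correlation(a2, b2)))
print(cors)
write.table(cors, "results/04_pairwise_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# PCA across the four aggregated samples
tab <- rbind(A1 = aggregate_sample(a1), A2 = aggregate_sample(a2),
             B1 = aggregate_sample(b1), B2 = aggregate_sample(b2))
p <- pca_top_expressed(tab, n_top = 200)
cat(sprintf("PC1 carries %.0f%% of variance, PC2 %.0f%%\n",
            100 * p$var_frac[1], 100 * p$var_frac[2]))
write.table(data.frame(sample = rownames(p$scores),
                       round(p$scores[, 1:3], 3)),
            "results/04_pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# feature-level top-variance selection; with a 200-gene panel the
# >= 500-expressed-genes heatmap filter is scaled to 100, a deeper library
# is simulated, and the positive-counts size-factor variant handles the
# zero-rich feature-level table
deep <- st_counts(
  simulate_expression(rmap_a, expression_model(
    n_genes = 200, depth_scale = 2, duplication_rate = 0,
    contamination = 0, barcode_error_rate = 0, homopolymer_rate = 0),
    seed = 35)$counts,
  layout$features, tissue = rmap_a$feature_id[rmap_a$tissue])
af <- filter_features_by_genes(select_under_tissue(deep), 100)
norm <- normalize_log(af$counts,
                      size_factors(af$counts, type = "poscounts"))
topvar <- top_variance_genes(norm, n_top = 50)
writeLines(topvar, "results/04_top_variance_genes.txt")

# DE between cardiomyocyte and fibrous territory of section A1
groups <- split(rmap_a$feature_id, rmap_a$region)
de <- differential_expression(a1, groups$cardiomyocyte, groups$fibrous)
de <- de[order(de$padj), ]
cat(sprintf("%d genes DE between cardiomyocyte and fibrous regions\n",
            sum(de$de_flag)))
write.table(de, "results/04_de_cardiomyocyte_vs_fibrous.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# saturation curve on a duplicated library
model_dup <- expression_model(n_genes = 200, depth_scale = 0.2,
                              duplication_rate = 0.5, contamination = 0,
                              barcode_error_rate = 0, homopolymer_rate = 0)
truth <- simulate_expression(rmap_a, model_dup, seed = 41)
tx <- synthetic_transcriptome(model_dup$genes$gene, seed = 11)
reads <- simulate_reads(truth, layout, tx, seed = 42)
ref <- data.frame(barcode = layout$features$barcode,
                  x = layout$features$x, y = layout$features$y,
                  feature_id = layout$features$feature_id)
sizes <- floor(length(reads$id) * c(0.1, 0.5, 1))
sc <- saturation_curve(reads, sizes = sizes, n_reps = 2, reference = ref,
                       gene_idx = gene_index(tx), seed = 43)
print(sc$summary)
write.table(sc$summary, "results/04_saturation_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
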