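#!/usr/bin/env Rscript
# Design the spatially barcoded microarray: 1,007 capture features (100 um
# spots, 200 um pitch) inside a 6,200 x 6,600 um area, ringed by 148 frame
# spots, each feature carrying a unique 18-nt barcode (pairwise Hamming
# distance >= 3). Writes the barcode reference the demultiplexer consumes
# and a layout summary.

library(stheart)

dir.create("results", showWarnings = FALSE)

layout <- generate_layout(spot_geometry(), n_features = 1007,
                          n_frame = 148, seed = 1)
print(layout)

write_barcode_reference(layout, "results/barcode_reference.tsv")

d <- stats::dist(layout$features[, c("x", "y")])
summary <- data.frame(
  n_features = nrow(layout$features),
  n_frame = nrow(layout$frame_spots),
  min_center_distance_um = min(d),
  barcode_length = unique(nchar(layout$features$barcode)))
write.table(summary, "results/01_array_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("array: %d features, %d frame spots, min spacing %g um\n",
            summary$n_features, summary$n_frame,
            summary$min_center_distance_um))
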