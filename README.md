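# stheart

Spatially resolved transcriptomics (ST) of adult human heart tissue, as a
tested, reusable, desk-scale R workflow.

## The scientific problem

Heart-failure research is interested in *fetal marker genes* (NKX2-5,
GATA4, TBX20, TBX5, HOPX, TNNI1): genes characteristic of fetal myocardium
that may be reactivated at low level in the failing adult heart and could
serve as biomarkers. Bulk RNA-seq of a homogenized biopsy averages each
gene over every cell in the sample, so a gene expressed weakly by a small
subpopulation of cells is diluted toward the technical noise floor and
lost. Spatial transcriptomics instead captures mRNA on a barcoded
microarray under the intact tissue section — one small transcriptome per
printed 100 µm feature (~5–15 cardiac cells) — so a sparse signal stays
concentrated in the few features that carry it.

The package implements the complete workflow around that idea:

* **Array design** — 1,007 barcoded capture features (100 µm spots, 200 µm
  center-to-center pitch, 6,200 × 6,600 µm area) ringed by 148 frame
  spots; 18-nt spatial barcodes at pairwise Hamming distance ≥ 3;
  degenerate `WSNNWSNNV` molecular identifiers (12,288 sequences).
* **A generative simulator** — connected tissue-region maps
  (cardiomyocyte / fibrous / adipose / pericardial), negative-binomial
  ground-truth molecule ledgers with gated low-level fetal genes, and
  paired-end FASTQ reads (31 nt barcode read / 121 nt transcript read)
  with PCR duplication, rRNA contamination, barcode errors and poly-A
  artifacts.
* **Read processing** — homopolymer truncation (runs ≥ 15), BWA-rule
  quality trimming, < 28 nt length filter, k-mer contaminant filter,
  intersection-nonempty k-mer gene assignment, exact-match spatial
  demultiplexing, and UMI duplicate collapse into a feature × gene
  molecule count matrix.
* **Comparative statistics** — median-of-ratios size factors (strict and
  positive-counts variants), pseudocount–log normalization, pairwise
  Pearson correlation of aggregated sections, PCA on the top-1,000
  expressed genes, top-variance gene selection, thresholded NB-Wald
  differential expression (|log2FC| > 1, BH-adjusted p < 0.01), and
  sequencing saturation curves by read subsampling.
* **The sensitivity statistic** — the headline comparison. For a gene with
  counts c_f over n features, n⁺ of them positive:

      st_signal   = log(1 + Σ c_f / n⁺)   (per expressing feature)
      bulk_signal = log(1 + Σ c_f / n)    (per all features, "bulk treated")

  with st_signal ≥ bulk_signal always, and ≫ for sparse low-level genes —
  plus a Monte-Carlo power study of both detection modes against a common
  technical-noise floor.

## Worked example

The `analysis/` directory holds the numbered workflow drivers. A condensed
session:

```r
library(stheart)

layout <- generate_layout(spot_geometry(), n_features = 1007, n_frame = 148)
rmap   <- simulate_region_map(layout, seed = 2)
model  <- expression_model(n_genes = 200, depth_scale = 0.2)
truth  <- simulate_expression(rmap, model, seed = 3)
tx     <- synthetic_transcriptome(model$genes$gene, seed = 11)
contam <- synthetic_contaminants(avoid_kmers =
            unlist(lapply(tx, stheart:::seq_kmers, k = 21), use.names = FALSE))
reads  <- simulate_reads(truth, layout, tx, contaminants = contam, seed = 4)

ref <- tempfile(); write_barcode_reference(layout, ref)
res <- run_pipeline(reads, read_barcode_reference(ref),
                    gene_index(tx), contaminant_index(contam))
print(res$stats)
#> pipeline_stats: 92510 pairs in, 86912 kept, 44798 unique molecules
#>   discarded short:             0
#>   discarded contaminant:       4674
#>   discarded unassigned:        0
#>   discarded ambiguous:         0
#>   discarded barcode_mismatch:  924
```

92,510 simulated read pairs collapse to 44,798 unique molecules (96.9 % of
the 46,210 in the ground-truth ledger; the rest were lost to contaminant
replacement and barcode errors, exactly as tagged by the simulator). The
sensitivity comparison on the tissue features of such a section
(`analysis/05_spatial_sensitivity.R`):

```
   gene st_signal bulk_signal n_expressing n_total
  TBX20 0.8754687 0.008733680            5     798
   TBX5 0.6931472 0.005000010            4     798
   HOPX 0.9162907 0.003752350            2     798
  TNNI1 0.7884574 0.007490672            5     798
  HSK_1 0.9652092 0.562832949          371     798
```

Every fetal gene — expressed in < 1 % of features — keeps a spatial signal
two orders of magnitude above its bulk-treated signal, while a
housekeeping gene expressed everywhere shows a modest gap. The power study
at the fetal configuration (fraction 0.02 of features, mean 2 molecules,
200 replicates, detection threshold = 95th percentile of the
technical-noise null) prints:

```
fetal regime (fraction 0.02, mean 2): ST power 0.95 vs bulk 0.00
```

— spatially resolved data detects the gene in 95 % of sections where the
bulk-treated view of the *same data* never clears the noise floor.

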