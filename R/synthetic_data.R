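UMI_TEMPLATE <- "WSNNWSNNV"

REGIONS <- c("cardiomyocyte", "fibrous", "adipose", "pericardial")

#' Simulate a tissue region map over an array layout
#'
#' Labels every feature of the layout with a tissue region
#' (cardiomyocyte-rich, fibrous, adipose, pericardial) or `off_tissue`,
#' emulating a cardiac biopsy section whose cell composition varies in
#' connected patches across the array. Each region is grown from a random
#' seed spot by stochastic region-growing on the feature grid
#' (4-adjacency), so every present region forms one connected blob.
#'
#' @param layout An [generate_layout()] `array_layout`.
#' @param weights Named numeric vector of target region area fractions over
#'   a subset of `c("cardiomyocyte","fibrous","adipose","pericardial")`;
#'   must sum to at most 1, the remainder is left `off_tissue`.
#' @param blob_scale Compactness exponent: candidate frontier spots are
#'   drawn with probability proportional to (number of already-assigned
#'   same-region neighbors)^`blob_scale`. Larger values give rounder blobs.
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return Object of class `region_map`: data.frame with `feature_id`,
#'   `region` (factor incl. `off_tissue`) and logical `tissue`.
#' @export
simulate_region_map <- function(layout,
                                weights = c(cardiomyocyte = 0.45,
                                            fibrous = 0.25,
                                            adipose = 0.15,
                                            pericardial = 0.05),
                                blob_scale = 1, seed = 1) {
  stopifnot(inherits(layout, "array_layout"))
  if (is.null(names(weights)) || !all(names(weights) %in% REGIONS))
    stop("weights must be named with tissue regions", call. = FALSE)
  if (any(weights < 0) || sum(weights) > 1 + 1e-9)
    stop("weights must be nonnegative and sum to <= 1", call. = FALSE)
  f <- layout$features
  n <- nrow(f)
  targets <- round(weights * n)
  targets <- targets[targets > 0]
  if (length(targets) == 0)
    stop("empty tissue: all features would be off_tissue", call. = FALSE)

  # neighbor lists under 4-adjacency on the feature grid
  key <- paste(f$grid_col, f$grid_row)
  id_of <- stats::setNames(f$feature_id, key)
  nbr <- function(i) {
    c0 <- f$grid_col[i]; r0 <- f$grid_row[i]
    cand <- paste(c(c0 - 1, c0 + 1, c0, c0), c(r0, r0, r0 - 1, r0 + 1))
    unname(id_of[cand[cand %in% key]])
  }
  neighbors <- lapply(seq_len(n), nbr)

  withr::with_seed(seed, {
    region <- rep(NA_character_, n)
    seeds <- sample.int(n, length(targets))
    region[seeds] <- names(targets)
    remaining <- targets - 1L
    active <- names(targets)
    while (length(active) > 0) {
      # regions still under quota expand in weighted random order
      rg <- if (length(active) == 1) active else
        sample(active, 1, prob = remaining[active])
      members <- which(region == rg)
      frontier <- unique(unlist(neighbors[members]))
      frontier <- frontier[is.na(region[frontier])]
      if (length(frontier) == 0 || remaining[rg] <= 0) {
        active <- setdiff(active, rg)
        next
      }
      w <- vapply(frontier, function(i)
        sum(region[neighbors[[i]]] == rg, na.rm = TRUE), numeric(1))
      pick <- if (length(frontier) == 1) frontier else
        sample(frontier, 1, prob = w^blob_scale)
      region[pick] <- rg
      remaining[rg] <- remaining[rg] - 1L
      if (remaining[rg] <= 0) active <- setdiff(active, rg)
    }
    region[is.na(region)] <- "off_tissue"
  })

  structure(
    data.frame(feature_id = f$feature_id,
               region = factor(region, levels = c(REGIONS, "off_tissue")),
               tissue = region != "off_tissue"),
    class = c("region_map", "data.frame"))
}

#' Expression model for simulated cardiac sections
#'
#' Defines the statistical structure of the simulated data: a gene panel
#' with per-cell baseline means and negative-binomial dispersions,
#' region-specific marker multipliers, a set of lowly expressed "fetal"
#' marker genes gated to a small minority of features, the cells-per-feature
#' range, and read-level artifact rates.
#'
#' Counts for gene g in tissue feature f follow
#' NB(mean = cells_f * base_g * mult(region_f, g), dispersion_g), with
#' cells_f uniform on `cells_range`. Fetal genes bypass this layer: each
#' tissue feature expresses a fetal gene with probability `fetal_fraction`,
#' and expressing features draw NB(`fetal_mean`, dispersion) molecules —
#' the sparse low-level signal whose detectability the sensitivity analysis
#' quantifies.
#'
#' @param n_genes Total panel size (default 200), split into region markers
#'   (12 per region), high-expressed housekeeping genes (20), the 6 fetal
#'   markers, and lognormal background genes.
#' @param marker_fold Multiplier of a marker gene's mean in its own region.
#' @param fetal_genes Names of the gated low-level genes.
#' @param fetal_fraction Probability that a tissue feature expresses a
#'   fetal gene.
#' @param fetal_mean Mean molecules per expressing feature for fetal genes.
#' @param cells_range Integer range of cells per 100-um feature.
#' @param dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param depth_scale Global multiplier on all baseline means; scales the
#'   simulated sequencing depth.
#' @param duplication_rate Geometric PCR duplication parameter: each
#'   molecule yields 1 + Geom(duplication_rate) read pairs.
#' @param contamination Fraction of read pairs whose transcript read is
#'   drawn from the rRNA-like contaminant set.
#' @param barcode_error_rate Fraction of read pairs with one substitution
#'   in the spatial barcode.
#' @param homopolymer_rate Fraction of read pairs with an appended poly-A
#'   artifact run on the transcript read.
#' @param seed Seed for drawing the baseline means of background genes.
#' @return Object of class `expression_model`.
#' @export
expression_model <- function(n_genes = 200,
                             marker_fold = 8,
                             fetal_genes = c("NKX2-5", "GATA4", "TBX20",
                                             "TBX5", "HOPX", "TNNI1"),
                             fetal_fraction = 0.02,
                             fetal_mean = 2,
                             cells_range = c(5L, 15L),
                             dispersion = 0.4,
                             depth_scale = 1,
                             duplication_rate = 0.5,
                             contamination = 0.05,
                             barcode_error_rate = 0.01,
                             homopolymer_rate = 0.02,
                             seed = 1) {
  n_markers_per_region <- 12L
  n_house <- 20L
  n_fetal <- length(fetal_genes)
  n_fixed <- n_markers_per_region * length(REGIONS) + n_house + n_fetal
  if (n_genes < n_fixed + 1)
    stop(sprintf("n_genes must be at least %d", n_fixed + 1), call. = FALSE)
  if (fetal_fraction < 0 || fetal_fraction > 1)
    stop("fetal_fraction must lie in [0,1]", call. = FALSE)
  for (r in c(duplication_rate, contamination, barcode_error_rate,
              homopolymer_rate))
    if (r < 0 || r > 1) stop("artifact rates must lie in [0,1]", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (cells_range[1] < 1 || cells_range[2] < cells_range[1])
    stop("invalid cells_range", call. = FALSE)

  n_bg <- n_genes - n_fixed
  genes <- data.frame(
    gene = c(paste0("MRK_", rep(REGIONS, each = n_markers_per_region), "_",
                    rep(seq_len(n_markers_per_region), length(REGIONS))),
             paste0("HSK_", seq_len(n_house)),
             fetal_genes,
             paste0("BG_", seq_len(n_bg))),
    class = c(rep("marker", n_markers_per_region * length(REGIONS)),
              rep("housekeeping", n_house),
              rep("fetal", n_fetal),
              rep("background", n_bg)),
    marker_region = c(rep(REGIONS, each = n_markers_per_region),
                      rep(NA, n_house + n_fetal + n_bg)),
    stringsAsFactors = FALSE
  )
  withr::with_seed(seed, {
    base <- numeric(nrow(genes))
    base[genes$class == "marker"] <- 0.1
    base[genes$class == "housekeeping"] <-
      stats::rlnorm(n_house, meanlog = log(0.5), sdlog = 0.5)
    base[genes$class == "fetal"] <- 0           # gated layer instead
    base[genes$class == "background"] <-
      stats::rlnorm(n_bg, meanlog = log(0.02), sdlog = 1)
  })
  genes$base_mean <- base * depth_scale

  structure(list(
    genes = genes,
    marker_fold = marker_fold,
    fetal_fraction = fetal_fraction,
    fetal_mean = fetal_mean * depth_scale,
    cells_range = as.integer(cells_range),
    dispersion = dispersion,
    duplication_rate = duplication_rate,
    contamination = contamination,
    barcode_error_rate = barcode_error_rate,
    homopolymer_rate = homopolymer_rate
  ), class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf(
    "expression_model: %d genes (%d fetal at fraction %.3g, mean %.3g); cells %d-%d\n",
    nrow(x$genes), sum(x$genes$class == "fetal"), x$fetal_fraction,
    x$fetal_mean, x$cells_range[1], x$cells_range[2]))
  invisible(x)
}

#' Simulate ground-truth molecule counts for a tissue section
#'
#' Draws, for every tissue feature and gene, the true number of captured
#' mRNA molecules under the model's negative-binomial law, and materializes
#' a molecule ledger with one record per molecule carrying a degenerate
#' WSNNWSNNV molecular identifier. Identifiers are drawn uniformly from the
#' 12,288-sequence template space without replacement within each
#' (feature, gene) pair, so distinct molecules of a gene at a feature never
#' share an identifier. Off-tissue features receive zero molecules.
#'
#' @param region_map A [simulate_region_map()] result.
#' @param model An [expression_model()].
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: list with `ledger`
#'   (data.table: molecule_id, feature_id, gene, umi), `counts`
#'   (features x genes integer matrix over all layout features),
#'   `region_map`, and `model`.
#' @export
simulate_expression <- function(region_map, model, seed = 1) {
  stopifnot(inherits(region_map, "region_map"),
            inherits(model, "expression_model"))
  genes <- model$genes
  n_feat <- nrow(region_map)
  n_gene <- nrow(genes)
  umi_card <- iupac_space(UMI_TEMPLATE)$cardinality

  withr::with_seed(seed, {
    cells <- model$cells_range[1] - 1L +
      sample.int(model$cells_range[2] - model$cells_range[1] + 1L,
                 n_feat, replace = TRUE)
    mu <- outer(cells, genes$base_mean)
    for (rg in REGIONS) {
      rows <- which(region_map$region == rg)
      cols <- which(!is.na(genes$marker_region) & genes$marker_region == rg)
      if (length(rows) && length(cols))
        mu[rows, cols] <- mu[rows, cols] * model$marker_fold
    }
    mu[!region_map$tissue, ] <- 0
    size <- 1 / model$dispersion
    counts <- matrix(0L, n_feat, n_gene,
                     dimnames = list(region_map$feature_id, genes$gene))
    pos <- mu > 0
    counts[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)

    # gated fetal layer: Bernoulli(fraction) mask per tissue feature
    fetal_cols <- which(genes$class == "fetal")
    if (length(fetal_cols) && model$fetal_fraction > 0 &&
        model$fetal_mean > 0) {
      tis <- which(region_map$tissue)
      for (j in fetal_cols) {
        on <- tis[stats::runif(length(tis)) < model$fetal_fraction]
        if (length(on))
          counts[on, j] <- stats::rnbinom(length(on), mu = model$fetal_mean,
                                          size = size)
      }
    }

    nz <- which(counts > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      ledger <- data.table::data.table(
        feature_id = rep(region_map$feature_id[nz[, 1]], counts[nz]),
        gene = rep(genes$gene[nz[, 2]], counts[nz]))
      data.table::setorder(ledger, feature_id, gene)
      # distinct UMIs within each (feature, gene): redraw collisions
      idx <- sample.int(umi_card, nrow(ledger), replace = TRUE)
      repeat {
        dup <- ledger[, .I[duplicated(idx[.I])],
                      by = c("feature_id", "gene")]$V1
        if (length(dup) == 0) break
        idx[dup] <- sample.int(umi_card, length(dup), replace = TRUE)
      }
      ledger[, umi := iupac_decode(UMI_TEMPLATE, idx)]
    } else {
      ledger <- data.table::data.table(feature_id = integer(0),
                                       gene = character(0),
                                       umi = character(0))
    }
    storage.mode(counts) <- "integer"
    ledger[, molecule_id := seq_len(.N)]
    data.table::setcolorder(ledger,
                            c("molecule_id", "feature_id", "gene", "umi"))
  })

  structure(list(ledger = ledger, counts = counts,
                 region_map = region_map, model = model),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d molecules over %d features x %d genes\n",
              nrow(x$ledger), nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

random_dna <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

has_homopolymer <- function(seq, min_run = 15) {
  grepl(sprintf("([ACGTN])\\1{%d,}", min_run - 1), seq)
}

seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

#' Generate a synthetic transcriptome
#'
#' Random gene sequences standing in for a genome + annotation: every 21-mer
#' is unique to one gene and no sequence contains a homopolymer run of 15 or
#' more bases, so k-mer gene assignment is well-posed and artifact trimming
#' never truncates genuine transcript sequence.
#'
#' @param genes Character vector of gene names.
#' @param min_len,max_len Transcript length range in nt.
#' @param k K-mer size whose cross-gene uniqueness is enforced.
#' @param seed Integer seed.
#' @param avoid_kmers Optional character vector of k-mers the transcriptome
#'   must not contain (used to keep it disjoint from the contaminant set).
#' @return Named character vector of transcript sequences.
#' @export
synthetic_transcriptome <- function(genes, min_len = 400, max_len = 1500,
                                    k = 21, seed = 1,
                                    avoid_kmers = character(0)) {
  withr::with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (km in avoid_kmers) assign(km, TRUE, envir = seen)
    out <- character(length(genes))
    for (i in seq_along(genes)) {
      len <- min_len + sample.int(max_len - min_len + 1L, 1L) - 1L
      repeat {
        s <- random_dna(len)
        if (has_homopolymer(s, 15)) next
        kms <- seq_kmers(s, k)
        if (anyDuplicated(kms) ||
            any(vapply(kms, exists, logical(1), envir = seen))) next
        for (km in kms) assign(km, TRUE, envir = seen)
        out[i] <- s
        break
      }
    }
    stats::setNames(out, genes)
  })
}

#' Generate synthetic rRNA-like contaminant sequences
#'
#' @param n Number of contaminant sequences.
#' @param len Length of each sequence in nt.
#' @param k K-mer size kept disjoint from `avoid_kmers`.
#' @param seed Integer seed.
#' @param avoid_kmers K-mers (e.g. of the transcriptome) the contaminants
#'   must not share.
#' @return Named character vector (`rRNA_1`, ...).
#' @export
synthetic_contaminants <- function(n = 4, len = 1500, k = 21, seed = 2,
                                   avoid_kmers = character(0)) {
  seqs <- synthetic_transcriptome(paste0("rRNA_", seq_len(n)),
                                  min_len = len, max_len = len, k = k,
                                  seed = seed, avoid_kmers = avoid_kmers)
  seqs
}

#' Write / read a ground truth to plain-text files
#'
#' Persists the molecule ledger and the aggregated count table as TSV files
#' (`<prefix>_ledger.tsv`, `<prefix>_counts.tsv`); the round trip through
#' [read_truth()] is lossless.
#'
#' @param truth A `ground_truth`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  ledger_path <- paste0(prefix, "_ledger.tsv")
  counts_path <- paste0(prefix, "_counts.tsv")
  data.table::fwrite(truth$ledger, ledger_path, sep = "\t")
  cts <- data.table::as.data.table(truth$counts, keep.rownames = "feature_id")
  data.table::fwrite(cts, counts_path, sep = "\t")
  invisible(c(ledger = ledger_path, counts = counts_path))
}

#' @rdname write_truth
#' @param prefix Path prefix used by [write_truth()].
#' @return `read_truth`: list with `ledger` (data.table) and `counts`
#'   (integer matrix).
#' @export
read_truth <- function(prefix) {
  ledger <- data.table::fread(paste0(prefix, "_ledger.tsv"),
                              colClasses = list(character = c("gene", "umi")))
  cts <- data.table::fread(paste0(prefix, "_counts.tsv"))
  m <- as.matrix(cts[, -1])
  rownames(m) <- as.character(cts[[1]])
  storage.mode(m) <- "integer"
  list(ledger = ledger, counts = m)
}
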