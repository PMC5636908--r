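test_that("median-of-ratios factors match hand arithmetic", {
  # two samples; two genes with counts (2,8) across the samples:
  # geometric means 4, ratios (0.5, 0.5) and (2, 2)
  tab <- rbind(s1 = c(2, 2), s2 = c(8, 8))
  expect_equal(unname(size_factors(tab)), c(0.5, 2))
  # identical columns: all factors 1
  expect_equal(unname(size_factors(rbind(c(3, 7, 1), c(3, 7, 1)))), c(1, 1))
})

test_that("size factors are equivariant under column scaling", {
  set.seed(4)
  for (i in 1:20) {
    tab <- matrix(rnbinom(5 * 60, mu = 20, size = 5) + 1, 5, 60)
    sf <- size_factors(tab)
    c_scale <- runif(1, 0.2, 5)
    tab2 <- tab
    tab2[3, ] <- tab[3, ] * c_scale
    sf2 <- size_factors(tab2)
    # scaling a unit by c rescales all geometric means by c^(1/m), so the
    # estimator is equivariant in the factor ratios: the scaled unit's
    # factor grows c-fold relative to every other unit
    expect_equal(sf2[3] / sf2[-3], c_scale * sf[3] / sf[-3],
                 tolerance = 1e-12)
    # and unscaled units keep their relative factors exactly
    expect_equal(sf2[-3] / sf2[1], sf[-3] / sf[1], tolerance = 1e-12)
  }
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  tab <- matrix(rnbinom(6 * 200, mu = 15, size = 3), 6, 200)
  tab <- tab[, colSums(tab == 0) == 0]   # reference genes only
  ours <- unname(size_factors(tab))
  theirs <- unname(DESeq2::estimateSizeFactorsForMatrix(t(tab)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("size factors error without a reference gene", {
  tab <- rbind(c(0, 5), c(5, 0))
  expect_error(size_factors(tab), "no reference genes")
})

test_that("positive-counts size factors extend the strict estimator to sparse tables", {
  # identical on zero-free tables
  set.seed(21)
  tab <- matrix(rnbinom(5 * 60, mu = 20, size = 5) + 1, 5, 60)
  expect_equal(size_factors(tab, type = "poscounts"), size_factors(tab))
  # defined on zero-rich tables where the strict estimator fails, and
  # still tracks a planted depth difference
  sparse <- matrix(rnbinom(12 * 300, mu = 0.3, size = 1), 12, 300)
  sparse[2, ] <- sparse[2, ] + rnbinom(300, mu = 2, size = 1)
  expect_error(size_factors(sparse), "no reference genes")
  sf <- size_factors(sparse, type = "poscounts")
  expect_true(all(sf > 0))
  expect_gt(sf[2], max(sf[-2]))
})

test_that("pseudocount-log normalization matches the elementwise closed form", {
  expect_equal(normalize_log(matrix(0, 1, 1), sf = 1)[1, 1], 0)
  expect_equal(normalize_log(matrix(exp(1) - 1, 1, 1), sf = 1)[1, 1], 1)
  set.seed(6)
  tab <- matrix(rnbinom(4 * 30, mu = 10, size = 5), 4, 30)
  sf <- c(0.5, 1, 2, 1.5)
  got <- normalize_log(tab, sf, pseudocount = 1, base = 2)
  want <- log2(1 + sweep(tab, 1, sf, "/"))
  expect_equal(got, want)
  expect_true(all(got >= 0))
})

test_that("pairwise correlation is 1 on identical samples and drops all-zero genes", {
  m <- simulate_expression(simulate_region_map(small_layout(), seed = 1),
                           noise_free_model(depth_scale = 0.2), seed = 2)
  sm <- st_counts(m$counts, small_layout()$features)
  expect_equal(pairwise_correlation(sm, sm), 1)
  # invariance to genes zero in both samples
  va <- aggregate_sample(sm)
  vb <- va + rpois(length(va), 3)
  r1 <- pairwise_correlation(va, vb)
  va2 <- c(va, DEAD1 = 0, DEAD2 = 0)
  vb2 <- c(vb, DEAD1 = 0, DEAD2 = 0)
  expect_equal(pairwise_correlation(va2, vb2), r1)
})

test_that("same-model replicate sections correlate higher than cross-model ones", {
  layout <- small_layout()
  rmap <- simulate_region_map(layout, seed = 2)
  base <- noise_free_model(depth_scale = 0.3)
  shifted <- noise_free_model(depth_scale = 0.3)
  set.seed(30)
  shifted$genes$base_mean <- shifted$genes$base_mean *
    exp(rnorm(nrow(shifted$genes), sd = 1.5))
  same <- numeric(20); cross <- numeric(20)
  for (i in 1:20) {
    a <- aggregate_sample(st_counts(
      simulate_expression(rmap, base, seed = 100 + i)$counts,
      layout$features))
    b <- aggregate_sample(st_counts(
      simulate_expression(rmap, base, seed = 200 + i)$counts,
      layout$features))
    c <- aggregate_sample(st_counts(
      simulate_expression(rmap, shifted, seed = 300 + i)$counts,
      layout$features))
    same[i] <- pairwise_correlation(a, b)
    cross[i] <- pairwise_correlation(a, c)
  }
  expect_gt(mean(same), mean(cross))
  expect_gt(mean(same), 0.9)
})

test_that("PCA on top expressed genes has orthogonal scores and unit variance split", {
  set.seed(9)
  tab <- matrix(rnbinom(6 * 300, mu = 25, size = 4) + 1, 6, 300,
                dimnames = list(paste0("s", 1:6), paste0("g", 1:300)))
  p <- pca_top_expressed(tab, n_top = 100)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-9)
  # scores covariance is diagonal (matches eigen-decomposition route)
  cv <- stats::cov(p$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_equal(length(p$genes), 100)
  # requesting more genes than exist falls back to all, with a warning
  expect_warning(p2 <- pca_top_expressed(tab, n_top = 1000), "using all")
  expect_equal(length(p2$genes), 300)
})

test_that("duplicated sample groups separate on PC1 with dominant variance", {
  set.seed(10)
  profile_a <- rnbinom(200, mu = 30, size = 5) + 1
  profile_b <- profile_a + rnbinom(200, mu = 30, size = 5)
  tab <- rbind(a1 = profile_a, a2 = profile_a + rpois(200, 1),
               b1 = profile_b, b2 = profile_b + rpois(200, 1))
  colnames(tab) <- paste0("g", 1:200)
  p <- pca_top_expressed(tab, n_top = 200)
  expect_gt(p$var_frac[1], 0.9)
  pc1 <- p$scores[, 1]
  expect_true(all(pc1[1:2] < 0) || all(pc1[1:2] > 0))
  expect_true(sign(mean(pc1[1:2])) != sign(mean(pc1[3:4])))
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  p2 <- pca_top_expressed(tab[perm, ], n_top = 200)
  expect_equal(abs(p2$scores[, 1]), abs(pc1[perm]), tolerance = 1e-8)
})

test_that("variance ranking puts planted genes first and constants last", {
  set.seed(11)
  norm <- matrix(rnorm(50 * 20, sd = 0.3), 50, 20,
                 dimnames = list(NULL, sprintf("g%02d", 1:20)))
  norm[, "g07"] <- rnorm(50, sd = 4)     # planted high variance
  norm[, "g13"] <- 1                     # constant
  ord <- top_variance_genes(norm, n_top = 20)
  expect_equal(ord[1], "g07")
  expect_equal(ord[20], "g13")
  # matches a direct variance oracle
  v <- apply(norm, 2, var)
  expect_equal(ord, names(sort(-v)))
  # n_top beyond the gene count returns the full ordering
  expect_equal(length(top_variance_genes(norm, n_top = 100)), 20)
  # deterministic lexicographic tie-break
  tied <- cbind(bb = c(0, 1, 0, 1), aa = c(0, 1, 0, 1))
  expect_equal(top_variance_genes(tied, 2), c("aa", "bb"))
})

test_that("differential expression flags planted changes, not nulls", {
  set.seed(12)
  n <- 40
  counts <- matrix(rnbinom(2 * n * 100, mu = 10, size = 2.5), 2 * n, 100,
                   dimnames = list(NULL, paste0("g", 1:100)))
  counts[1:n, "g1"] <- rnbinom(n, mu = 80, size = 2.5)  # planted 8-fold
  m <- st_counts(counts, data.frame(feature_id = 1:(2 * n)))
  de <- differential_expression(m, 1:n, (n + 1):(2 * n))
  expect_true(de$de_flag[de$gene == "g1"])
  expect_gt(de$log2fc[de$gene == "g1"], 1)
  expect_lt(mean(de$de_flag[-1]), 0.1)
  # BH monotonicity: adjusted p respects the raw-p order and exceeds it
  expect_true(all(de$padj >= de$pvalue - 1e-15))
  o <- order(de$pvalue)
  expect_true(all(diff(cummin(rev(de$padj[o]))) <= 1e-15))
  expect_true(all(diff(de$padj[o]) >= -1e-15))
})

test_that("all-zero genes are reported flat and unflagged", {
  counts <- matrix(5L, 6, 3, dimnames = list(NULL, c("a", "b", "zero")))
  counts[, "zero"] <- 0L
  m <- st_counts(counts, data.frame(feature_id = 1:6))
  de <- differential_expression(m, 1:3, 4:6)
  z <- de[de$gene == "zero", ]
  expect_equal(z$log2fc, 0)
  expect_equal(z$pvalue, 1)
  expect_false(z$de_flag)
})

test_that("degenerate DE groups are rejected", {
  m <- st_counts(matrix(1L, 4, 2, dimnames = list(NULL, c("a", "b"))),
                 data.frame(feature_id = 1:4))
  expect_error(differential_expression(m, 1:2, 2:3), "disjoint")
  expect_error(differential_expression(m, 1, 2:4), "at least 2")
})

test_that("saturation curves are computed per subsample and nondecreasing in expectation", {
  layout <- small_layout()
  rmap <- simulate_region_map(layout, seed = 2)
  model <- expression_model(n_genes = 80, depth_scale = 0.3,
                            duplication_rate = 0.4, contamination = 0,
                            barcode_error_rate = 0, homopolymer_rate = 0)
  truth <- simulate_expression(rmap, model, seed = 3)
  reads <- simulate_reads(truth, layout, small_transcriptome(), seed = 4)
  tf <- tempfile(); write_barcode_reference(layout, tf)
  ref <- read_barcode_reference(tf)
  gi <- gene_index(small_transcriptome())
  total <- length(reads$id)
  sizes <- c(0, floor(total / 4), floor(total / 2), total)
  sc <- saturation_curve(reads, sizes = sizes, n_reps = 2,
                         reference = ref, gene_idx = gi, seed = 5)
  expect_equal(sc$summary$size, sort(sizes))
  expect_true(all(diff(sc$summary$mean_transcripts) >= 0))
  expect_true(all(diff(sc$summary$mean_genes) >= 0))
  expect_equal(sc$summary$mean_transcripts[1], 0)
  # degenerate full-size subsample equals the full pipeline
  full <- run_pipeline(reads, ref, gi)
  expect_equal(sc$replicates$mean_transcripts[sc$replicates$size == total],
               rep(mean(rowSums(full$counts$counts)), 2))
  expect_error(saturation_curve(reads, sizes = total + 1, reference = ref,
                                gene_idx = gi), "exceeds")
})
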