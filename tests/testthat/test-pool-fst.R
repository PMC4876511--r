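test_that("coverage-tail exclusion uses the nearest-rank quantile over any pool", {
  pc <- make_counts(ref_counts = cbind(1:100), alt_counts = cbind(rep(0, 100)))
  out <- exclude_high_expression_positions(pc, fraction = 0.02)
  expect_equal(n_positions(out), 98L)
  expect_equal(max(coverage_matrix(out)), 98L)

  expect_equal(n_positions(exclude_high_expression_positions(pc, 0)), 100L)
  expect_error(exclude_high_expression_positions(pc, 1), "fraction")

  # over-quantile in pool 2 only: dropped for all pools
  ref <- cbind(rep(10, 50), c(rep(10, 49), 1000))
  pc2 <- make_counts(ref, matrix(0, 50, 2))
  out2 <- exclude_high_expression_positions(pc2, fraction = 0.02)
  expect_equal(n_positions(out2), 49L)
  expect_false(50L %in% out2$pos)
})

test_that("sub-sampling is degenerate-exact, unbiased and seed-deterministic", {
  pc <- make_counts(ref_counts = cbind(0), alt_counts = cbind(20))
  s <- subsample_frequencies(pc, target_coverage = 10, replicates = 50, seed = 1)
  expect_equal(unname(s$freq[1, 1]), 1.0)

  pc2 <- make_counts(ref_counts = cbind(10), alt_counts = cbind(10))
  s2 <- subsample_frequencies(pc2, 10, 50, seed = 2)
  se <- sqrt(0.25 / 10) / sqrt(50)
  expect_lt(abs(s2$freq[1, 1] - 0.5), 3 * se)

  s3 <- subsample_frequencies(pc2, 10, 50, seed = 2)
  expect_identical(s2$freq, s3$freq)

  # positions below target coverage are dropped
  pc3 <- make_counts(ref_counts = cbind(c(5, 30)), alt_counts = cbind(c(2, 10)))
  s4 <- subsample_frequencies(pc3, 10, 5, seed = 1)
  expect_equal(n_positions(s4$counts), 1L)
  expect_equal(s4$n_dropped, 1L)
})

test_that("per-SNP FST matches the hand-derived component arithmetic", {
  eq <- snp_fst(0.3, 0.3, 100, 100)
  expect_equal(eq$fst, 0)

  fx <- snp_fst(1, 0, 100, 100)
  expect_equal(fx$pi_s, 0)
  expect_equal(fx$fst, 1)

  hv <- snp_fst(0.8, 0.2, 50, 50)
  expect_equal(hv$fst, 0.36)
  c50 <- 50 / 49
  expect_equal(hv$pi_s, 0.32 * c50)
  expect_equal(hv$pi_t, 0.5 * c50)

  # both pools fixed for the same allele: undefined
  expect_true(is.na(snp_fst(1, 1, 100, 100)$fst))
  expect_true(is.na(snp_fst(0, 0, 100, 100)$fst))
})

test_that("gene FST is the ratio of sums over SNP components", {
  one <- snp_fst(0.8, 0.2, 50, 50)
  expect_equal(gene_fst(one$pi_t, one$pi_s), one$fst)
  expect_equal(gene_fst(c(0.5, 0.5), c(0.32, 0.50)), 0.18)
  expect_equal(gene_fst(c(0.4, 0.3), c(0.4, 0.3)), 0)
  expect_true(is.na(gene_fst(c(0, NA), c(0, NA))))
  # mean-of-ratios alternative
  expect_equal(gene_fst(c(0.5, 0.5), c(0.25, 0.5), mean_of_ratios = TRUE), 0.25)
})

test_that("Fisher exact p matches known tables and the significance rule", {
  expect_equal(-log10(fisher_exact_p(10, 0, 0, 10)), -log10(2 / 184756),
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_p(0, 0, 0, 10), 1)  # zero margin convention

  # gene significance: mean -log10 p over SNPs against 1.301
  pc <- make_counts(ref_counts = cbind(c(10, 2), c(5, 10)),
                    alt_counts = cbind(c(0, 8), c(5, 0)))
  s <- subsample_frequencies(pc, 10, 50, seed = 5)
  comp <- pairwise_fst_components(s$freq, 10, 100)
  tab <- gene_fst_table(comp, c("gA", "gA"), s$alt_sub, 10)
  hand <- mean(-log10(fisher_exact_p(s$alt_sub[, 1], 10 - s$alt_sub[, 1],
                                     s$alt_sub[, 2], 10 - s$alt_sub[, 2])))
  expect_equal(tab$neglog10p, hand)
  expect_equal(tab$significant, hand >= 1.301)
})

test_that("highly variable genes require a strict 1.301 threshold", {
  tab <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3"),
    pair = c("a", "b", "a", "b", "a"),
    fst = 0.1,
    neglog10p = c(0.5, 2.5, 1.30, 1.30, 1.301),
    significant = c(0.5, 2.5, 1.30, 1.30, 1.301) >= 1.301
  )
  expect_setequal(highly_variable_genes(tab), c("g1", "g3"))
})

test_that("ten-gene significance fixture equals hand enumeration", {
  set.seed(41)
  genes <- rep(sprintf("g%02d", 1:10), each = 3)
  n <- length(genes)
  alt <- cbind(sample(0:10, n, TRUE), sample(0:10, n, TRUE))
  freq <- alt / 10
  comp <- pairwise_fst_components(freq, 10, 100)
  tab <- gene_fst_table(comp, genes, alt, 10)
  p <- fisher_exact_p(alt[, 1], 10 - alt[, 1], alt[, 2], 10 - alt[, 2])
  hand_sig <- tapply(-log10(p), genes, mean) >= 1.301
  expect_equal(tab$significant, as.vector(hand_sig[tab$gene]))
  expect_setequal(highly_variable_genes(tab), names(which(hand_sig)))
})

test_that("FST histogram bin conventions and percentages", {
  h <- fst_histogram(rep(0.005, 10))
  expect_equal(h$percent[1], 100)
  h2 <- fst_histogram(c(1.0))
  expect_equal(h2$count[100], 1L)
  expect_equal(sum(h2$percent), 100)
  set.seed(6)
  h3 <- fst_histogram(runif(1000))
  expect_equal(sum(h3$percent), 100)
  gof <- chisq.test(h3$count, p = rep(0.01, 100))
  expect_gt(gof$p.value, 0.001)
})

test_that("overall FST: degenerate cases and brute-force equivalence", {
  freq_same <- matrix(rep(c(0.2, 0.7, 0.5), 4), ncol = 4)
  comp <- pairwise_fst_components(freq_same, 30, 100)
  expect_true(all(overall_fst(comp) == 0))

  freq_opp <- cbind(rep(1, 5), rep(0, 5))
  comp2 <- pairwise_fst_components(freq_opp, 30, 100)
  expect_equal(overall_fst(comp2)[1, 2], 1)

  set.seed(51)
  freq <- matrix(runif(50 * 4), 50, 4)
  comp3 <- pairwise_fst_components(freq, 30, 100)
  m <- overall_fst(comp3)
  # independent brute force, summing per-SNP components pair by pair
  n_eff <- min(30, 100)
  corr <- n_eff / (n_eff - 1)
  for (i in 1:3) for (j in (i + 1):4) {
    pit <- pis <- numeric(50)
    for (k in 1:50) {
      p1 <- freq[k, i]; p2 <- freq[k, j]
      pis[k] <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2 * corr
      pb <- (p1 + p2) / 2
      pit[k] <- 2 * pb * (1 - pb) * corr
    }
    ok <- pit > 0
    expect_equal(m[i, j], max(0, (sum(pit[ok]) - sum(pis[ok])) / sum(pit[ok])),
                 tolerance = 1e-12)
  }
})

test_that("replicate pools drawn from identical frequencies give near-zero FST", {
  # field vs controlled-condition style replicates: same true frequencies,
  # independent read sampling
  set.seed(61)
  p <- runif(2000)
  cov <- 60L
  alt1 <- rbinom(2000, cov, p); alt2 <- rbinom(2000, cov, p)
  freq <- cbind(alt1, alt2) / cov
  comp <- pairwise_fst_components(freq, cov, 100)
  expect_lt(overall_fst(comp)[1, 2], 0.05)
})

test_that("drift-tree structure is reflected in the overall FST matrix", {
  ds <- generate_dataset(sim_config(n_genes = 300, n_associated_genes = 0,
                                    seed = 19))
  filt <- filter_variants(ds$counts)
  s <- subsample_frequencies(filt, 10, 50, seed = 3)
  comp <- pairwise_fst_components(s$freq, 10, 100)
  m <- overall_fst(comp)
  off <- m[upper.tri(m)]
  # P3/P4 are the near-identical pair: smallest pairwise distance
  expect_equal(min(off), m["P3", "P4"])
})

test_that("per-SNP FST is clamped to [0,1] and monotone in |p1 - p2| at pbar = 0.5", {
  set.seed(71)
  p1 <- runif(500); p2 <- runif(500)
  f <- snp_fst(p1, p2, 100, 100)$fst
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  d <- seq(0, 0.5, by = 0.05)
  fst_d <- snp_fst(0.5 + d, 0.5 - d, 100, 100)$fst
  expect_true(all(diff(fst_d) > 0))
})
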