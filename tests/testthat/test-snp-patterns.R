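test_that("variant filter applies inclusive MAF and coverage thresholds", {
  # one position at exactly MAF 0.05 (1 alt / 20 reads): inclusive boundary
  pc <- make_counts(ref_counts = cbind(19), alt_counts = cbind(1))
  kept <- filter_variants(pc, min_maf = 0.05, min_coverage = 20)
  expect_equal(n_positions(kept), 1L)
  # coverage 19 in one pool: dropped
  pc2 <- make_counts(ref_counts = cbind(15, 30), alt_counts = cbind(4, 10))
  expect_equal(n_positions(filter_variants(pc2)), 0L)
})

test_that("hand-built filter fixture: 3 of 10 positions violate the rules", {
  ref <- cbind(c(19, 10, 30, 25, 40, 20, 18, 50, 22, 35),
               c(20, 15, 28, 24, 39, 20, 30, 48, 25, 30))
  alt <- cbind(c(1, 15, 10, 0, 5, 10, 4, 0, 8, 5),
               c(0, 10, 12, 1, 6, 10, 2, 1, 5, 10))
  # hand-derived violations (pooled MAF on 2 pools, coverage >= 20 in both):
  # row 1: MAF = 1/40 = 0.025 < 0.05            -> drop
  # row 4: MAF = 1/50 = 0.02  < 0.05            -> drop
  # row 7: pool2 coverage 32, pool1 coverage 22; MAF 6/54 = 0.111 -> keep
  # row 8: MAF = 1/99 ~ 0.0101 < 0.05           -> drop
  pc <- make_counts(ref, alt)
  kept <- filter_variants(pc, min_maf = 0.05, min_coverage = 20)
  expect_equal(n_positions(kept), 7L)
  expect_false(any(kept$pos %in% c(1L, 4L, 8L)))
})

test_that("population-specific classification follows the presence rules", {
  ann <- data.frame(chrom = "chr1", pos = 1:3,
                    effect_class = "nonsyn_nondeleterious",
                    known = c(TRUE, FALSE, TRUE))
  pc <- make_counts(ref_counts = matrix(10, 3, 4),
                    alt_counts = rbind(c(5, 0, 0, 0),
                                       c(5, 0, 0, 0),
                                       c(5, 0, 2, 0)))
  calls <- classify_population_specific(pc, ann)
  expect_equal(calls$scope, c("local_specific", "global_specific", "shared"))
  expect_equal(calls$focal_pop, c("P1", "P1", NA))
})

test_that("merging two pools into one unit changes locality", {
  ann <- data.frame(chrom = "chr1", pos = 1L,
                    effect_class = "nonsyn_nondeleterious", known = TRUE)
  pc <- make_counts(ref_counts = matrix(10, 1, 4),
                    alt_counts = rbind(c(0, 0, 2, 3)))
  plain <- classify_population_specific(pc, ann)
  expect_equal(plain$scope, "shared")
  merged <- classify_population_specific(pc, ann, merge_pools = c("P3", "P4"))
  expect_equal(merged$scope, "local_specific")
  expect_equal(merged$focal_pop, "P3+P4")
})

test_that("only non-deleterious non-synonymous SNPs are classified", {
  ann <- data.frame(chrom = "chr1", pos = 1:3,
                    effect_class = c("synonymous", "nonsyn_deleterious",
                                     "nonsyn_nondeleterious"),
                    known = FALSE)
  pc <- make_counts(ref_counts = matrix(10, 3, 4),
                    alt_counts = matrix(c(5, 5, 5), 3, 4))
  calls <- classify_population_specific(pc, ann)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 3L)
})

test_that("frequency summaries: fixation, means and empty subsets", {
  # single pool with frequencies 1.0, 0.5, 0.25, 1.0
  pc <- make_counts(ref_counts = cbind(c(0, 10, 30, 0)),
                    alt_counts = cbind(c(20, 10, 10, 40)))
  s <- summarize_allele_frequencies(pc)
  expect_equal(unname(s$pct_fixed), 50)
  expect_equal(unname(s$mean_freq), 0.6875)
  expect_true(is.na(s$mean_freq_local_specific[1]))

  # every SNP fixed
  pc2 <- make_counts(ref_counts = cbind(c(0, 0)), alt_counts = cbind(c(7, 9)))
  expect_equal(unname(summarize_allele_frequencies(pc2)$pct_fixed), 100)
})

test_that("Ts/Tv ratio follows the transition definition", {
  expect_equal(transition_transversion_ratio(
    ref = c("A", "G", "C", "T", "A", "C"),
    alt = c("G", "A", "T", "C", "C", "G")), 2.0)
  expect_true(is.na(transition_transversion_ratio("A", "G")))
  set.seed(31)
  ref <- sample(c("A", "T", "C", "G"), 100, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "T", "C", "G"), r), 1), "")
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  hand <- sum(pair %in% c("AG", "CT")) / sum(!pair %in% c("AG", "CT"))
  expect_equal(transition_transversion_ratio(ref, alt), hand)
})

test_that("SNP density bins are left-closed on bases-per-SNP", {
  gm <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                   start = c(1, 1000), end = c(450, 1999))
  h1 <- snp_density_distribution(gm, c("g1"))
  expect_equal(h1$bin_lower[h1$count == 1], 400)
  h2 <- snp_density_distribution(gm, c("g2", "g2"))
  expect_equal(h2$bin_lower[h2$count == 1], 500)
  expect_error(
    snp_density_distribution(data.frame(gene = "g", chrom = "c", start = 5,
                                        end = 4), "g"),
    "length")
})

test_that("20-gene density histogram equals direct enumeration", {
  set.seed(12)
  len <- sample(200:2000, 20)
  nsnp <- sample(1:6, 20, replace = TRUE)
  gm <- data.frame(gene = sprintf("g%02d", 1:20), chrom = "chr1",
                   start = 1, end = len)
  snp_genes <- rep(gm$gene, nsnp)
  h <- snp_density_distribution(gm, snp_genes)
  hand <- table(floor((len / nsnp) / 100) * 100)
  expect_equal(h$count, as.integer(hand))
  expect_equal(h$bin_lower, as.numeric(names(hand)))
  expect_equal(sum(h$percent), 100)
})

test_that("classification partitions SNPs and nests global within local", {
  ds <- small_dataset(seed = 23, frac_pop_specific = 0.2)
  filt <- filter_variants(ds$counts)
  ann <- ds$truth$snps[c("chrom", "pos", "effect_class", "known")]
  calls <- classify_population_specific(filt, ann)
  expect_equal(sum(calls$scope == "shared") +
                 sum(calls$scope %in% c("local_specific", "global_specific")),
               nrow(calls))
  # every eligible SNP classified exactly once
  n_elig <- sum(ann$effect_class == "nonsyn_nondeleterious" &
                  paste(ann$chrom, ann$pos) %in%
                    paste(filt$chrom, filt$pos))
  expect_equal(nrow(calls), n_elig)
})

test_that("planted population-specific SNPs sit at lower frequencies than shared ones", {
  ds <- generate_dataset(sim_config(n_genes = 400, n_associated_genes = 0,
                                    frac_pop_specific = 0.15, seed = 29))
  ac <- allele_counts(ds$counts)
  freq <- ifelse(ac$coverage > 0, ac$alt / ac$coverage, NA)
  ps <- ds$truth$snps$pop_specific
  # compare the focal-pool frequency of private SNPs with the overall mean
  # frequency of shared SNPs
  focal_freq <- freq[cbind(which(ps), match(ds$truth$snps$focal_pop[ps],
                                            ds$counts$pools))]
  shared_freq <- as.vector(freq[!ps, ])
  se <- sqrt(var(focal_freq, na.rm = TRUE) / sum(!is.na(focal_freq)) +
               var(shared_freq, na.rm = TRUE) / sum(!is.na(shared_freq)))
  expect_lt(mean(focal_freq, na.rm = TRUE) + 3 * se,
            mean(shared_freq, na.rm = TRUE))
})
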