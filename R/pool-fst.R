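#' Exclude the most highly covered positions
#'
#' Removes the expression-driven upper tail of the coverage distribution:
#' per pool, the nearest-rank `(1 - fraction)` quantile of position coverage
#' is computed, and a position is dropped when its coverage strictly exceeds
#' that quantile in any pool.
#'
#' @param counts a [pool_counts] object.
#' @param fraction fraction of the upper tail to remove (default 0.02).
#' @return The filtered [pool_counts]; attribute `n_dropped` records the
#'   number of removed positions.
#' @export
exclude_high_expression_positions <- function(counts, fraction = 0.02) {
  if (fraction >= 1 || fraction < 0) stopf("fraction must lie in [0, 1)")
  cov <- coverage_matrix(counts)
  n <- nrow(cov)
  if (n == 0L || fraction == 0) {
    attr(counts, "n_dropped") <- 0L
    return(counts)
  }
  rank_idx <- max(1L, ceiling((1 - fraction) * n))
  q <- apply(cov, 2L, function(v) sort(v)[rank_idx])
  over <- sweep(cov, 2L, q, `>`)
  keep <- !apply(over, 1L, any)
  out <- counts[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Sub-sampled allele-frequency estimation
#'
#' Equalises coverage across positions and pools: for every position and
#' pool, `replicates` draws of `target_coverage` reads are taken with
#' replacement from the observed (reference, alternate) read counts, and the
#' frequency estimate is the mean alternate fraction over replicates.
#' Positions whose coverage falls below `target_coverage` in any pool are
#' dropped.
#'
#' @param counts a [pool_counts] object.
#' @param target_coverage even target coverage per position per pool
#'   (10 for single datasets, 20 for combined, by convention).
#' @param replicates number of sub-sampling replicates (default 50).
#' @param seed RNG seed; estimates are deterministic given the seed.
#' @return A list with `freq` (positions x pools estimate matrix), `counts`
#'   (the retained [pool_counts]), `alt_sub` (rounded sub-sampled alternate
#'   counts at target coverage, round-half-to-even, for downstream exact
#'   tests), `target_coverage` and `n_dropped`.
#' @export
subsample_frequencies <- function(counts, target_coverage = 10,
                                  replicates = 50, seed = NULL) {
  if (target_coverage < 1) stopf("target_coverage must be >= 1")
  if (replicates < 1) stopf("replicates must be >= 1")
  ac <- allele_counts(counts)
  keep <- apply(ac$coverage >= target_coverage, 1L, all)
  kept <- counts[keep]
  ac <- allele_counts(kept)
  n <- nrow(ac$alt)
  np <- ncol(ac$alt)
  p_raw <- ifelse(ac$coverage > 0, ac$alt / ac$coverage, 0)
  freq <- matrix(0, n, np, dimnames = list(NULL, kept$pools))
  if (n > 0L) {
    with_seed(seed, {
      for (r in seq_len(replicates)) {
        # with-replacement draws of target_coverage reads = binomial draws
        draw <- stats::rbinom(n * np, size = target_coverage,
                              prob = as.vector(p_raw))
        freq <- freq + matrix(draw, n, np) / target_coverage
      }
    })
    freq <- freq / replicates
  }
  list(freq = freq, counts = kept,
       alt_sub = matrix(as.integer(round(freq * target_coverage)), n, np,
                        dimnames = list(NULL, kept$pools)),
       target_coverage = target_coverage, n_dropped = sum(!keep))
}

#' Per-SNP pool FST components for one population pair
#'
#' Heterozygosities use the finite-pool unbiasedness correction
#' `n / (n - 1)` with effective size `n = min(haploid pool size, coverage)`:
#' `pi_i = 2 p_i (1 - p_i) n_i / (n_i - 1)`, `pi_S = (pi_1 + pi_2) / 2`,
#' and `pi_T = 2 pbar (1 - pbar) ntilde / (ntilde - 1)` with
#' `pbar = (p_1 + p_2) / 2` and `ntilde = min(n_1, n_2)`. FST is
#' `(pi_T - pi_S) / pi_T`, clamped at 0, and undefined (NA) when `pi_T = 0`
#' (both pools fixed for the same allele).
#'
#' @param p1,p2 alternate-allele frequencies in the two pools.
#' @param n1,n2 effective sizes, `min(haploid pool size, coverage)` per pool.
#' @return List with `pi_t`, `pi_s`, `fst` (vectors; `fst` is NA where
#'   undefined).
#' @export
snp_fst <- function(p1, p2, n1, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stopf("effective sizes must be >= 2")
  pi1 <- 2 * p1 * (1 - p1) * n1 / (n1 - 1)
  pi2 <- 2 * p2 * (1 - p2) * n2 / (n2 - 1)
  pi_s <- (pi1 + pi2) / 2
  pbar <- (p1 + p2) / 2
  nt <- pmin(n1, n2)
  pi_t <- 2 * pbar * (1 - pbar) * nt / (nt - 1)
  fst <- ifelse(pi_t > 0, pmax(0, (pi_t - pi_s) / pi_t), NA_real_)
  list(pi_t = pi_t, pi_s = pi_s, fst = fst)
}

#' Gene-level FST as a ratio of sums
#'
#' Aggregates per-SNP components over a window (here: the gene body) as
#' `(sum pi_T - sum pi_S) / sum pi_T`, clamped at 0. Undefined components
#' (pi_T = 0) are excluded; a gene whose components are all undefined gets
#' NA. `mean_of_ratios = TRUE` instead averages per-SNP FST values (for
#' sensitivity checks).
#'
#' @param pi_t,pi_s per-SNP component vectors.
#' @param mean_of_ratios use the mean of per-SNP ratios instead.
#' @return Scalar gene FST in [0, 1], or NA.
#' @export
gene_fst <- function(pi_t, pi_s, mean_of_ratios = FALSE) {
  ok <- !is.na(pi_t) & pi_t > 0
  if (!any(ok)) return(NA_real_)
  if (mean_of_ratios) {
    return(mean(pmax(0, (pi_t[ok] - pi_s[ok]) / pi_t[ok])))
  }
  st <- sum(pi_t[ok])
  max(0, (st - sum(pi_s[ok])) / st)
}

#' All pairwise per-SNP FST components
#'
#' @param freq positions x pools frequency matrix.
#' @param coverage positions x pools coverage matrix (or a scalar, e.g. the
#'   sub-sampling target coverage).
#' @param pool_size haploid pool size (e.g. 200 for 100 diploids; 100 is the
#'   windowed-FST convention used downstream for single datasets).
#' @return A list with `pairs` (labels), `i`, `j` (pool indices), and
#'   `pi_t`, `pi_s`, `fst` (positions x pairs matrices).
#' @export
pairwise_fst_components <- function(freq, coverage, pool_size) {
  pools <- colnames(freq)
  if (is.null(pools)) pools <- paste0("P", seq_len(ncol(freq)))
  if (length(coverage) == 1L) {
    coverage <- matrix(coverage, nrow(freq), ncol(freq))
  }
  n_eff <- pmin(coverage, pool_size)
  pl <- pair_labels(pools)
  np <- length(pl$label)
  pi_t <- pi_s <- fst <- matrix(NA_real_, nrow(freq), np,
                                dimnames = list(NULL, pl$label))
  for (k in seq_len(np)) {
    cc <- snp_fst(freq[, pl$i[k]], freq[, pl$j[k]],
                  n_eff[, pl$i[k]], n_eff[, pl$j[k]])
    pi_t[, k] <- cc$pi_t
    pi_s[, k] <- cc$pi_s
    fst[, k] <- cc$fst
  }
  list(pairs = pl$label, i = pl$i, j = pl$j,
       pi_t = pi_t, pi_s = pi_s, fst = fst, pools = pools)
}

#' Per-gene, per-pair FST table with Fisher exact significance
#'
#' Builds the gene-level table used by the association screen: for every
#' gene and population pair, the ratio-of-sums gene FST, the mean
#' `-log10 p` of per-SNP two-sided Fisher exact tests on the sub-sampled
#' (reference, alternate) x (pool1, pool2) tables, and a significance flag
#' at the `-log10 p >= 1.301` convention. With
#' `any_snp_significant = TRUE` the gene flag instead requires at least one
#' per-SNP test to reach the threshold.
#'
#' @param components result of [pairwise_fst_components].
#' @param genes character vector assigning each position to a gene.
#' @param alt_sub rounded sub-sampled alternate counts (positions x pools).
#' @param target_coverage the sub-sampling target coverage.
#' @param neglog10_threshold significance threshold (default 1.301).
#' @param mean_of_ratios see [gene_fst].
#' @param any_snp_significant alternative gene-level significance rule.
#' @return data.frame with columns `gene`, `pair`, `fst`, `neglog10p`,
#'   `significant`.
#' @export
gene_fst_table <- function(components, genes, alt_sub, target_coverage,
                           neglog10_threshold = 1.301,
                           mean_of_ratios = FALSE,
                           any_snp_significant = FALSE) {
  keep <- !is.na(genes)
  lookup <- fisher_p_lookup(as.integer(target_coverage))
  gl <- sort(unique(genes[keep]))
  out <- vector("list", length(components$pairs))
  for (k in seq_along(components$pairs)) {
    a1 <- alt_sub[, components$i[k]]
    a2 <- alt_sub[, components$j[k]]
    p <- lookup[cbind(a1 + 1L, a2 + 1L)]
    nl <- -log10(p)
    df <- data.frame(gene = genes[keep],
                     pi_t = components$pi_t[keep, k],
                     pi_s = components$pi_s[keep, k],
                     nl = nl[keep])
    sp <- split(df, factor(df$gene, levels = gl))
    fst_g <- vapply(sp, function(d) gene_fst(d$pi_t, d$pi_s,
                                             mean_of_ratios), 0)
    nl_g <- vapply(sp, function(d) mean(d$nl), 0)
    sig <- if (any_snp_significant) {
      vapply(sp, function(d) any(d$nl >= neglog10_threshold), TRUE)
    } else {
      nl_g >= neglog10_threshold
    }
    out[[k]] <- data.frame(gene = gl, pair = components$pairs[k],
                           fst = unname(fst_g), neglog10p = unname(nl_g),
                           significant = unname(sig),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene, res$pair), , drop = FALSE]
}

#' Highly variable SNP-containing genes
#'
#' Genes with at least one significant pairwise comparison in the gene FST
#' table.
#'
#' @param fst_table result of [gene_fst_table].
#' @return Character vector of gene ids.
#' @export
highly_variable_genes <- function(fst_table) {
  sort(unique(fst_table$gene[fst_table$significant]))
}

#' Percentage frequency distribution of FST values
#'
#' Left-closed bins of the stated width over [0, 1]; the last bin is
#' right-closed so that a value of exactly 1 is counted.
#'
#' @param values FST values in [0, 1] (NAs dropped).
#' @param bin_width bin width (default 0.01).
#' @return data.frame with `bin_lower`, `bin_upper`, `count`, `percent`;
#'   percents sum to 100 when any value is present.
#' @export
fst_histogram <- function(values, bin_width = 0.01) {
  values <- values[!is.na(values)]
  if (any(values < 0 | values > 1)) stopf("FST values must lie in [0, 1]")
  n_bins <- as.integer(round(1 / bin_width))
  bin <- pmin(floor(values / bin_width), n_bins - 1L)  # 1.0 -> last bin
  counts <- tabulate(bin + 1L, nbins = n_bins)
  lower <- (seq_len(n_bins) - 1L) * bin_width
  data.frame(bin_lower = lower, bin_upper = lower + bin_width,
             count = counts,
             percent = if (length(values)) 100 * counts / length(values)
                       else rep(0, n_bins))
}

#' Genome-wide (overall) pairwise FST matrix
#'
#' The ratio-of-sums FST over all defined SNP components per pool pair; the
#' structure-control distance matrix of the association screen.
#'
#' @param components result of [pairwise_fst_components].
#' @return Symmetric matrix with zero diagonal, labelled by pool.
#' @export
overall_fst <- function(components) {
  ok_any <- FALSE
  v <- numeric(length(components$pairs))
  for (k in seq_along(components$pairs)) {
    ok <- !is.na(components$pi_t[, k]) & components$pi_t[, k] > 0
    if (!any(ok)) { v[k] <- NA_real_; next }
    ok_any <- TRUE
    st <- sum(components$pi_t[ok, k])
    v[k] <- max(0, (st - sum(components$pi_s[ok, k])) / st)
  }
  if (!ok_any) stopf("no defined SNP components")
  sym_from_upper(v, components$pools)
}
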