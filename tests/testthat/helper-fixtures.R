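# Small in-code fixtures shared across test files.

# pool_counts built from ref/alt count matrices (one column per pool).
make_counts <- function(ref_counts, alt_counts, ref_base = "A",
                        alt_base = "G", pools = NULL, chrom = "chr1",
                        pos = NULL) {
  ref_counts <- as.matrix(ref_counts)
  alt_counts <- as.matrix(alt_counts)
  n <- nrow(ref_counts)
  np <- ncol(ref_counts)
  if (is.null(pools)) pools <- paste0("P", seq_len(np))
  if (is.null(pos)) pos <- seq_len(n)
  ref_base <- rep_len(ref_base, n)
  alt_base <- rep_len(alt_base, n)
  counts <- array(0L, c(n, np, 6L))
  ri <- match(ref_base, c("A", "T", "C", "G", "N", "del"))
  ai <- match(alt_base, c("A", "T", "C", "G", "N", "del"))
  for (p in seq_len(np)) {
    counts[cbind(seq_len(n), p, ri)] <- ref_counts[, p]
    counts[cbind(seq_len(n), p, ai)] <- alt_counts[, p]
  }
  pool_counts(rep_len(chrom, n), pos, ref_base, counts, pools)
}

# A tiny deterministic synthetic dataset reused by several tests.
small_dataset <- function(seed = 42, ...) {
  args <- modifyList(list(n_genes = 80L, n_associated_genes = 4L, seed = seed),
                     list(...))
  generate_dataset(do.call(sim_config, args))
}

# Random symmetric zero-diagonal distance matrix.
random_dist <- function(n, labels = paste0("S", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  v <- runif(n * (n - 1) / 2)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  m
}
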