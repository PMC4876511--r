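#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbour joining (via [ape::nj]); negative branch
#' lengths, which NJ can produce on noisy matrices, are floored at zero with
#' the deficit transferred to the sibling edge so path lengths through the
#' parent node are preserved.
#'
#' @param d symmetric non-negative matrix with zero diagonal and labels.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stopf("need at least 3 labels")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("P", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stopf("distance matrix diagonal must be zero")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- which(tr$edge[, 1L] == parent & seq_along(tr$edge.length) != e)
    if (length(sib)) {
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Bootstrap majority-rule consensus tree from per-locus FST components
#'
#' Resamples SNP loci with replacement, recomputes the genome-wide pairwise
#' FST matrix (ratio of sums over the resampled loci) for each replicate,
#' builds a neighbour-joining tree per replicate, and returns the
#' majority-rule (> 50%) consensus with node labels giving the percentage of
#' replicate trees containing each bipartition.
#'
#' @param components result of [pairwise_fst_components] (loci are the
#'   resampling unit).
#' @param n_reps number of bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @return A list with `consensus` (an [ape::phylo] with percentage support
#'   in `node.label`), `trees` (the replicate trees, `multiPhylo`) and
#'   `n_reps`.
#' @export
bootstrap_consensus <- function(components, n_reps = 500, seed = NULL) {
  n_loci <- nrow(components$pi_t)
  if (n_loci < 2L) stopf("need at least 2 loci to resample")
  if (n_reps < 1L) stopf("n_reps must be >= 1")
  trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(n_loci, n_loci, replace = TRUE)
      sub <- list(pairs = components$pairs, pools = components$pools,
                  pi_t = components$pi_t[idx, , drop = FALSE],
                  pi_s = components$pi_s[idx, , drop = FALSE])
      m <- overall_fst(sub)
      m[is.na(m)] <- 0
      nj_tree(m)
    })
  })
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  cons$node.label <- as.character(round(100 * counts / n_reps))
  list(consensus = cons, trees = trees, n_reps = n_reps)
}

#' Test whether a tree contains a given bipartition
#'
#' @param tree an [ape::phylo] tree.
#' @param tips character vector: one side of the bipartition.
#' @return TRUE when some internal edge splits the leaves into `tips`
#'   versus the rest.
#' @export
has_bipartition <- function(tree, tips) {
  all_tips <- tree$tip.label
  if (!all(tips %in% all_tips)) stopf("unknown tip label")
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  want1 <- sort(match(tips, labs))
  want2 <- sort(match(setdiff(all_tips, tips), labs))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, want1) || identical(sp, want2)) return(TRUE)
  }
  FALSE
}

#' Support of a bipartition in a consensus result
#'
#' @param boot result of [bootstrap_consensus].
#' @param tips character vector: one side of the bipartition.
#' @return Percentage of replicate trees containing the bipartition.
#' @export
bipartition_support <- function(boot, tips) {
  hits <- vapply(boot$trees, has_bipartition, TRUE, tips = tips)
  100 * mean(hits)
}
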