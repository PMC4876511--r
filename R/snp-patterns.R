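#' Filter variants by minor-allele frequency and coverage
#'
#' Applies the calling rules used throughout the pipeline: pooled (across
#' populations) minor-allele frequency at least `min_maf`, read coverage of
#' at least `min_coverage` in every pool, and removal of positions with zero
#' coverage in any pool. Both thresholds are inclusive.
#'
#' @param counts a [pool_counts] object.
#' @param min_maf minimum pooled minor-allele frequency (default 0.05).
#' @param min_coverage minimum per-pool coverage (default 20).
#' @return The filtered [pool_counts]; attribute `n_dropped` records how
#'   many positions were removed.
#' @export
filter_variants <- function(counts, min_maf = 0.05, min_coverage = 20) {
  ac <- allele_counts(counts)
  tot_alt <- rowSums(ac$alt)
  tot_ref <- rowSums(ac$ref)
  tot <- tot_alt + tot_ref
  maf <- ifelse(tot > 0, pmin(tot_alt, tot_ref) / tot, 0)
  keep <- maf >= min_maf &
    apply(ac$coverage >= min_coverage, 1L, all) &
    apply(ac$coverage > 0, 1L, all)
  out <- counts[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Classify population-specific SNPs
#'
#' A SNP is local-level population-specific when its alternate allele is
#' present (alternate count > 0) in exactly one pool, and global-level
#' population-specific when additionally it is not flagged as known in the
#' reference variant catalogue. Only non-synonymous non-deleterious SNPs are
#' classified (deleterious and synonymous variants are excluded upstream of
#' this analysis); other SNPs are absent from the result. Two pools can be
#' merged into one unit (e.g. a phylogenetically near-identical pair) via
#' `merge_pools`.
#'
#' @param counts a [pool_counts] object.
#' @param annotation data.frame with columns `chrom`, `pos`, `effect_class`
#'   (one of `synonymous`, `nonsyn_deleterious`, `nonsyn_nondeleterious`,
#'   `none`) and logical `known`.
#' @param merge_pools optional character vector of two pool names treated as
#'   a single population unit.
#' @return data.frame with columns `chrom`, `pos`, `scope` (`shared`,
#'   `local_specific`, `global_specific`) and `focal_pop` (unit name, NA for
#'   shared SNPs). `global_specific` rows satisfy the local criterion too.
#' @export
classify_population_specific <- function(counts, annotation,
                                         merge_pools = NULL) {
  ac <- allele_counts(counts)
  key <- paste(counts$chrom, counts$pos)
  akey <- paste(annotation$chrom, annotation$pos)
  idx <- match(key, akey)
  eligible <- !is.na(idx) &
    annotation$effect_class[idx] == "nonsyn_nondeleterious"
  present <- ac$alt > 0
  if (any(rowSums(present) == 0L & eligible)) {
    stopf("SNP absent in all pools: should have been filtered")
  }
  units <- counts$pools
  pres_u <- present
  if (!is.null(merge_pools)) {
    if (length(merge_pools) != 2L || !all(merge_pools %in% units)) {
      stopf("merge_pools must name two pools present in the data")
    }
    merged_name <- paste(merge_pools, collapse = "+")
    keep_cols <- setdiff(units, merge_pools)
    pres_u <- cbind(present[, keep_cols, drop = FALSE],
                    present[, merge_pools[1L]] | present[, merge_pools[2L]])
    colnames(pres_u) <- c(keep_cols, merged_name)
    units <- colnames(pres_u)
  }
  sel <- which(eligible)
  n_present <- rowSums(pres_u[sel, , drop = FALSE])
  local <- n_present == 1L
  known <- annotation$known[idx[sel]]
  scope <- ifelse(local & !known, "global_specific",
                  ifelse(local, "local_specific", "shared"))
  focal <- rep(NA_character_, length(sel))
  if (any(local)) {
    focal[local] <- units[max.col(pres_u[sel, , drop = FALSE],
                                  ties.method = "first")[local]]
  }
  data.frame(chrom = counts$chrom[sel], pos = counts$pos[sel],
             scope = scope, focal_pop = focal, stringsAsFactors = FALSE)
}

#' Summaries of per-pool allele frequencies
#'
#' "Fixed" means the alternate allele accounts for every read in the raw
#' (pre-sub-sampling) counts, i.e. alternate count equals coverage.
#'
#' @param counts a [pool_counts] object (raw counts, for fixation).
#' @param freq optional matrix of estimated frequencies (positions x pools);
#'   defaults to raw `alt / coverage`.
#' @param calls optional result of [classify_population_specific], enabling
#'   per-scope mean frequencies.
#' @param breaks histogram breaks over [0,1] (default width 0.05).
#' @return A list with per-pool `pct_fixed`, `mean_freq`,
#'   `mean_freq_local_specific`, `mean_freq_global_specific` (NA when the
#'   subset is empty) and a per-pool frequency `histogram` (counts matrix).
#' @export
summarize_allele_frequencies <- function(counts, freq = NULL, calls = NULL,
                                         breaks = seq(0, 1, by = 0.05)) {
  ac <- allele_counts(counts)
  if (is.null(freq)) {
    freq <- ifelse(ac$coverage > 0, ac$alt / ac$coverage, NA_real_)
  }
  fixed <- ac$alt == ac$coverage & ac$coverage > 0
  pct_fixed <- 100 * colMeans(fixed)
  mean_freq <- colMeans(freq, na.rm = TRUE)
  subset_mean <- function(scope) {
    if (is.null(calls)) return(stats::setNames(rep(NA_real_, ncol(freq)),
                                               colnames(freq)))
    key <- paste(counts$chrom, counts$pos)
    ckey <- paste(calls$chrom, calls$pos)
    want <- if (scope == "local_specific") {
      calls$scope %in% c("local_specific", "global_specific")
    } else calls$scope == scope
    sel <- key %in% ckey[want]
    if (!any(sel)) return(stats::setNames(rep(NA_real_, ncol(freq)),
                                          colnames(freq)))
    colMeans(freq[sel, , drop = FALSE], na.rm = TRUE)
  }
  hist_m <- apply(freq, 2L, function(v) {
    v <- v[!is.na(v)]
    graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE,
                   include.lowest = TRUE)$counts
  })
  list(pct_fixed = pct_fixed,
       mean_freq = mean_freq,
       mean_freq_local_specific = subset_mean("local_specific"),
       mean_freq_global_specific = subset_mean("global_specific"),
       histogram = hist_m, breaks = breaks)
}

#' Transition/transversion ratio
#'
#' Transitions are the A<->G and C<->T substitutions; everything else is a
#' transversion.
#'
#' @param ref,alt character vectors of reference and alternate bases.
#' @return The Ts/Tv ratio, or `NA` when there are no transversions.
#' @export
transition_transversion_ratio <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  ts <- pair %in% c("AG", "CT")
  n_tv <- sum(!ts)
  if (n_tv == 0L) return(NA_real_)
  sum(ts) / n_tv
}

#' Gene-level SNP density distribution
#'
#' Density per gene is measured as bases per SNP (gene length divided by SNP
#' count) and binned into left-closed intervals `[0,bin_width)`,
#' `[bin_width, 2*bin_width)`, ...
#'
#' @param gene_map data.frame with columns `gene`, `start`, `end` (1-based
#'   inclusive).
#' @param snp_genes character vector: the gene id of each SNP (one entry per
#'   SNP; genes with no SNPs are excluded).
#' @param bin_width bin width in bp (default 100).
#' @return data.frame with columns `bin_lower`, `bin_upper`, `count`,
#'   `percent`.
#' @export
snp_density_distribution <- function(gene_map, snp_genes, bin_width = 100) {
  tab <- table(snp_genes)
  idx <- match(names(tab), gene_map$gene)
  if (anyNA(idx)) stopf("SNP assigned to unknown gene '%s'",
                        names(tab)[is.na(idx)][1L])
  len <- gene_map$end[idx] - gene_map$start[idx] + 1L
  if (any(len <= 0)) stopf("zero- or negative-length gene in gene map")
  density <- len / as.integer(tab)
  bin <- floor(density / bin_width)
  tb <- table(bin)
  lower <- as.integer(names(tb)) * bin_width
  data.frame(bin_lower = lower, bin_upper = lower + bin_width,
             count = as.integer(tb),
             percent = 100 * as.integer(tb) / length(density))
}

#' Assign SNPs to genes by coordinate overlap
#'
#' A SNP belongs to a gene iff `start <= pos <= end` on the same chromosome
#' (1-based inclusive intervals).
#'
#' @param counts a [pool_counts] object.
#' @param gene_map data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @return Character vector of gene ids (NA for intergenic SNPs), one per
#'   position.
#' @export
assign_genes <- function(counts, gene_map) {
  out <- rep(NA_character_, n_positions(counts))
  for (ch in unique(counts$chrom)) {
    gm <- gene_map[gene_map$chrom == ch, , drop = FALSE]
    if (nrow(gm) == 0L) next
    gm <- gm[order(gm$start), , drop = FALSE]
    sel <- which(counts$chrom == ch)
    pos <- counts$pos[sel]
    # intervals are non-overlapping in generated data, but handle overlap by
    # taking the first matching gene in map order
    idx <- findInterval(pos, gm$start)
    ok <- idx >= 1L & pos <= gm$end[pmax(idx, 1L)]
    out[sel[ok]] <- gm$gene[idx[ok]]
  }
  out
}
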