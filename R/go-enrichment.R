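#' GO term over-representation with Benjamini-Yekutieli FDR
#'
#' One-sided Fisher's exact (hypergeometric) over-representation test per
#' term, across all terms annotated to at least one universe gene, followed
#' by Benjamini-Yekutieli adjustment (valid under arbitrary dependence
#' between terms, as nested GO terms are strongly dependent). A term is
#' significant when both its raw p and its adjusted q are at most 0.05.
#'
#' @param study_genes character vector of study-set gene ids (must be a
#'   subset of the universe).
#' @param universe_genes character vector of background gene ids.
#' @param annotations ancestor-closed gene-to-GO data.frame (`gene`,
#'   `term`).
#' @param alpha significance level for both p and q (default 0.05).
#' @return data.frame with columns `term`, `k` (study hits), `n` (study
#'   size), `K` (universe hits), `N` (universe size), `p`, `q`,
#'   `significant`, sorted by p.
#' @export
go_enrich <- function(study_genes, universe_genes, annotations,
                      alpha = 0.05) {
  study_genes <- unique(study_genes)
  universe_genes <- unique(universe_genes)
  missing <- setdiff(study_genes, universe_genes)
  if (length(missing)) {
    stopf("study gene '%s' missing from universe", missing[1L])
  }
  ann <- annotations[annotations$gene %in% universe_genes, , drop = FALSE]
  terms <- sort(unique(ann$term))
  N <- length(universe_genes)
  n <- length(study_genes)
  rows <- lapply(terms, function(tm) {
    tg <- unique(ann$gene[ann$term == tm])
    K <- length(tg)
    k <- length(intersect(tg, study_genes))
    # one-sided over-representation tail: P(X >= k)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = min(1, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BY")
  out$significant <- out$p <= alpha & out$q <= alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
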