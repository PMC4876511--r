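#' Run the full pool-seq environmental-association pipeline
#'
#' Orchestrates the whole inference chain from one configuration: obtain
#' pooled allele counts (from the built-in generator or from files), apply
#' the variant-calling filters, remove the expression-driven coverage tail,
#' estimate allele frequencies by replicated sub-sampling, compute per-SNP
#' and gene-level pairwise FST with Fisher exact significance, classify
#' population-specific SNPs, build the genome-wide FST matrix and its
#' bootstrap consensus tree, prepare the climate table (growing-season
#' variables, correlation pruning, PCoA), screen highly variable genes with
#' partial Mantel tests against each retained factor, derive
#' simulation-based effect-size thresholds, apply the three-step stringency
#' filter, and test candidates for GO-term over-representation.
#'
#' @param config a nested list or the path to a YAML file. Recognised
#'   entries (with defaults): `simulate` (list of [sim_config] arguments;
#'   mutually exclusive with `inputs`), `inputs` (list with paths `sync`,
#'   `pool_names`, `gene_map`, `climate`, `go`, `annotation`), `pool_size`
#'   (haploid size used in FST corrections, 100), `min_maf` (0.05),
#'   `min_coverage` (20), `exclude_top_fraction` (0.02), `target_coverage`
#'   (10), `replicates` (50), `neglog10_threshold` (1.301), `n_perm`
#'   (1000), `threshold_quantile` (0.95), `p_max` (0.05), `required_term`,
#'   `tree_reps` (500), `merge_pools`, `seed` (1).
#' @param out_dir optional output directory; when given, all stage outputs
#'   (TSV tables, newick tree, JSON manifest) are written there.
#' @param quiet suppress stage-boundary messages.
#' @return A list with every stage result: `data`, `counts_filtered`,
#'   `subsample`, `snp_genes`, `components`, `gene_fst`, `hv_genes`,
#'   `fst_hist`, `overall_fst`, `tree`, `patterns`, `climate`, `pruning`,
#'   `pcoa`, `thresholds`, `mantel`, `filtered` (three-step table),
#'   `candidates`, `enrichment`, `funnel` (record counts per stage) and
#'   `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    pool_size = 100, min_maf = 0.05, min_coverage = 20,
    exclude_top_fraction = 0.02, target_coverage = 10, replicates = 50,
    neglog10_threshold = 1.301, n_perm = 1000, threshold_quantile = 0.95,
    p_max = 0.05, required_term = "response to abiotic stimulus",
    tree_reps = 500, merge_pools = NULL, seed = 1L
  ), config)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  seed <- as.integer(cfg$seed)

  # --- data -----------------------------------------------------------
  if (!is.null(cfg$inputs)) {
    ins <- cfg$inputs
    for (f in c("sync", "gene_map", "climate", "go", "annotation")) {
      if (!is.null(ins[[f]]) && !file.exists(ins[[f]])) {
        stopf("input file '%s' does not exist", ins[[f]])
      }
    }
    counts <- read_sync(ins$sync, ins$pool_names)
    gene_map <- utils::read.table(ins$gene_map, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    climate <- read_climate_table(ins$climate)
    go <- utils::read.table(ins$go, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    annotation <- utils::read.table(ins$annotation, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    data <- list(counts = counts, gene_map = gene_map, climate = climate,
                 go = go, annotation = annotation, truth = NULL)
  } else {
    sim_args <- cfg$simulate %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sc <- do.call(sim_config, sim_args)
    ds <- generate_dataset(sc)
    data <- list(counts = ds$counts, gene_map = ds$gene_map,
                 climate = ds$climate, go = ds$go,
                 annotation = ds$truth$snps[c("chrom", "pos", "gene",
                                              "effect_class", "known")],
                 truth = ds$truth, dataset = ds)
  }
  say("data", "%d positions x %d pools", n_positions(data$counts),
      length(data$counts$pools))
  funnel <- list(positions_in = n_positions(data$counts))

  # --- variant filters ------------------------------------------------
  filt <- filter_variants(data$counts, cfg$min_maf, cfg$min_coverage)
  say("filter", "%d positions retained (%d dropped)", n_positions(filt),
      attr(filt, "n_dropped"))
  filt <- exclude_high_expression_positions(filt, cfg$exclude_top_fraction)
  say("coverage-tail", "%d positions retained (%d dropped)",
      n_positions(filt), attr(filt, "n_dropped"))
  funnel$positions_filtered <- n_positions(filt)

  # --- frequencies ----------------------------------------------------
  sub <- subsample_frequencies(filt, cfg$target_coverage, cfg$replicates,
                               seed = substream_seed(seed, 11L))
  say("subsample", "%d positions at target coverage %d (%d dropped)",
      n_positions(sub$counts), cfg$target_coverage, sub$n_dropped)
  snp_genes <- assign_genes(sub$counts, data$gene_map)
  funnel$positions_subsampled <- n_positions(sub$counts)

  # --- FST ------------------------------------------------------------
  comp <- pairwise_fst_components(sub$freq, cfg$target_coverage,
                                  cfg$pool_size)
  gene_tab <- gene_fst_table(comp, snp_genes, sub$alt_sub,
                             cfg$target_coverage, cfg$neglog10_threshold)
  hv <- highly_variable_genes(gene_tab)
  say("fst", "%d genes, %d highly variable",
      length(unique(gene_tab$gene)), length(hv))
  fst_hist <- fst_histogram(gene_tab$fst)
  dmat_s <- overall_fst(comp)
  funnel$genes_with_snps <- length(unique(gene_tab$gene))
  funnel$highly_variable_genes <- length(hv)

  # --- tree -----------------------------------------------------------
  tree <- bootstrap_consensus(comp, n_reps = cfg$tree_reps,
                              seed = substream_seed(seed, 12L))
  say("tree", "consensus over %d replicates", cfg$tree_reps)

  # --- SNP patterns ---------------------------------------------------
  ac <- allele_counts(sub$counts)
  calls <- classify_population_specific(sub$counts, data$annotation,
                                        merge_pools = cfg$merge_pools)
  freq_summary <- summarize_allele_frequencies(sub$counts, freq = sub$freq,
                                               calls = calls)
  tstv <- transition_transversion_ratio(sub$counts$ref, ac$alt_base)
  density <- snp_density_distribution(data$gene_map,
                                      snp_genes[!is.na(snp_genes)])
  patterns <- list(calls = calls, freq_summary = freq_summary, tstv = tstv,
                   density = density)
  say("patterns", "Ts/Tv %.3f; %d pop-specific SNPs", tstv,
      sum(calls$scope != "shared"))

  # --- climate --------------------------------------------------------
  climate <- data$climate
  if (!"MRGS" %in% names(climate) && "gs_months" %in% names(climate)) {
    climate <- derive_growing_season_variables(climate)
  }
  auto_vars <- setdiff(names(climate),
                       c("site", "altitude", "gs_months",
                         grep("^(temp|prec|rad)_[0-9]{2}$", names(climate),
                              value = TRUE)))
  # growing-season factors are scanned first so they survive pruning in
  # favour of their annual analogues
  pref <- intersect(c("TS", "TAR", "RS", "MRGS", "MPGS"), auto_vars)
  pruning <- prune_correlated_variables(climate,
                                        vars = c(pref,
                                                 setdiff(auto_vars, pref)))
  say("climate", "factors kept: %s (flagged near-constant: %s)",
      paste(pruning$kept, collapse = ", "),
      paste(pruning$flagged, collapse = ", "))
  if (length(pruning$kept) == 0L) stopf("no climate factors survive pruning")
  zvars <- scale(as.matrix(climate[pruning$kept]))
  pco <- pcoa(as.matrix(stats::dist(zvars)))

  # --- association ----------------------------------------------------
  dy_list <- stats::setNames(lapply(pruning$kept, env_distance,
                                    climate = climate), pruning$kept)
  hv_idx <- gene_tab$gene %in% hv
  gm <- gene_tab[hv_idx, , drop = FALSE]
  gene_mat <- matrix(NA_real_, length(hv), length(comp$pairs),
                     dimnames = list(hv, comp$pairs))
  gene_mat[cbind(match(gm$gene, hv), match(gm$pair, comp$pairs))] <- gm$fst
  thresholds <- simulate_threshold(dy_list, dmat_s, n_sim = max(length(hv), 1L),
                                   quantile = cfg$threshold_quantile,
                                   seed = substream_seed(seed, 13L))
  mantel <- partial_mantel_screen(gene_mat, dy_list, dmat_s,
                                  n_perm = cfg$n_perm,
                                  seed = substream_seed(seed, 14L))
  filtered <- three_step_filter(mantel, thresholds, data$go,
                                required_term = cfg$required_term,
                                p_max = cfg$p_max)
  candidates <- filtered[filtered$candidate, , drop = FALSE]
  say("associate", "%d candidate gene-factor pairs (%d unique genes)",
      nrow(candidates), length(unique(candidates$gene)))
  funnel$candidates <- length(unique(candidates$gene))

  # --- enrichment -----------------------------------------------------
  universe <- sort(unique(snp_genes[!is.na(snp_genes)]))
  enrichment <- if (nrow(candidates) > 0L) {
    go_enrich(unique(candidates$gene), universe, data$go)
  } else {
    NULL
  }

  res <- list(data = data, counts_filtered = filt, subsample = sub,
              snp_genes = snp_genes, components = comp,
              gene_fst = gene_tab, hv_genes = hv, fst_hist = fst_hist,
              overall_fst = dmat_s, tree = tree, patterns = patterns,
              climate = climate, pruning = pruning, pcoa = pco,
              thresholds = thresholds, mantel = mantel,
              filtered = filtered, candidates = candidates,
              enrichment = enrichment, funnel = funnel, config = cfg)

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$gene_fst, "gene_fst.tsv")
  wt(res$fst_hist, "fst_histogram.tsv")
  m <- res$overall_fst
  wt(data.frame(pool = rownames(m), as.data.frame(m), check.names = FALSE),
     "overall_fst.tsv")
  wt(res$thresholds, "thresholds.tsv")
  wt(res$mantel, "mantel.tsv")
  wt(res$filtered, "three_step_filter.tsv")
  wt(res$candidates, "candidates.tsv")
  if (!is.null(res$enrichment)) wt(res$enrichment, "enrichment.tsv")
  wt(res$patterns$calls, "pop_specific.tsv")
  wt(res$patterns$density, "snp_density.tsv")
  co <- res$pcoa$coords
  wt(data.frame(site = rownames(co), as.data.frame(co), check.names = FALSE),
     "pcoa.tsv")
  write_newick(res$tree$consensus, file.path(out_dir, "consensus.nwk"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("altigrad")),
    r_version = as.character(getRversion()),
    parameters = res$config[setdiff(names(res$config),
                                    c("inputs", "simulate"))],
    funnel = res$funnel
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
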