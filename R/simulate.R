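#' Simulation configuration
#'
#' Parameters of the synthetic pool-seq generator. Defaults emulate the study
#' design the package targets: four population pools of 100 diploids each
#' (ploidy 200) sampled along an altitudinal gradient, tree-structured drift
#' with one near-identical pool pair and one distal pool, overdispersed
#' per-gene coverage with a heavy upper tail (expression variation), a subset
#' of genes whose allele-frequency differentiation tracks one climate
#' variable through a logistic link, population-private low-frequency
#' variants, and per-SNP effect-class / known-variant labels.
#'
#' @param n_pops number of population pools (>= 4).
#' @param pool_size diploid individuals per pool (haploid pool size is
#'   `2 * pool_size`).
#' @param n_genes number of genes.
#' @param snps_per_gene mean SNP count per gene (Poisson, floored at 1).
#' @param gene_length_bp mean gene length in bp (Gamma distributed).
#' @param coverage_mean,coverage_dispersion negative-binomial mean and size
#'   of per-SNP, per-pool read coverage (mean scaled per gene by an
#'   expression factor).
#' @param heavy_tail_fraction fraction of genes with strongly inflated
#'   coverage, emulating highly expressed transcripts.
#' @param drift_tree rooted drift tree: an [ape::phylo] object or newick
#'   string whose branch lengths are Balding-Nichols F parameters in (0,1)
#'   and whose tips name the pools. `NULL` uses a default n-pool tree with a
#'   near-identical terminal pair and a distal first pool.
#' @param altitudes site altitudes in metres, one per pool. Default
#'   700/2000/2600/3400 m for 4 pools, evenly spaced in that range otherwise.
#' @param env_gradient per-site values of the driving climate variable;
#'   `NULL` derives it from the generated climate table (growing-season
#'   radiation).
#' @param n_associated_genes number of genes whose frequencies track the
#'   gradient.
#' @param effect_size slope b of the logistic frequency-environment link
#'   `p = plogis(a + b * z)`, z the standardized driving variable.
#' @param frac_pop_specific fraction of (non-associated) SNPs private to one
#'   pool.
#' @param frac_known fraction of SNPs flagged as present in the reference
#'   variant catalogue.
#' @param effect_class_probs named probabilities over the effect classes
#'   `synonymous`, `nonsyn_deleterious`, `nonsyn_nondeleterious`, `none`.
#' @param seed root RNG seed; per-gene sub-streams are derived from it so
#'   changing `n_genes` does not reshuffle earlier genes.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 4L,
                       pool_size = 100L,
                       n_genes = 500L,
                       snps_per_gene = 3,
                       gene_length_bp = 1350,
                       coverage_mean = 80,
                       coverage_dispersion = 5,
                       heavy_tail_fraction = 0.02,
                       drift_tree = NULL,
                       altitudes = NULL,
                       env_gradient = NULL,
                       n_associated_genes = 25L,
                       effect_size = 3,
                       frac_pop_specific = 0.08,
                       frac_known = 0.85,
                       effect_class_probs = c(synonymous = 0.45,
                                              nonsyn_deleterious = 0.07,
                                              nonsyn_nondeleterious = 0.38,
                                              none = 0.10),
                       seed = 1L) {
  if (n_pops < 4L) stopf("n_pops must be >= 4")
  if (pool_size < 2L) stopf("pool_size must be >= 2")
  if (n_associated_genes > n_genes) {
    stopf("configuration error: n_associated_genes (%d) > n_genes (%d)",
          n_associated_genes, n_genes)
  }
  if (heavy_tail_fraction < 0 || heavy_tail_fraction > 1 ||
      frac_pop_specific < 0 || frac_pop_specific > 1 ||
      frac_known < 0 || frac_known > 1) {
    stopf("fractions must lie in [0,1]")
  }
  req <- c("synonymous", "nonsyn_deleterious", "nonsyn_nondeleterious", "none")
  if (!setequal(names(effect_class_probs), req)) {
    stopf("effect_class_probs must be named %s", paste(req, collapse = ", "))
  }
  effect_class_probs <- effect_class_probs[req]
  if (any(effect_class_probs < 0) || abs(sum(effect_class_probs) - 1) > 1e-8) {
    stopf("effect_class_probs must be non-negative and sum to 1")
  }
  if (is.null(altitudes)) {
    altitudes <- if (n_pops == 4L) c(700, 2000, 2600, 3400) else
      round(seq(700, 3400, length.out = n_pops))
  }
  if (length(altitudes) != n_pops) stopf("altitudes must have one value per pool")
  if (is.character(drift_tree)) drift_tree <- ape::read.tree(text = drift_tree)
  if (is.null(drift_tree)) drift_tree <- default_drift_tree(n_pops)
  if (!inherits(drift_tree, "phylo")) stopf("drift_tree must be phylo or newick")
  if (length(drift_tree$tip.label) != n_pops) {
    stopf("drift_tree must have exactly n_pops leaves")
  }
  if (any(drift_tree$edge.length <= 0) || any(drift_tree$edge.length >= 1)) {
    stopf("drift_tree branch F parameters must lie in (0,1)")
  }
  if (!is.null(env_gradient)) {
    if (length(env_gradient) != n_pops) {
      stopf("env_gradient must have one value per pool")
    }
    if (n_associated_genes > 0L && stats::sd(env_gradient) == 0) {
      stopf("configuration error: degenerate (constant) env_gradient with associated genes")
    }
  }
  structure(
    list(n_pops = as.integer(n_pops), pool_size = as.integer(pool_size),
         n_genes = as.integer(n_genes), snps_per_gene = snps_per_gene,
         gene_length_bp = gene_length_bp, coverage_mean = coverage_mean,
         coverage_dispersion = coverage_dispersion,
         heavy_tail_fraction = heavy_tail_fraction,
         drift_tree = drift_tree, altitudes = as.numeric(altitudes),
         env_gradient = env_gradient,
         n_associated_genes = as.integer(n_associated_genes),
         effect_size = effect_size,
         frac_pop_specific = frac_pop_specific, frac_known = frac_known,
         effect_class_probs = effect_class_probs, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default drift tree for n pools
#'
#' Pools P3 and P4 form a near-identical terminal pair (small F), P1 is the
#' most distal pool and P2 intermediate, mirroring a lowland-to-highland
#' colonisation history. Additional pools attach to the backbone with
#' moderate F.
#'
#' @param n_pops number of pools.
#' @return An [ape::phylo] tree with branch lengths as F parameters.
#' @export
default_drift_tree <- function(n_pops = 4L) {
  if (n_pops < 4L) stopf("n_pops must be >= 4")
  extras <- ""
  if (n_pops > 4L) {
    lab <- paste0("P", 5:n_pops)
    extras <- paste0(",", paste0(lab, ":", seq(0.03, 0.08,
                                               length.out = n_pops - 4L),
                                 collapse = ","))
  }
  txt <- sprintf("((P1:0.10,P2:0.06):0.02,(P3:0.005,P4:0.005):0.06%s);", extras)
  ape::read.tree(text = txt)
}

# Balding-Nichols drift of a vector of ancestral frequencies along one branch
# with parameter F: child ~ Beta(p(1-F)/F, (1-p)(1-F)/F), mean p, variance
# F p (1-p). Frequencies 0 and 1 are absorbing.
bn_step <- function(p, F) {
  out <- p
  seg <- p > 0 & p < 1
  if (any(seg)) {
    k <- (1 - F) / F
    out[seg] <- stats::rbeta(sum(seg), p[seg] * k, (1 - p[seg]) * k)
  }
  out
}

# Evolve ancestral frequencies down the drift tree; returns a matrix
# n_snps x n_tips with columns in tip.label order.
bn_evolve <- function(p0, tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  freq <- vector("list", n_node)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  freq[[root]] <- p0
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- tree$edge.length[match(paste(ord[, 1], ord[, 2]),
                               paste(tree$edge[, 1], tree$edge[, 2]))]
  for (e in seq_len(nrow(ord))) {
    freq[[ord[e, 2L]]] <- bn_step(freq[[ord[e, 1L]]], el[e])
  }
  out <- do.call(cbind, freq[seq_len(n_tip)])
  colnames(out) <- tree$tip.label
  out
}

#' Generate a synthetic site climate table
#'
#' Emulates interpolated bio-climatic layers for sites along an altitudinal
#' gradient: monthly temperature (lapse-rate decrease with altitude,
#' site-specific seasonal amplitude), monthly precipitation (monsoon peak,
#' site-specific wetness), monthly radiation (strictly increasing with
#' altitude), a three-month growing season that starts later at higher
#' altitude, and derived annual variables. By construction the table contains
#' at least one highly correlated variable pair (TS/TAR), one near-constant
#' variable (RS, radiation seasonality) and one altitude-monotone
#' radiation-like variable (RAD_ANN).
#'
#' @param site_spec data.frame with columns `site` and `altitude` (m), or a
#'   numeric altitude vector (sites are then named S1..Sn).
#' @param seed RNG seed.
#' @return Climate `data.frame` (see [read_climate_table]).
#' @export
generate_climate_table <- function(site_spec, seed = 1L) {
  if (is.numeric(site_spec)) {
    site_spec <- data.frame(site = paste0("S", seq_along(site_spec)),
                            altitude = site_spec)
  }
  if (nrow(site_spec) < 2L) stopf("need at least 2 sites")
  with_seed(seed, {
    n <- nrow(site_spec)
    alt <- site_spec$altitude
    m <- 1:12
    temp <- prec <- rad <- matrix(0, n, 12)
    amp_t <- 7 + stats::rnorm(n, 0, 1.2)          # seasonal temp amplitude
    wet <- stats::runif(n, 0.5, 1.6)              # site wetness factor
    rad_level <- 12 + 0.0025 * alt                # strictly altitude-monotone
    for (i in seq_len(n)) {
      temp[i, ] <- 26 - 0.006 * alt[i] +
        amp_t[i] * sin(2 * pi * (m - 4.5) / 12) + stats::rnorm(12, 0, 0.3)
      prec[i, ] <- pmax(5, wet[i] * (60 + 140 * exp(-(m - 7.5)^2 / 14)) +
                          stats::rnorm(12, 0, 5))
      rad[i, ] <- rad_level[i] * (1 + 0.29 * sin(2 * pi * (m - 5.5) / 12)) +
        stats::rnorm(12, 0, 0.05)
    }
    gs_start <- pmin(9L, 3L + as.integer(round(alt / 1000)))
    gs <- vapply(gs_start, function(s) paste(s:(s + 2L), collapse = ","), "")
    df <- data.frame(
      site = site_spec$site,
      altitude = alt,
      TS = apply(temp, 1, stats::sd) * 100,
      TAR = apply(temp, 1, max) - apply(temp, 1, min),
      RS = apply(rad, 1, stats::sd) / rowMeans(rad),
      MAT = rowMeans(temp),
      AP = rowSums(prec),
      RAD_ANN = rowMeans(rad),
      stringsAsFactors = FALSE
    )
    tm <- as.data.frame(temp); names(tm) <- sprintf("temp_%02d", m)
    pm <- as.data.frame(prec); names(pm) <- sprintf("prec_%02d", m)
    rm_ <- as.data.frame(rad); names(rm_) <- sprintf("rad_%02d", m)
    df <- cbind(df, tm, pm, rm_)
    df$gs_months <- gs
    validate_climate_table(df)
  })
}

#' Generate gene-to-GO annotations with planted signal
#'
#' Associated genes (per the truth table) receive the term
#' `response to radiation` with probability `p_assoc`; background genes
#' receive abiotic-stress terms at lower rates. The output is ancestor-closed
#' over a small internal term hierarchy
#' (`response to radiation` < `response to abiotic stimulus` <
#' `response to stimulus`; `response to water` < `response to abiotic
#' stimulus`; `pigment metabolic process` < `metabolic process`).
#'
#' @param gene_ids character vector of all gene ids.
#' @param truth truth table (see [generate_dataset]) or `NULL` for no
#'   planted signal.
#' @param seed RNG seed.
#' @param p_assoc probability an associated gene is annotated with
#'   `response to radiation`.
#' @param p_background_stress probability a background gene carries
#'   `response to abiotic stimulus`.
#' @param p_background_radiation probability a background gene carries
#'   `response to radiation`.
#' @return data.frame with columns `gene`, `term`, ancestor-closed.
#' @export
generate_go_annotations <- function(gene_ids, truth = NULL, seed = 1L,
                                    p_assoc = 0.9,
                                    p_background_stress = 0.15,
                                    p_background_radiation = 0.03) {
  assoc <- character()
  if (!is.null(truth)) {
    assoc <- truth$genes$gene[truth$genes$associated]
  }
  with_seed(seed, {
    rows <- list()
    add <- function(gene, term) rows[[length(rows) + 1L]] <<- c(gene, term)
    for (g in gene_ids) {
      if (g %in% assoc) {
        if (stats::runif(1) < p_assoc) add(g, "response to radiation")
      } else {
        if (stats::runif(1) < p_background_radiation) {
          add(g, "response to radiation")
        } else if (stats::runif(1) < p_background_stress) {
          add(g, if (stats::runif(1) < 0.5) "response to water"
              else "response to abiotic stimulus")
        }
      }
      if (stats::runif(1) < 0.35) add(g, "metabolic process")
      if (stats::runif(1) < 0.10) add(g, "pigment metabolic process")
    }
    df <- if (length(rows)) {
      data.frame(gene = vapply(rows, `[`, "", 1L),
                 term = vapply(rows, `[`, "", 2L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(), term = character(),
                 stringsAsFactors = FALSE)
    }
    close_ancestors(df)
  })
}

# Internal mini-hierarchy: term -> direct parent.
go_parents <- function() {
  c("response to radiation" = "response to abiotic stimulus",
    "response to water" = "response to abiotic stimulus",
    "response to abiotic stimulus" = "response to stimulus",
    "pigment metabolic process" = "metabolic process")
}

#' Close a gene-to-GO table over term ancestors
#' @param annotations data.frame with columns `gene`, `term`.
#' @param parents named character vector mapping term -> parent term.
#' @return The ancestor-closed annotation data.frame (unique rows).
#' @export
close_ancestors <- function(annotations, parents = go_parents()) {
  df <- unique(annotations[c("gene", "term")])
  repeat {
    par <- parents[df$term]
    extra <- data.frame(gene = df$gene[!is.na(par)],
                        term = unname(par[!is.na(par)]),
                        stringsAsFactors = FALSE)
    new <- unique(rbind(df, extra))
    if (nrow(new) == nrow(df)) break
    df <- new
  }
  df[order(df$gene, df$term), , drop = FALSE]
}

#' Generate a complete synthetic pool-seq dataset with planted truth
#'
#' Draws an ancestral alternate frequency per SNP from the mixture
#' `0.5 Beta(20,1) + 0.5 Beta(1,1)` (a high-fixation regime plus a uniform
#' background), evolves it along the drift tree by Balding-Nichols steps,
#' replaces frequencies of associated genes by the logistic
#' frequency-environment link, plants population-private SNPs with true
#' frequency zero outside their focal pool, and draws read counts as
#' binomial(coverage, frequency) with negative-binomial coverage per
#' SNP x pool (gene-level expression factors, heavy-tailed for a configurable
#' fraction of genes). Transition substitutions are drawn at a rate matching
#' a transition/transversion ratio of about 1.37.
#'
#' @param config a [sim_config] object.
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `counts` ([pool_counts]), `gene_map` (gene, chrom, start, end; 1-based
#'   inclusive), `climate` (climate table incl. growing-season variables),
#'   `go` (gene-to-GO data.frame), `truth` (list with per-gene and per-SNP
#'   truth and the true frequency matrix), `z` (standardized driving
#'   variable) and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  pools <- config$drift_tree$tip.label
  n_pops <- config$n_pops
  climate <- generate_climate_table(
    data.frame(site = pools, altitude = config$altitudes),
    seed = substream_seed(config$seed, 0L)
  )
  climate <- derive_growing_season_variables(climate)
  gradient <- config$env_gradient %||% climate$MRGS
  if (config$n_associated_genes > 0L && stats::sd(gradient) == 0) {
    stopf("configuration error: degenerate (constant) climate gradient")
  }
  z <- as.numeric(scale(gradient))
  if (any(!is.finite(z))) z <- rep(0, n_pops)

  assoc_idx <- integer()
  if (config$n_associated_genes > 0L) {
    assoc_idx <- unique(round(seq(1L, config$n_genes,
                                  length.out = config$n_associated_genes)))
  }
  classes <- names(config$effect_class_probs)

  gene_rows <- vector("list", config$n_genes)
  snp_rows <- vector("list", config$n_genes)
  freq_rows <- vector("list", config$n_genes)
  cnt_rows <- vector("list", config$n_genes)
  offset <- 1L
  for (g in seq_len(config$n_genes)) {
    res <- with_seed(substream_seed(config$seed, g), {
      L <- max(200L, as.integer(round(stats::rgamma(1, shape = 4,
                                                    scale = config$gene_length_bp / 4))))
      n_snp <- max(1L, stats::rpois(1, config$snps_per_gene))
      n_snp <- min(n_snp, L)
      rel_pos <- sort(sample.int(L, n_snp))
      heavy <- stats::runif(1) < config$heavy_tail_fraction
      expr_factor <- if (heavy) stats::runif(1, 5, 12) else
        stats::rlnorm(1, 0, 0.5)
      associated <- g %in% assoc_idx

      freq <- matrix(0, n_snp, n_pops)
      pop_specific <- rep(FALSE, n_snp)
      focal <- rep(NA_character_, n_snp)
      if (associated) {
        a <- stats::rnorm(n_snp, 0, 0.7)
        freq <- stats::plogis(outer(a, config$effect_size * z, `+`))
      } else {
        pop_specific <- stats::runif(n_snp) < config$frac_pop_specific
        n_bg <- sum(!pop_specific)
        if (n_bg > 0L) {
          comp <- stats::runif(n_bg) < 0.5
          p0 <- ifelse(comp, stats::rbeta(n_bg, 20, 1), stats::runif(n_bg))
          freq[!pop_specific, ] <- bn_evolve(p0, config$drift_tree)[,
            pools, drop = FALSE]
        }
        if (any(pop_specific)) {
          fp <- sample.int(n_pops, sum(pop_specific), replace = TRUE)
          freq[cbind(which(pop_specific), fp)] <- stats::rbeta(sum(pop_specific), 2, 2)
          focal[pop_specific] <- pools[fp]
        }
      }

      cov <- matrix(stats::rnbinom(n_snp * n_pops,
                                   size = config$coverage_dispersion,
                                   mu = expr_factor * config$coverage_mean),
                    n_snp, n_pops)
      alt_reads <- matrix(stats::rbinom(n_snp * n_pops, as.vector(cov),
                                        as.vector(freq)), n_snp, n_pops)

      # substitution type: transitions at the rate giving Ts/Tv ~ 1.37
      is_ts <- stats::runif(n_snp) < 1.37 / 2.37
      ts_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                         ncol = 2, byrow = TRUE)
      tv_pairs <- matrix(c("A", "C", "A", "T", "C", "A", "C", "G",
                           "G", "C", "G", "T", "T", "A", "T", "G"),
                         ncol = 2, byrow = TRUE)
      pick_ts <- sample.int(4L, n_snp, replace = TRUE)
      pick_tv <- sample.int(8L, n_snp, replace = TRUE)
      ref_b <- ifelse(is_ts, ts_pairs[pick_ts, 1L], tv_pairs[pick_tv, 1L])
      alt_b <- ifelse(is_ts, ts_pairs[pick_ts, 2L], tv_pairs[pick_tv, 2L])

      effect <- sample(classes, n_snp, replace = TRUE,
                       prob = config$effect_class_probs)
      known <- stats::runif(n_snp) < config$frac_known

      list(L = L, n_snp = n_snp, rel_pos = rel_pos, heavy = heavy,
           associated = associated, freq = freq, cov = cov,
           alt_reads = alt_reads, ref_b = ref_b, alt_b = alt_b,
           effect = effect, known = known, pop_specific = pop_specific,
           focal = focal)
    })
    gid <- sprintf("g%05d", g)
    gene_rows[[g]] <- data.frame(
      gene = gid, chrom = "chr1", start = offset,
      end = offset + res$L - 1L, associated = res$associated,
      heavy_tail = res$heavy,
      slope = if (res$associated) config$effect_size else 0,
      stringsAsFactors = FALSE
    )
    snp_rows[[g]] <- data.frame(
      chrom = "chr1", pos = offset + res$rel_pos - 1L, gene = gid,
      ref = res$ref_b, alt = res$alt_b, effect_class = res$effect,
      known = res$known, pop_specific = res$pop_specific,
      focal_pop = res$focal, stringsAsFactors = FALSE
    )
    freq_rows[[g]] <- res$freq
    cnt_rows[[g]] <- list(cov = res$cov, alt = res$alt_reads)
    offset <- offset + res$L + 100L
  }

  gene_map <- do.call(rbind, gene_rows)
  snps <- do.call(rbind, snp_rows)
  true_freq <- do.call(rbind, freq_rows)
  colnames(true_freq) <- pools
  cov <- do.call(rbind, lapply(cnt_rows, `[[`, "cov"))
  alt <- do.call(rbind, lapply(cnt_rows, `[[`, "alt"))
  n <- nrow(snps)
  counts <- array(0L, c(n, n_pops, 6L))
  ref_i <- match(snps$ref, SYNC_COLS)
  alt_i <- match(snps$alt, SYNC_COLS)
  for (p in seq_len(n_pops)) {
    counts[cbind(seq_len(n), p, ref_i)] <- cov[, p] - alt[, p]
    counts[cbind(seq_len(n), p, alt_i)] <- alt[, p]
  }
  pc <- pool_counts(snps$chrom, snps$pos, snps$ref, counts, pools)

  truth <- list(
    genes = gene_map[c("gene", "associated", "slope")],
    snps = snps,
    freq = true_freq,
    driving_variable = if (is.null(config$env_gradient)) "MRGS" else "custom"
  )
  truth$genes$factor <- ifelse(truth$genes$associated,
                               truth$driving_variable, NA_character_)
  go <- generate_go_annotations(gene_map$gene, truth,
                                seed = substream_seed(config$seed, -1L))
  structure(
    list(counts = pc,
         gene_map = gene_map[c("gene", "chrom", "start", "end")],
         climate = climate, go = go, truth = truth, z = z,
         pools = pools, config = config),
    class = "synthetic_dataset"
  )
}

#' @method print synthetic_dataset
#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d SNPs in %d genes x %d pools (%d associated genes)\n",
    n_positions(x$counts), nrow(x$gene_map), length(x$pools),
    sum(x$truth$genes$associated)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `counts.sync`, `genes.tsv`, `climate.tsv`, `go.tsv`,
#' `truth_genes.tsv` and `truth_snps.tsv`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sync(dataset$counts, file.path(dir, "counts.sync"))
  utils::write.table(dataset$gene_map, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_climate_table(dataset$climate, file.path(dir, "climate.tsv"))
  utils::write.table(dataset$go, file.path(dir, "go.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cbind(dataset$truth$snps,
              stats::setNames(as.data.frame(dataset$truth$freq),
                              paste0("freq_", colnames(dataset$truth$freq))))
  utils::write.table(tr, file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
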