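#' Derive growing-season climate variables
#'
#' Adds `MTGS`, `MPGS` and `MRGS` (mean temperature, precipitation and
#' radiation of each site's growing season) as arithmetic means of the
#' monthly series over the months listed in `gs_months`.
#'
#' @param climate climate `data.frame` with monthly columns
#'   `temp_01..temp_12`, `prec_01..prec_12`, `rad_01..rad_12` and a
#'   `gs_months` column.
#' @return The climate table with the three columns appended (replaced when
#'   already present).
#' @export
derive_growing_season_variables <- function(climate) {
  gm <- gs_month_list(climate)
  if (any(vapply(gm, length, 0L) == 0L)) {
    stopf("site without growing-season months")
  }
  series_mean <- function(prefix) {
    cols <- sprintf("%s_%02d", prefix, 1:12)
    if (!all(cols %in% names(climate))) {
      stopf("missing monthly columns '%s_*'", prefix)
    }
    m <- as.matrix(climate[cols])
    vapply(seq_len(nrow(climate)), function(i) mean(m[i, gm[[i]]]), 0)
  }
  climate$MTGS <- series_mean("temp")
  climate$MPGS <- series_mean("prec")
  climate$MRGS <- series_mean("rad")
  climate
}

#' Prune highly correlated bio-climatic variables
#'
#' Greedy scan in input column order: a variable is dropped when its
#' absolute Pearson correlation with any already-kept variable reaches
#' `r_threshold`. Near-constant variables, whose range relative to their
#' mean magnitude falls below `rel_range_epsilon`, are flagged as
#' uninformative and excluded from the kept set (the radiation-seasonality
#' rule: a variable varying only in the second decimal across sites carries
#' no usable contrast).
#'
#' @param climate climate `data.frame`.
#' @param vars variables to consider, in scan order. Default: every numeric
#'   column except `altitude`, the monthly series and `gs_months`.
#' @param r_threshold absolute correlation threshold (default 0.8,
#'   inclusive).
#' @param rel_range_epsilon relative-range threshold for the near-constant
#'   flag (default 0.2).
#' @return List with `kept` (character), `dropped` (data.frame `variable`,
#'   `correlated_with`, `r`) and `flagged` (near-constant variables).
#' @export
prune_correlated_variables <- function(climate, vars = NULL,
                                       r_threshold = 0.8,
                                       rel_range_epsilon = 0.2) {
  if (nrow(climate) < 3L) {
    stopf("need at least 3 sites for correlation pruning")
  }
  if (is.null(vars)) {
    vars <- setdiff(names(climate),
                    c("site", "altitude", "gs_months",
                      grep("^(temp|prec|rad)_[0-9]{2}$", names(climate),
                           value = TRUE)))
  }
  for (v in vars) {
    if (!is.numeric(climate[[v]])) stopf("variable '%s' is not numeric", v)
    if (anyNA(climate[[v]])) stopf("variable '%s' has missing values", v)
  }
  rel_range <- vapply(vars, function(v) {
    x <- climate[[v]]
    mu <- mean(abs(x))
    if (mu == 0) 0 else (max(x) - min(x)) / mu
  }, 0)
  flagged <- vars[rel_range < rel_range_epsilon]
  kept <- character()
  dropped <- data.frame(variable = character(), correlated_with = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  for (v in setdiff(vars, flagged)) {
    if (stats::sd(climate[[v]]) == 0) { flagged <- c(flagged, v); next }
    rs <- vapply(kept, function(k) stats::cor(climate[[v]], climate[[k]]), 0)
    hit <- which(abs(rs) >= r_threshold)
    if (length(hit)) {
      dropped <- rbind(dropped, data.frame(
        variable = v, correlated_with = kept[hit[1L]], r = rs[hit[1L]],
        stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, v)
    }
  }
  list(kept = kept, dropped = dropped, flagged = flagged)
}

#' Principal co-ordinate analysis (classical MDS)
#'
#' Gower double-centring of the squared distance matrix followed by
#' eigendecomposition; co-ordinates are eigenvectors scaled by the square
#' root of the positive eigenvalues, sorted descending.
#'
#' @param d symmetric distance matrix.
#' @return List with `coords` (sites x axes) and `eigenvalues` (all of
#'   them, descending).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix must be symmetric")
  if (all(d == 0)) {
    return(list(coords = matrix(0, n, 1L,
                                dimnames = list(rownames(d), "PCo1")),
                eigenvalues = rep(0, n)))
  }
  # cmdscale warns when fewer than k eigenvalues are positive; expected for
  # low-rank configurations, and the full eigenvalue vector is returned anyway
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  coords <- mds$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coords = coords, eigenvalues = mds$eig)
}

#' Environmental distance matrix for one factor
#'
#' `D[i, j] = |y_i - y_j|` on the raw (unstandardised) factor values.
#'
#' @param climate climate `data.frame`.
#' @param factor name of the factor column.
#' @return Symmetric matrix labelled by site.
#' @export
env_distance <- function(climate, factor) {
  if (!factor %in% names(climate)) stopf("factor '%s' not in climate table", factor)
  y <- climate[[factor]]
  if (anyNA(y)) stopf("factor '%s' has missing values", factor)
  m <- abs(outer(y, y, `-`))
  dimnames(m) <- list(climate$site, climate$site)
  m
}

# pair-index matrix: K[i,j] = index of pair (i,j) in pair_labels() order
pair_index_matrix <- function(n) {
  K <- matrix(0L, n, n)
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      K[i, j] <- k; K[j, i] <- k; k <- k + 1L
    }
  }
  K
}

# First-order partial correlation of x and y given s, on plain vectors.
partial_cor <- function(x, y, s) {
  rxy <- stats::cor(x, y)
  rxs <- stats::cor(x, s)
  rys <- stats::cor(y, s)
  den <- (1 - rxs^2) * (1 - rys^2)
  if (den <= 0) return(NA_real_)
  (rxy - rxs * rys) / sqrt(den)
}

# Permute the row/column labels of the x-matrix (as an upper-triangle
# vector) and return partial correlations for every permutation row of P.
perm_partial_cors <- function(x, y, s, P, K) {
  n_pairs <- length(x)
  pl <- pair_labels(seq_len(nrow(K)))
  Xp <- matrix(0, nrow(P), n_pairs)
  for (k in seq_len(n_pairs)) {
    Xp[, k] <- x[K[cbind(P[, pl$i[k]], P[, pl$j[k]])]]
  }
  yc <- y - mean(y); yn <- sqrt(sum(yc^2))
  sc <- s - mean(s); sn <- sqrt(sum(sc^2))
  Xc <- Xp - rowMeans(Xp)
  xn <- sqrt(rowSums(Xc^2))
  rxy <- as.vector(Xc %*% yc) / (xn * yn)
  rxs <- as.vector(Xc %*% sc) / (xn * sn)
  rys <- sum(yc * sc) / (yn * sn)
  den <- (1 - rxs^2) * (1 - rys^2)
  out <- (rxy - rxs * rys) / sqrt(pmax(den, 0))
  out[den <= 0 | !is.finite(out)] <- NA_real_
  out
}

# All n! permutations of 1..n as a matrix (rows), identity first.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Partial Mantel test
#'
#' Correlates the distance matrix `dx` with `dy` while controlling for `ds`
#' using the first-order partial Pearson correlation of the unfolded upper
#' triangles, `r = (r_xy - r_xs r_ys) / sqrt((1 - r_xs^2)(1 - r_ys^2))`.
#' Significance is one-sided (positive association) by jointly permuting the
#' row/column labels of `dx`. For `n <= 5` labels the permutation
#' distribution is enumerated exhaustively (identity included,
#' `p = #\{r_perm >= r_obs\} / n!`); otherwise `n_perm` random permutations
#' give `p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1)`.
#'
#' @param dx,dy,ds conformable symmetric matrices (>= 4 labels): the tested
#'   matrix, the covariate matrix, and the control matrix.
#' @param n_perm number of sampled permutations (default 1000).
#' @param seed RNG seed for sampled permutations.
#' @param exhaustive force exhaustive enumeration on or off; default
#'   (`NULL`) enumerates when `n <= 5`.
#' @return A list of class `mantel_result`: `r`, `p`, `n_perm` (number of
#'   permutations actually used), `exhaustive`, and `error` (NA, or the
#'   reason the statistic is undefined, in which case `r` and `p` are NA).
#' @export
partial_mantel <- function(dx, dy, ds, n_perm = 1000, seed = NULL,
                           exhaustive = NULL) {
  dx <- as.matrix(dx); dy <- as.matrix(dy); ds <- as.matrix(ds)
  n <- nrow(dx)
  if (n < 4L) stopf("need at least 4 labels")
  if (!all(dim(dy) == n) || !all(dim(ds) == n)) {
    stopf("matrices must be conformable")
  }
  x <- upper_vec(dx); y <- upper_vec(dy); s <- upper_vec(ds)
  fail <- function(reason) {
    structure(list(r = NA_real_, p = NA_real_, n_perm = 0L,
                   exhaustive = FALSE, error = reason),
              class = "mantel_result")
  }
  if (stats::sd(x) == 0) return(fail("constant x distances"))
  if (stats::sd(y) == 0) return(fail("constant y distances"))
  r_obs <- if (stats::sd(s) == 0) stats::cor(x, y) else partial_cor(x, y, s)
  if (is.na(r_obs)) return(fail("undefined partial correlation (|r_xs| or |r_ys| = 1)"))
  use_exhaustive <- exhaustive %||% (n <= 5L)
  K <- pair_index_matrix(n)
  if (use_exhaustive) {
    P <- all_permutations(n)
    rp <- if (stats::sd(s) == 0) {
      perm_plain_cors(x, y, P, K)
    } else perm_partial_cors(x, y, s, P, K)
    p <- sum(rp >= r_obs - 1e-12, na.rm = TRUE) / nrow(P)
    m <- nrow(P)
  } else {
    P <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
    rp <- if (stats::sd(s) == 0) {
      perm_plain_cors(x, y, P, K)
    } else perm_partial_cors(x, y, s, P, K)
    p <- (sum(rp >= r_obs - 1e-12, na.rm = TRUE) + 1) / (n_perm + 1)
    m <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = m,
                 exhaustive = use_exhaustive, error = NA_character_),
            class = "mantel_result")
}

# Plain Mantel correlations under permutation (used when the control matrix
# is constant, where the partial statistic reduces to the simple one).
perm_plain_cors <- function(x, y, P, K) {
  pl <- pair_labels(seq_len(nrow(K)))
  Xp <- matrix(0, nrow(P), length(x))
  for (k in seq_along(x)) {
    Xp[, k] <- x[K[cbind(P[, pl$i[k]], P[, pl$j[k]])]]
  }
  yc <- y - mean(y); yn <- sqrt(sum(yc^2))
  Xc <- Xp - rowMeans(Xp)
  as.vector(Xc %*% yc) / (sqrt(rowSums(Xc^2)) * yn)
}

#' @method print mantel_result
#' @export
print.mantel_result <- function(x, ...) {
  if (!is.na(x$error)) {
    cat("partial Mantel: undefined (", x$error, ")\n", sep = "")
  } else {
    cat(sprintf("partial Mantel: r = %.4f, p = %.4g (%s, %d permutations)\n",
                x$r, x$p, if (x$exhaustive) "exhaustive" else "sampled",
                x$n_perm))
  }
  invisible(x)
}

#' Partial Mantel screen of gene FST matrices against climate factors
#'
#' Runs the partial Mantel test for every gene (rows of `gene_pair_fst`)
#' against each factor's environmental distance matrix, controlling for the
#' genome-wide FST matrix. Permutations of a gene's FST matrix are shared
#' across factors, and each gene uses a deterministic sub-stream of `seed`.
#'
#' @param gene_pair_fst genes x pairs matrix of gene-level FST values, pair
#'   columns in [pair_labels] order; rownames are gene ids.
#' @param dy_list named list of environmental distance matrices.
#' @param ds genome-wide FST matrix (structure control).
#' @param n_perm sampled permutations per gene (default 1000).
#' @param seed root seed.
#' @param exhaustive see [partial_mantel].
#' @return data.frame with columns `gene`, `factor`, `r`, `p`, `n_perm`,
#'   `exhaustive`, `error`.
#' @export
partial_mantel_screen <- function(gene_pair_fst, dy_list, ds,
                                  n_perm = 1000, seed = 1L,
                                  exhaustive = NULL) {
  n <- nrow(as.matrix(ds))
  use_exhaustive <- exhaustive %||% (n <= 5L)
  K <- pair_index_matrix(n)
  ys <- lapply(dy_list, function(m) upper_vec(as.matrix(m)))
  s <- upper_vec(as.matrix(ds))
  genes <- rownames(gene_pair_fst)
  P_fixed <- if (use_exhaustive) all_permutations(n) else NULL
  rows <- vector("list", length(genes) * length(ys))
  ri <- 1L
  for (gi in seq_along(genes)) {
    x <- gene_pair_fst[gi, ]
    x_const <- stats::sd(x) == 0 || anyNA(x)
    P <- if (use_exhaustive) P_fixed else
      with_seed(substream_seed(seed, gi),
                t(replicate(n_perm, sample.int(n))))
    for (f in names(ys)) {
      if (x_const) {
        rows[[ri]] <- data.frame(gene = genes[gi], factor = f,
                                 r = NA_real_, p = NA_real_, n_perm = 0L,
                                 exhaustive = use_exhaustive,
                                 error = "constant or missing x distances",
                                 stringsAsFactors = FALSE)
        ri <- ri + 1L
        next
      }
      r_obs <- partial_cor(x, ys[[f]], s)
      if (is.na(r_obs)) {
        rows[[ri]] <- data.frame(gene = genes[gi], factor = f,
                                 r = NA_real_, p = NA_real_, n_perm = 0L,
                                 exhaustive = use_exhaustive,
                                 error = "undefined partial correlation",
                                 stringsAsFactors = FALSE)
        ri <- ri + 1L
        next
      }
      rp <- perm_partial_cors(x, ys[[f]], s, P, K)
      p <- if (use_exhaustive) {
        sum(rp >= r_obs - 1e-12, na.rm = TRUE) / nrow(P)
      } else {
        (sum(rp >= r_obs - 1e-12, na.rm = TRUE) + 1) / (nrow(P) + 1)
      }
      rows[[ri]] <- data.frame(gene = genes[gi], factor = f, r = r_obs,
                               p = p, n_perm = nrow(P),
                               exhaustive = use_exhaustive,
                               error = NA_character_,
                               stringsAsFactors = FALSE)
      ri <- ri + 1L
    }
  }
  out <- do.call(rbind, rows[seq_len(ri - 1L)])
  rownames(out) <- NULL
  out
}

#' Simulation-derived effect-size thresholds
#'
#' For each factor, draws `n_sim` random gene-FST matrices whose
#' upper-triangle entries are i.i.d. Uniform(0, 1), computes the signed
#' partial Mantel correlation of each against the factor's real distance
#' matrix (controlling for the real genome-wide FST matrix), and returns the
#' empirical `quantile` (linear interpolation) of those correlations as the
#' screening threshold r*. The same simulated matrices are reused across
#' factors. `n_sim` conventionally matches the number of highly variable
#' genes being screened.
#'
#' @param dy_list named list of environmental distance matrices.
#' @param ds genome-wide FST matrix.
#' @param n_sim number of simulated matrices.
#' @param quantile quantile of the simulated r distribution (default 0.95).
#' @param seed RNG seed.
#' @return data.frame with columns `factor`, `r_star`, `n_sim`, `quantile`.
#' @export
simulate_threshold <- function(dy_list, ds, n_sim, quantile = 0.95,
                               seed = 1L) {
  ds <- as.matrix(ds)
  n <- nrow(ds)
  n_pairs <- n * (n - 1L) / 2L
  s <- upper_vec(ds)
  X <- with_seed(seed, matrix(stats::runif(n_sim * n_pairs), n_sim, n_pairs))
  rows <- lapply(names(dy_list), function(f) {
    y <- upper_vec(as.matrix(dy_list[[f]]))
    if (stats::sd(y) == 0) stopf("degenerate (constant) factor '%s'", f)
    yc <- y - mean(y); yn <- sqrt(sum(yc^2))
    sc <- s - mean(s); sn <- sqrt(sum(sc^2))
    Xc <- X - rowMeans(X)
    xn <- sqrt(rowSums(Xc^2))
    rxy <- as.vector(Xc %*% yc) / (xn * yn)
    if (sn > 0) {
      rxs <- as.vector(Xc %*% sc) / (xn * sn)
      rys <- sum(yc * sc) / (yn * sn)
      r <- (rxy - rxs * rys) / sqrt((1 - rxs^2) * (1 - rys^2))
    } else {
      r <- rxy
    }
    data.frame(factor = f,
               r_star = unname(stats::quantile(r, quantile, na.rm = TRUE)),
               n_sim = n_sim, quantile = quantile,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Three-step stringency filter for candidate genes
#'
#' Step 1 keeps gene-factor results whose partial Mantel r exceeds the
#' factor's simulation-derived threshold (strict `r > r*`); step 2 keeps
#' those with a significant permutation p (`p <= p_max`); step 3 keeps genes
#' annotated with the required GO term. Candidates are the results passing
#' all three.
#'
#' @param results data.frame from [partial_mantel_screen].
#' @param thresholds data.frame from [simulate_threshold].
#' @param annotations ancestor-closed gene-to-GO data.frame (`gene`,
#'   `term`).
#' @param required_term GO term required at step 3 (default
#'   `"response to abiotic stimulus"`).
#' @param p_max significance cut-off at step 2 (default 0.05).
#' @return data.frame of all non-error results with logical columns
#'   `step1`, `step2`, `step3`, `candidate`.
#' @export
three_step_filter <- function(results, thresholds, annotations,
                              required_term = "response to abiotic stimulus",
                              p_max = 0.05) {
  res <- results[is.na(results$error), , drop = FALSE]
  idx <- match(res$factor, thresholds$factor)
  if (anyNA(idx)) {
    stopf("no threshold for factor '%s'", res$factor[is.na(idx)][1L])
  }
  res$r_star <- thresholds$r_star[idx]
  res$step1 <- res$r > res$r_star
  res$step2 <- res$p <= p_max
  with_term <- unique(annotations$gene[annotations$term == required_term])
  res$step3 <- res$gene %in% with_term
  res$candidate <- res$step1 & res$step2 & res$step3
  rownames(res) <- NULL
  res
}
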