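make_climate <- function() {
  generate_climate_table(c(700, 2000, 2600, 3400), seed = 3)
}

test_that("growing-season means are per-site arithmetic means", {
  ct <- data.frame(site = c("a", "b"), altitude = c(1, 2))
  for (p in c("temp", "prec", "rad")) {
    for (m in 1:12) ct[[sprintf("%s_%02d", p, m)]] <- c(m, 10 * m)
  }
  ct$gs_months <- c("6,7,8", "5")
  out <- derive_growing_season_variables(ct)
  expect_equal(out$MRGS, c(7, 50))
  expect_equal(out$MTGS, c(7, 50))
  expect_equal(out$MPGS, c(7, 50))

  ct$gs_months <- c("6,7,8", "")
  expect_error(derive_growing_season_variables(ct), "gs_months|growing")
})

test_that("correlation pruning drops duplicates and exact linear dependants", {
  ct <- make_climate()
  ct$COPY <- ct$MAT
  ct$LIN <- 2 * ct$MAT + 5
  pr <- prune_correlated_variables(ct, vars = c("MAT", "COPY", "LIN"))
  expect_equal(pr$kept, "MAT")
  expect_setequal(pr$dropped$variable, c("COPY", "LIN"))
  expect_equal(pr$dropped$r, c(1, 1))
  expect_error(prune_correlated_variables(ct[1:2, ]), "3 sites")
})

test_that("planted correlated pairs are pruned to the hand-computed kept set", {
  ct <- make_climate()
  ct <- derive_growing_season_variables(ct)
  vars <- c("TS", "TAR", "RS", "MPGS", "MRGS", "MAT")
  pr <- prune_correlated_variables(ct, vars = vars)
  # independent greedy recomputation
  flagged <- vars[vapply(vars, function(v) {
    x <- ct[[v]]; (max(x) - min(x)) / mean(abs(x)) < 0.2
  }, TRUE)]
  kept <- character()
  for (v in setdiff(vars, flagged)) {
    if (all(abs(vapply(kept, function(k) cor(ct[[v]], ct[[k]]), 0)) < 0.8)) {
      kept <- c(kept, v)
    }
  }
  expect_equal(pr$kept, kept)
  expect_equal(sort(pr$flagged), sort(flagged))
})

test_that("PCoA reproduces classical MDS geometry", {
  # three collinear sites at positions 0, 1, 3
  x <- c(0, 1, 3)
  d <- abs(outer(x, x, `-`))
  res <- pcoa(d)
  ax1 <- res$coords[, 1]
  expect_equal(abs(diff(ax1)), abs(diff(x)), tolerance = 1e-8)
  expect_lt(abs(res$eigenvalues[2]), 1e-8)

  # Euclidean input: eigenvalues all (numerically) non-negative
  set.seed(101)
  pts <- matrix(rnorm(20), 5, 4)
  res2 <- pcoa(as.matrix(dist(pts)))
  expect_true(all(res2$eigenvalues >= -1e-9))

  # equidistant sites: all non-null eigenvalues equal (regular simplex)
  d3 <- matrix(1, 4, 4); diag(d3) <- 0
  ev <- pcoa(d3)$eigenvalues
  pos <- ev[ev > 1e-9]
  expect_equal(length(pos), 3L)
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-9)

  # all-zero distances: single zero coordinate
  z <- pcoa(matrix(0, 3, 3))
  expect_equal(dim(z$coords), c(3L, 1L))
  expect_true(all(z$coords == 0))
})

test_that("environmental distance is the absolute difference", {
  ct <- data.frame(site = c("a", "b"), altitude = 1:2, v = c(1, 4))
  expect_equal(env_distance(ct, "v")[1, 2], 3)
  ct$w <- c(2, 2)
  expect_true(all(env_distance(ct, "w") == 0))
  ct4 <- data.frame(site = letters[1:4], altitude = 1:4, v = c(1, 5, 2, 9))
  m <- env_distance(ct4, "v")
  expect_equal(m["a", "d"], 8)
  expect_equal(m["b", "c"], 3)
  expect_equal(m, t(m))
})

test_that("partial Mantel r is exact for identical matrices and matches vegan", {
  set.seed(111)
  dx <- random_dist(6)
  ds <- random_dist(6)
  res <- partial_mantel(dx, dx, ds, n_perm = 99, seed = 1)
  expect_equal(res$r, 1.0)

  for (i in 1:20) {
    dx <- random_dist(7); dy <- random_dist(7); dc <- random_dist(7)
    mine <- partial_mantel(dx, dy, dc, n_perm = 10, seed = 1)
    ref <- vegan::mantel.partial(as.dist(dx), as.dist(dy), as.dist(dc),
                                 permutations = 0)
    expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("exhaustive permutation p at n = 4 equals the 24-permutation enumeration", {
  set.seed(121)
  dy <- random_dist(4); dc <- random_dist(4)
  # find an x achieving the strict maximum over all 24 relabellings
  repeat {
    dx <- random_dist(4)
    res <- partial_mantel(dx, dy, dc)
    if (res$p == 1 / 24) break
  }
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 24L)
  expect_equal(res$p, 1 / 24)

  # direct enumeration oracle for an arbitrary matrix
  dx <- random_dist(4)
  res <- partial_mantel(dx, dy, dc)
  perms <- altigrad:::all_permutations(4)
  rs <- apply(perms, 1, function(pm) {
    dxp <- dx[pm, pm]
    x <- dxp[upper.tri(dxp)]
    y <- dy[upper.tri(dy)]
    s <- dc[upper.tri(dc)]
    (cor(x, y) - cor(x, s) * cor(y, s)) /
      sqrt((1 - cor(x, s)^2) * (1 - cor(y, s)^2))
  })
  expect_equal(res$p, mean(rs >= res$r - 1e-12))
})

test_that("a zero-variance control reduces the partial statistic to simple Mantel", {
  set.seed(131)
  dx <- random_dist(6); dy <- random_dist(6)
  dzero <- matrix(1, 6, 6); diag(dzero) <- 0  # constant off-diagonal
  res <- partial_mantel(dx, dy, dzero, n_perm = 49, seed = 1)
  x <- dx[upper.tri(dx)]; y <- dy[upper.tri(dy)]
  expect_equal(res$r, cor(x, y), tolerance = 1e-12)
})

test_that("permutation p is invariant to joint relabelling of all matrices", {
  set.seed(141)
  dx <- random_dist(6); dy <- random_dist(6); dc <- random_dist(6)
  r1 <- partial_mantel(dx, dy, dc, n_perm = 500, seed = 9)
  pm <- sample(6)
  r2 <- partial_mantel(dx[pm, pm], dy[pm, pm], dc[pm, pm],
                       n_perm = 500, seed = 9)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  # sampled p varies only through the permutation draw; both estimate the
  # same tail probability
  expect_lt(abs(r1$p - r2$p), 0.1)
})

test_that("degenerate Mantel inputs return labelled error results", {
  dzero <- matrix(0, 4, 4)
  dy <- random_dist(4)
  res <- partial_mantel(dzero, dy, dy)
  expect_true(is.na(res$r))
  expect_match(res$error, "constant x")
  res2 <- partial_mantel(dy, dzero, dy)
  expect_match(res2$error, "constant y")
  res3 <- partial_mantel(dy, dy, dy)
  expect_match(res3$error, "undefined partial")
})

test_that("simulated thresholds: quantile conventions and Monte-Carlo stability", {
  set.seed(151)
  dy <- random_dist(4); dc <- random_dist(4)
  t1 <- simulate_threshold(list(f = dy), dc, n_sim = 200, quantile = 1.0,
                           seed = 5)
  t2 <- simulate_threshold(list(f = dy), dc, n_sim = 200, quantile = 1.0,
                           seed = 5)
  expect_identical(t1, t2)
  t95 <- simulate_threshold(list(f = dy), dc, n_sim = 200, seed = 5)
  expect_gt(t1$r_star, t95$r_star)  # max exceeds the 95% quantile

  a <- simulate_threshold(list(f = dy), dc, n_sim = 10000, seed = 1)$r_star
  b <- simulate_threshold(list(f = dy), dc, n_sim = 10000, seed = 2)$r_star
  expect_lt(abs(a - b), 0.02)

  dconst <- matrix(2, 4, 4); diag(dconst) <- 0
  expect_error(simulate_threshold(list(f = dconst), dc, 10, seed = 1),
               "degenerate")
})

test_that("three-step filter applies threshold, significance and GO rules", {
  th <- data.frame(factor = "MRGS", r_star = 0.81)
  ann <- data.frame(gene = c("g1", "g2"),
                    term = "response to abiotic stimulus")
  res <- data.frame(gene = c("g1", "g1", "g3"),
                    factor = "MRGS",
                    r = c(0.90, 0.90, 0.90),
                    p = c(0.03, 0.20, 0.03),
                    n_perm = 1000, exhaustive = FALSE,
                    error = NA_character_)
  out <- three_step_filter(res, th, ann)
  expect_equal(out$candidate, c(TRUE, FALSE, FALSE))
  expect_equal(out$step1, c(TRUE, TRUE, TRUE))
  expect_equal(out$step2, c(TRUE, FALSE, TRUE))
  expect_equal(out$step3, c(TRUE, TRUE, FALSE))
  expect_error(three_step_filter(transform(res, factor = "XX"), th, ann),
               "threshold")
})

test_that("twenty-gene filter fixture matches hand enumeration", {
  set.seed(161)
  res <- data.frame(gene = sprintf("g%02d", 1:20), factor = "F1",
                    r = runif(20, 0.5, 1), p = runif(20, 0, 0.1),
                    n_perm = 1000, exhaustive = FALSE, error = NA_character_)
  th <- data.frame(factor = "F1", r_star = 0.75)
  ann <- data.frame(gene = sprintf("g%02d", seq(2, 20, by = 2)),
                    term = "response to abiotic stimulus")
  out <- three_step_filter(res, th, ann)
  hand <- res$r > 0.75 & res$p <= 0.05 & res$gene %in% ann$gene
  expect_equal(out$candidate, hand)
})

test_that("screen results agree with the single-test interface", {
  set.seed(171)
  n <- 6
  dmat <- random_dist(n)
  dy <- random_dist(n)
  X <- matrix(runif(3 * n * (n - 1) / 2), 3)
  rownames(X) <- c("gA", "gB", "gC")
  colnames(X) <- altigrad:::pair_labels(paste0("S", 1:n))$label
  scr <- partial_mantel_screen(X, list(f = dy), dmat, n_perm = 200, seed = 4)
  for (i in 1:3) {
    single_r <- altigrad:::partial_cor(X[i, ],
                                       altigrad:::upper_vec(dy),
                                       altigrad:::upper_vec(dmat))
    expect_equal(scr$r[i], single_r, tolerance = 1e-12)
  }
})
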