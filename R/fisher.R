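#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Computes the exact two-sided p-value of the table
#' `rbind(c(a, b), c(c, d))` by enumerating the hypergeometric support and
#' summing the probabilities of all tables no more probable than the
#' observed one, using the conventional relative tolerance of 1e-7 when
#' comparing probabilities. Tables with a zero margin have p = 1.
#'
#' Vectorised over `a`, `b`, `c`, `d`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]          # row 1 margin
    m2 <- c[i] + d[i]          # row 2 margin
    k <- a[i] + c[i]           # column 1 margin
    if (m1 == 0L || m2 == 0L || k == 0L || (b[i] + d[i]) == 0L) {
      out[i] <- 1
      next
    }
    lo <- max(0L, k - m2)
    hi <- min(k, m1)
    dens <- stats::dhyper(lo:hi, m1, m2, k)
    obs <- dens[a[i] - lo + 1L]
    out[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  out
}

# Lookup table of two-sided Fisher p over all tables with both row sums equal
# to `target`: entry [i, j] is the p-value for alt counts (i-1, j-1).
fisher_p_lookup <- function(target) {
  g <- expand.grid(a = 0:target, c = 0:target)
  p <- fisher_exact_p(g$a, target - g$a, g$c, target - g$c)
  matrix(p, nrow = target + 1L, ncol = target + 1L)
}
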