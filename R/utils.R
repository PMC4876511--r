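#' @keywords internal
"_PACKAGE"

BASES <- c("A", "T", "C", "G")
SYNC_COLS <- c("A", "T", "C", "G", "N", "del")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-unit sub-stream seed from a root seed, kept within the
# 32-bit integer range so changing the number of units never reshuffles
# earlier ones.
substream_seed <- function(root_seed, index) {
  as.integer((as.double(root_seed) * 48271 + as.double(index) * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Names of all unordered pool pairs, in the row-major upper-triangle order
# used throughout the package.
pair_labels <- function(pools) {
  n <- length(pools)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  list(
    i = idx[, 1L], j = idx[, 2L],
    label = paste(pools[idx[, 1L]], pools[idx[, 2L]], sep = ":")
  )
}

# Upper triangle of a symmetric matrix as a vector in pair_labels() order.
upper_vec <- function(m) {
  t(m)[lower.tri(m)]
}

# Rebuild a symmetric zero-diagonal matrix from an upper-triangle vector.
sym_from_upper <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- NA_real_
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- v[k]
      m[j, i] <- v[k]
      k <- k + 1L
    }
  }
  m
}
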