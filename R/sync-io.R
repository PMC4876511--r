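#' Pooled allele counts
#'
#' `pool_counts` holds per-position, per-pool read counts of the four
#' nucleotides (plus N and deletion columns, carried but ignored downstream),
#' i.e. the content of a PoPoolation2 "sync" record. Positions are 1-based.
#'
#' @param chrom character vector of chromosome/contig names.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases (A/T/C/G).
#' @param counts integer array of dimension `n_positions x n_pools x 6`,
#'   third dimension named `A,T,C,G,N,del`.
#' @param pools character vector of pool (population) names, in the fixed
#'   column order of the sync file.
#'
#' @return An object of class `pool_counts`.
#' @export
pool_counts <- function(chrom, pos, ref, counts, pools) {
  n <- length(pos)
  if (length(chrom) != n || length(ref) != n) stopf("chrom/pos/ref lengths differ")
  if (any(pos < 1L)) stopf("positions must be >= 1")
  if (!is.array(counts) || length(dim(counts)) != 3L ||
      dim(counts)[1L] != n || dim(counts)[2L] != length(pools) ||
      dim(counts)[3L] != 6L) {
    stopf("counts must be an n_positions x n_pools x 6 array")
  }
  if (any(counts < 0)) stopf("counts must be non-negative")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, pools, SYNC_COLS)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = toupper(as.character(ref)), counts = counts,
         pools = as.character(pools)),
    class = "pool_counts"
  )
}

#' @method print pool_counts
#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %d positions x %d pools (%s)\n",
              n_positions(x), length(x$pools), paste(x$pools, collapse = ", ")))
  invisible(x)
}

#' Number of variant positions in a `pool_counts` object
#' @param x a `pool_counts` object.
#' @return Integer count of positions.
#' @export
n_positions <- function(x) length(x$pos)

#' Subset a `pool_counts` object by position index
#' @param x a `pool_counts` object.
#' @param i integer or logical index over positions.
#' @param ... ignored.
#' @return A `pool_counts` object with the selected positions.
#' @export
`[.pool_counts` <- function(x, i, ...) {
  pool_counts(x$chrom[i], x$pos[i], x$ref[i],
              x$counts[i, , , drop = FALSE], x$pools)
}

#' Per-pool read coverage
#'
#' Coverage is the sum of the four nucleotide counts (N and deletion columns
#' are excluded).
#'
#' @param x a `pool_counts` object.
#' @return Integer matrix, positions x pools.
#' @export
coverage_matrix <- function(x) {
  cov <- x$counts[, , "A", drop = FALSE] + x$counts[, , "T", drop = FALSE] +
    x$counts[, , "C", drop = FALSE] + x$counts[, , "G", drop = FALSE]
  matrix(cov, nrow = n_positions(x), ncol = length(x$pools),
         dimnames = list(NULL, x$pools))
}

#' Biallelic reduction to reference/alternate counts
#'
#' At each position the alternate allele is the non-reference base with the
#' highest read count summed over pools; ties are broken by the fixed base
#' order A < T < C < G. Counts of the remaining two bases are ignored.
#'
#' @param x a `pool_counts` object.
#' @return A list with `alt_base` (character vector), `ref` and `alt`
#'   (integer matrices, positions x pools) and `coverage` (four-base
#'   coverage matrix).
#' @export
allele_counts <- function(x) {
  n <- n_positions(x)
  np <- length(x$pools)
  base_tot <- sapply(BASES, function(b) {
    rowSums(matrix(x$counts[, , b], nrow = n, ncol = np))
  })
  base_tot <- matrix(base_tot, nrow = n, ncol = 4L, dimnames = list(NULL, BASES))
  ref_idx <- match(x$ref, BASES)
  if (anyNA(ref_idx)) stopf("reference base must be one of A/T/C/G")
  # mask the reference base, pick argmax in fixed A<T<C<G order
  masked <- base_tot
  masked[cbind(seq_len(n), ref_idx)] <- -1L
  alt_idx <- max.col(masked, ties.method = "first")
  alt_base <- BASES[alt_idx]
  ref_m <- matrix(0L, n, np, dimnames = list(NULL, x$pools))
  alt_m <- ref_m
  for (b in seq_along(BASES)) {
    sel_r <- ref_idx == b
    sel_a <- alt_idx == b
    cb <- matrix(x$counts[, , BASES[b]], nrow = n, ncol = np)
    if (any(sel_r)) ref_m[sel_r, ] <- cb[sel_r, , drop = FALSE]
    if (any(sel_a)) alt_m[sel_a, ] <- cb[sel_a, , drop = FALSE]
  }
  list(alt_base = alt_base, ref = ref_m, alt = alt_m,
       coverage = coverage_matrix(x))
}

#' Read a PoPoolation2 sync file
#'
#' Expects tab-separated lines `chrom pos ref pool1 pool2 ...` where each
#' pool column is `A:T:C:G:N:del` read counts and `pos` is 1-based.
#'
#' @param path file path.
#' @param pool_names character vector naming the pool columns, in file order.
#' @return A [pool_counts] object.
#' @export
read_sync <- function(path, pool_names) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(pool_counts(character(), integer(), character(),
                       array(0L, c(0L, length(pool_names), 6L)), pool_names))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expect <- 3L + length(pool_names)
  bad <- which(nf != expect)
  if (length(bad)) {
    stopf("sync parse error at line %d: expected %d columns, found %d",
          bad[1L], expect, nf[bad[1L]])
  }
  m <- matrix(unlist(fields), ncol = expect, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos)) stopf("sync parse error at line %d: non-integer position",
                        which(is.na(pos))[1L])
  np <- length(pool_names)
  n <- length(lines)
  counts <- array(0L, c(n, np, 6L))
  for (p in seq_len(np)) {
    parts <- strsplit(m[, 3L + p], ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      stopf("sync parse error at line %d: pool column must have 6 fields",
            which(lengths(parts) != 6L)[1L])
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) {
      stopf("sync parse error at line %d: non-integer count",
            ceiling(which(is.na(v))[1L] / 6))
    }
    counts[, p, ] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  pool_counts(m[, 1L], pos, m[, 3L], counts, pool_names)
}

#' Write a PoPoolation2 sync file
#'
#' @param x a [pool_counts] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  np <- length(x$pools)
  n <- n_positions(x)
  cols <- vapply(seq_len(np), function(p) {
    cm <- matrix(x$counts[, p, ], nrow = n, ncol = 6L)
    apply(cm, 1L, paste, collapse = ":")
  }, character(n))
  cols <- matrix(cols, nrow = n, ncol = np)
  lines <- paste(x$chrom, x$pos, x$ref,
                 apply(cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read pooled allele counts from a VCF with per-sample allelic depths
#'
#' Each VCF sample is treated as one pool; the `AD` FORMAT field supplies
#' reference and alternate read counts. Multiallelic records are skipped and
#' counted (reported as attribute `n_multiallelic` and via a message).
#'
#' @param path VCF file path (plain or bgzipped).
#' @return A [pool_counts] object; pools are the VCF sample names.
#' @export
read_vcf_pooled <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  pools <- colnames(v@gt)[-1L]
  if (nrow(fix) == 0L) {
    out <- pool_counts(character(), integer(), character(),
                       array(0L, c(0L, length(pools), 6L)), pools)
    attr(out, "n_multiallelic") <- 0L
    return(out)
  }
  fmt <- v@gt[, 1L]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    stopf("unsupported input: VCF records lack the AD FORMAT field")
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  biallelic <- !grepl(",", alt, fixed = TRUE) &
    ref %in% BASES & alt %in% BASES
  n_multi <- sum(grepl(",", alt, fixed = TRUE))
  if (n_multi > 0L) message(sprintf("skipping %d multiallelic record(s)", n_multi))
  ad <- vcfR::extract.gt(v, element = "AD")
  ad <- matrix(ad, nrow = nrow(fix), ncol = length(pools),
               dimnames = list(NULL, pools))
  keep <- which(biallelic)
  n <- length(keep)
  counts <- array(0L, c(n, length(pools), 6L))
  ref_i <- match(ref[keep], SYNC_COLS)
  alt_i <- match(alt[keep], SYNC_COLS)
  for (p in seq_along(pools)) {
    parts <- strsplit(ad[keep, p], ",", fixed = TRUE)
    rc <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    ac <- suppressWarnings(as.integer(vapply(parts, function(z) {
      if (length(z) >= 2L) z[2L] else "0"
    }, "")))
    rc[is.na(rc)] <- 0L
    ac[is.na(ac)] <- 0L
    counts[cbind(seq_len(n), p, ref_i)] <- rc
    counts[cbind(seq_len(n), p, alt_i)] <- ac
  }
  out <- pool_counts(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                     ref[keep], counts, pools)
  attr(out, "n_multiallelic") <- n_multi
  out
}
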