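#' Read a site climate table
#'
#' A climate table is a TSV with one row per site: a `site` column, a numeric
#' `altitude` column (metres), any number of numeric bio-climatic variable
#' columns, optional monthly series (`temp_01..temp_12`, `prec_01..prec_12`,
#' `rad_01..rad_12`) and an optional `gs_months` column listing each site's
#' growing-season months as a comma-separated subset of 1..12.
#'
#' @param path TSV file path.
#' @return A validated `data.frame`, one row per site.
#' @export
read_climate_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_climate_table(df)
}

#' Write a site climate table
#' @param climate climate `data.frame` (see [read_climate_table]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_climate_table <- function(climate, path) {
  utils::write.table(climate, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_climate_table <- function(df) {
  if (!"site" %in% names(df)) stopf("climate table must have a 'site' column")
  if (anyDuplicated(df$site)) stopf("duplicated site id in climate table")
  if (nrow(df) < 2L) stopf("climate table needs at least 2 sites")
  num_cols <- setdiff(names(df), c("site", "gs_months"))
  for (cn in num_cols) {
    if (!is.numeric(df[[cn]])) {
      stopf("climate variable '%s' is not numeric", cn)
    }
  }
  if ("gs_months" %in% names(df)) {
    gm <- gs_month_list(df)
    ok <- vapply(gm, function(m) length(m) >= 1L && all(m %in% 1:12), TRUE)
    if (!all(ok)) stopf("gs_months must be a non-empty subset of 1..12")
  }
  df
}

#' Growing-season months per site, as a list of integer vectors
#' @param climate climate `data.frame` with a `gs_months` column.
#' @return Named list (by site) of integer month vectors.
#' @export
gs_month_list <- function(climate) {
  if (!"gs_months" %in% names(climate)) {
    stopf("climate table has no gs_months column")
  }
  out <- lapply(strsplit(as.character(climate$gs_months), ","),
                function(z) as.integer(trimws(z)))
  names(out) <- climate$site
  out
}

#' Write a tree in newick format
#'
#' Internal node support values, when present as `node.label`, are written as
#' internal node labels (the convention used for bootstrap percentages).
#'
#' @param tree an [ape::phylo] tree.
#' @param path output file path, or `NULL` to return the newick string.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (anyDuplicated(tree$tip.label)) stopf("duplicate leaf labels in tree")
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
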