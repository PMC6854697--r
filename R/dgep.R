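# Differential gene-expression profiles (dGEPs).
#
# The dGEP of a drug on a cell line is the per-gene difference of
# log2-scaled expression between treated and untreated samples, after
# merging biological replicates by the mean:
#   dGEP = mean(log2 treated) - mean(log2 control).
# Raw-intensity tables are log2-transformed here (non-positive raw values
# are an error, no silent pseudo-count); tables flagged as already-log2
# are used as-is.

#' Compute the dGEP of one drug on one cell line
#'
#' @param expr an \code{\link{expression_table}}
#' @param drug_id drug identifier as used in the sample metadata
#' @param cell_line cell line identifier
#' @return named numeric vector over genes, with attributes
#'   \code{drug_id} and \code{cell_line}
#' @export
compute_dgep <- function(expr, drug_id, cell_line) {
  meta <- expr$sample_meta
  treated <- meta$sample_id[meta$drug_id == drug_id & meta$cell_line == cell_line]
  control <- meta$sample_id[meta$drug_id == "CONTROL" & meta$cell_line == cell_line]
  abort_if(length(treated) == 0, "no treated sample for drug '%s' on cell line '%s'",
           drug_id, cell_line)
  abort_if(length(control) == 0, "no control sample for cell line '%s'", cell_line)
  vals <- expr$values[, c(treated, control), drop = FALSE]
  if (!expr$logged) {
    abort_if(any(vals <= 0),
             "non-positive raw intensity encountered; cannot log2-transform")
    vals <- log2(vals)
  }
  d <- rowMeans(vals[, treated, drop = FALSE]) - rowMeans(vals[, control, drop = FALSE])
  attr(d, "drug_id") <- drug_id
  attr(d, "cell_line") <- cell_line
  d
}

#' Compute the dGEP matrix for all drugs in an expression table
#'
#' One row per drug. A drug profiled on several cell lines gets the mean
#' of its per-cell-line dGEPs (the within-cell-line treated-vs-control
#' contrast is always taken first).
#'
#' @param expr an \code{\link{expression_table}}
#' @param drugs optional drug ids (default: all non-control drugs in the
#'   metadata, lexicographic order)
#' @return numeric matrix drugs x genes
#' @export
compute_dgep_matrix <- function(expr, drugs = NULL) {
  meta <- expr$sample_meta
  drugs <- drugs %||% sort(setdiff(unique(meta$drug_id), "CONTROL"), method = "radix")
  abort_if(length(drugs) == 0, "expression table contains no treated drugs")
  rows <- lapply(drugs, function(d) {
    lines <- unique(meta$cell_line[meta$drug_id == d])
    abort_if(length(lines) == 0, "drug '%s' absent from expression metadata", d)
    per_line <- vapply(lines, function(cl) compute_dgep(expr, d, cl),
                       numeric(nrow(expr$values)))
    rowMeans(per_line)
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(drugs, rownames(expr$values))
  m
}
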