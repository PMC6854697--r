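# Disease feature encoders: flat phenotype/genotype term sets one-hot
# encoded over the observed vocabulary, then reduced by centered PCA to
# dense score vectors (30 phenotype / 20 genotype components by default).

#' Build a disease x term one-hot matrix
#'
#' Row i is the binary indicator of disease i's annotated terms over the
#' ordered vocabulary. Diseases with empty annotation sets yield all-zero
#' rows with a warning; a term outside the vocabulary is an error.
#'
#' @param annotations named list disease id -> character vector of terms
#'   (as from \code{\link{read_term_annotations}})
#' @param vocabulary ordered term universe (default: sorted union of the
#'   observed terms)
#' @return binary matrix diseases x terms with dimnames
#' @export
build_onehot <- function(annotations, vocabulary = NULL) {
  abort_if(length(annotations) == 0, "no disease annotations supplied")
  vocabulary <- vocabulary %||%
    sort(unique(unlist(annotations, use.names = FALSE)), method = "radix")
  ids <- sort(names(annotations), method = "radix")
  m <- matrix(0L, nrow = length(ids), ncol = length(vocabulary),
              dimnames = list(ids, vocabulary))
  for (d in ids) {
    terms <- annotations[[d]]
    if (length(terms) == 0) {
      warning(sprintf("disease '%s' has no annotated terms (all-zero row)", d),
              call. = FALSE)
      next
    }
    idx <- match(terms, vocabulary)
    abort_if(anyNA(idx), "term(s) outside the vocabulary for disease '%s': %s",
             d, paste(terms[is.na(idx)], collapse = ", "))
    m[d, idx] <- 1L
  }
  m
}

#' Fit PCA on a one-hot matrix and project the diseases
#'
#' Centered (unscaled) PCA. Component signs are fixed so that each
#' component's largest-magnitude loading is positive, making scores
#' reproducible across platforms.
#'
#' @param onehot binary matrix diseases x terms (from
#'   \code{\link{build_onehot}})
#' @param n_components number of retained components; must not exceed
#'   \code{min(nrow - 1, ncol)}
#' @return object of class \code{disease_pca}: list with \code{scores}
#'   (diseases x components), \code{rotation}, \code{center} and
#'   \code{explained_variance} (proportion per component)
#' @export
fit_project_pca <- function(onehot, n_components) {
  abort_if(nrow(onehot) < 2, "PCA needs at least 2 diseases")
  cap <- min(nrow(onehot) - 1L, ncol(onehot))
  abort_if(n_components > cap,
           "n_components = %d exceeds the feasible maximum %d", n_components, cap)
  pc <- stats::prcomp(onehot, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  rotation <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  rownames(scores) <- rownames(onehot)
  structure(list(scores = scores,
                 rotation = rotation,
                 center = pc$center,
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]),
            class = "disease_pca")
}

#' @export
print.disease_pca <- function(x, ...) {
  cat(sprintf("disease_pca: %d diseases x %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Encode diseases from phenotype and genotype annotations
#'
#' Restricts to diseases annotated with both feature types (those missing
#' one are excluded from downstream disease similarity), builds the two
#' one-hot matrices and projects each with PCA.
#'
#' @param phenotype_annotations,genotype_annotations named lists of term
#'   vectors
#' @param n_pheno,n_geno retained components (defaults 30 and 20); capped
#'   at the feasible maximum with a message if the cohort is too small
#' @return list with \code{phenotype} and \code{genotype} score matrices
#'   (rows = the common diseases), and the two \code{disease_pca} fits
#' @export
encode_diseases <- function(phenotype_annotations, genotype_annotations,
                            n_pheno = 30L, n_geno = 20L) {
  common <- intersect(names(phenotype_annotations), names(genotype_annotations))
  abort_if(length(common) < 2,
           "need at least 2 diseases with both phenotype and genotype annotations")
  dropped <- setdiff(union(names(phenotype_annotations), names(genotype_annotations)),
                     common)
  if (length(dropped) > 0) {
    message(sprintf("encode_diseases: excluded %d disease(s) missing one feature type",
                    length(dropped)))
  }
  ph <- build_onehot(phenotype_annotations[common])
  gt <- build_onehot(genotype_annotations[common])
  cap_ph <- min(nrow(ph) - 1L, ncol(ph))
  cap_gt <- min(nrow(gt) - 1L, ncol(gt))
  if (n_pheno > cap_ph || n_geno > cap_gt) {
    message(sprintf("encode_diseases: component counts capped to %d/%d",
                    min(n_pheno, cap_ph), min(n_geno, cap_gt)))
  }
  pca_ph <- fit_project_pca(ph, min(n_pheno, cap_ph))
  pca_gt <- fit_project_pca(gt, min(n_geno, cap_gt))
  list(phenotype = pca_ph$scores, genotype = pca_gt$scores,
       phenotype_pca = pca_ph, genotype_pca = pca_gt)
}
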