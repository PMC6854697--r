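# Per-feature similarity matrices and min-max fusion.
#
# Vector-valued features (SMILES vector s, dGEP vector g, disease
# phenotype a and genotype d) use pairwise cosine similarity. Set-valued
# features (target-protein sets P, enzyme sets E) use a best-match set
# similarity: iterate over the smaller set, take each member's best cosine
# match in the larger set, and sum. Per-feature matrices are summed
# off-diagonally and min-max normalised with +-0.01 offsets so that the
# fused drug-drug (DDSI) and disease-disease (DiDiS) matrices have unit
# diagonal and off-diagonal values strictly inside (0, 1).

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length, both nonzero
#' @return \code{sum(u*v) / (||u|| ||v||)}, in [-1, 1]
#' @export
cosine <- function(u, v) {
  abort_if(length(u) != length(v), "cosine: length mismatch (%d vs %d)",
           length(u), length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  abort_if(nu == 0 || nv == 0, "cosine is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# rows scaled to unit norm; errors naming offending ids
unit_rows <- function(m, ids = rownames(m)) {
  nrm <- sqrt(rowSums(m^2))
  bad <- which(nrm == 0)
  abort_if(length(bad) > 0, "zero feature vector for: %s",
           paste(ids[bad] %||% bad, collapse = ", "))
  m / nrm
}

#' Pairwise cosine similarity matrix for a vector-valued feature
#'
#' @param vectors numeric matrix with one row per entity (row names are
#'   the entity ids), or a named list of equal-length vectors
#' @param feature_code single-letter feature tag (\code{s}, \code{g},
#'   \code{a} or \code{d}), attached as an attribute
#' @return symmetric similarity matrix with unit diagonal and attribute
#'   \code{feature_code}
#' @export
vector_feature_matrix <- function(vectors, feature_code = "s") {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  abort_if(is.null(rownames(vectors)), "feature vectors need entity ids as row names")
  U <- unit_rows(vectors)
  M <- tcrossprod(U)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  attr(M, "feature_code") <- feature_code
  M
}

#' Best-match set similarity between two vector sets
#'
#' The smaller set (by cardinality) indexes the sum: each of its members
#' contributes its best cosine match in the larger set,
#' \code{sum over rho in S of max over tau in L of cosine(rho, tau)}.
#' When the two sets have equal cardinality the directed sums of the two
#' orientations need not coincide, so their average is returned; a
#' similarity must not depend on argument order. The value equals
#' \code{nrow(P)} when both arguments are the same set.
#'
#' @param P_i,P_j numeric matrices, one nonzero row per member vector
#' @return scalar similarity, symmetric in its arguments
#' @export
set_similarity <- function(P_i, P_j) {
  abort_if(is.null(P_i) || nrow(P_i) == 0 || is.null(P_j) || nrow(P_j) == 0,
           "set_similarity needs two nonempty vector sets")
  directed <- function(S, L) {
    C <- tcrossprod(unit_rows(S, seq_len(nrow(S))), unit_rows(L, seq_len(nrow(L))))
    sum(apply(C, 1, max))
  }
  if (nrow(P_i) < nrow(P_j)) {
    directed(P_i, P_j)
  } else if (nrow(P_j) < nrow(P_i)) {
    directed(P_j, P_i)
  } else {
    (directed(P_i, P_j) + directed(P_j, P_i)) / 2
  }
}

#' Pairwise set-similarity matrix for a set-valued feature
#'
#' Note the raw diagonal entry of drug i equals its set size |P_i| (each
#' member matches itself perfectly); the fusion step's unit-diagonal rule
#' supplies the final diagonal.
#'
#' @param sets named list of per-entity vector-set matrices (as from
#'   \code{\link{embed_sequence_sets}})
#' @param feature_code single-letter tag (\code{p} or \code{e})
#' @return symmetric similarity matrix with attribute \code{feature_code}
#' @export
set_feature_matrix <- function(sets, feature_code = "p") {
  ids <- names(sets)
  abort_if(is.null(ids), "sets must be a named list")
  empty <- vapply(sets, function(s) is.null(s) || nrow(s) == 0, logical(1))
  abort_if(any(empty), "missing/empty vector set for: %s",
           paste(ids[empty], collapse = ", "))
  n <- length(sets)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <- set_similarity(sets[[i]], sets[[j]])
    }
  }
  attr(M, "feature_code") <- feature_code
  M
}

#' Min-max fusion of per-feature similarity matrices
#'
#' Off-diagonal cells of the summed matrix are rescaled by
#' \code{(sum - min_const) / (max_const - min_const)} where
#' \code{min_const} / \code{max_const} are the off-diagonal minimum minus
#' 0.01 and maximum plus 0.01; the diagonal is set to 1. The offsets
#' guarantee off-diagonal values strictly inside (0, 1).
#'
#' @param matrices list of square symmetric similarity matrices over the
#'   identical id set, in identical order
#' @param kind label for the fused matrix (\code{"DDSI"} or
#'   \code{"DiDiS"})
#' @return fused matrix of class \code{fused_similarity} with attributes
#'   \code{kind}, \code{features}, \code{min_const}, \code{max_const}
#' @export
fuse_minmax <- function(matrices, kind = "DDSI") {
  abort_if(length(matrices) == 0, "fuse_minmax needs at least one matrix")
  ids <- rownames(matrices[[1]])
  for (m in matrices) {
    check_square_labelled(m, "similarity matrix")
    abort_if(!identical(rownames(m), ids), "id mismatch between feature matrices")
  }
  n <- length(ids)
  abort_if(n < 2, "fusion needs at least 2 entities (no off-diagonal cells)")
  if (n == 2) {
    warning("only 2 entities: the single off-diagonal value maps to 0.5",
            call. = FALSE)
  }
  S <- Reduce(`+`, lapply(matrices, function(m) {
    attributes(m)[c("feature_code")] <- NULL
    unclass(m)
  }))
  off <- S[row(S) != col(S)]
  min_const <- min(off) - 0.01
  max_const <- max(off) + 0.01
  F <- (S - min_const) / (max_const - min_const)
  diag(F) <- 1
  dimnames(F) <- list(ids, ids)
  structure(F, class = c("fused_similarity", "matrix"),
            kind = kind,
            features = vapply(matrices, function(m)
              attr(m, "feature_code") %||% "?", character(1)),
            min_const = min_const, max_const = max_const)
}

#' @export
print.fused_similarity <- function(x, ...) {
  cat(sprintf("%s matrix: %d x %d over features {%s}; min_const %.6g, max_const %.6g\n",
              attr(x, "kind"), nrow(x), ncol(x),
              paste(attr(x, "features"), collapse = ","),
              attr(x, "min_const"), attr(x, "max_const")))
  invisible(x)
}

#' Bundle encoded drug features
#'
#' @param smiles drugs x 192 matrix of SMILES vectors (or NULL)
#' @param targets named list of target-protein vector-set matrices (or NULL)
#' @param enzymes named list of enzyme vector-set matrices (or NULL)
#' @param dgep drugs x k matrix of (encoded) dGEP vectors (or NULL)
#' @return object of class \code{drug_profiles}
#' @export
drug_profiles <- function(smiles = NULL, targets = NULL, enzymes = NULL,
                          dgep = NULL) {
  structure(list(s = smiles, p = targets, e = enzymes, g = dgep),
            class = "drug_profiles")
}

#' @export
print.drug_profiles <- function(x, ...) {
  n_of <- function(f) if (is.null(x[[f]])) 0L else
    if (is.list(x[[f]])) length(x[[f]]) else nrow(x[[f]])
  cat(sprintf("drug_profiles: s:%d p:%d e:%d g:%d drugs per feature\n",
              n_of("s"), n_of("p"), n_of("e"), n_of("g")))
  invisible(x)
}

profile_ids <- function(profiles, feature) {
  x <- profiles[[feature]]
  if (is.null(x)) return(NULL)
  if (is.list(x)) names(x) else rownames(x)
}

#' Build the drug-drug similarity intersection (DDSI) matrix
#'
#' Restricts to the drugs possessing every feature in \code{features}
#' (larger feature subsets therefore retain fewer drugs), builds each
#' per-feature similarity matrix over that intersection and fuses them
#' with \code{\link{fuse_minmax}}.
#'
#' @param profiles a \code{\link{drug_profiles}} object
#' @param features nonempty subset of \code{c("s", "p", "e", "g")}
#' @return fused DDSI matrix; attribute \code{n_dropped} counts drugs
#'   excluded for missing features
#' @export
build_ddsi <- function(profiles, features = c("s", "p", "e", "g")) {
  abort_if(length(features) == 0 || !all(features %in% c("s", "p", "e", "g")),
           "features must be a nonempty subset of {s, p, e, g}")
  features <- intersect(c("s", "p", "e", "g"), features)  # canonical order
  have <- lapply(features, function(f) profile_ids(profiles, f))
  missing_feat <- features[vapply(have, is.null, logical(1))]
  abort_if(length(missing_feat) > 0, "no drugs carry feature(s): %s",
           paste(missing_feat, collapse = ", "))
  ids <- sort(Reduce(intersect, have), method = "radix")
  universe <- sort(unique(unlist(have)), method = "radix")
  abort_if(length(ids) < 2,
           "fewer than 2 drugs possess all features in {%s}",
           paste(features, collapse = ","))
  if (length(ids) < length(universe)) {
    message(sprintf("build_ddsi: retained %d of %d drugs for E = {%s}",
                    length(ids), length(universe), paste(features, collapse = ",")))
  }
  mats <- lapply(features, function(f) {
    x <- profiles[[f]]
    if (is.list(x)) set_feature_matrix(x[ids], feature_code = f)
    else vector_feature_matrix(x[ids, , drop = FALSE], feature_code = f)
  })
  out <- fuse_minmax(mats, kind = "DDSI")
  attr(out, "n_dropped") <- length(universe) - length(ids)
  out
}

#' Build the disease-disease similarity (DiDiS) matrix
#'
#' Fuses the phenotype and genotype cosine similarity matrices over the
#' diseases carrying both vectors.
#'
#' @param phenotype,genotype score matrices with disease ids as row names
#'   (as from \code{\link{encode_diseases}})
#' @return fused DiDiS matrix
#' @export
build_didis <- function(phenotype, genotype) {
  ids <- sort(intersect(rownames(phenotype), rownames(genotype)), method = "radix")
  abort_if(length(ids) < 2, "fewer than 2 diseases carry both feature vectors")
  fuse_minmax(list(vector_feature_matrix(phenotype[ids, , drop = FALSE], "a"),
                   vector_feature_matrix(genotype[ids, , drop = FALSE], "d")),
              kind = "DiDiS")
}
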