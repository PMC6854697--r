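# Evaluation protocols: leave-one-out scoring, rank AUC over sampled or
# full positive/negative sets, per-disease / per-drug AUC tables, and
# k-fold cross-validation.
#
# Positives are the known associations; negatives are all drug-disease
# pairs of the scored universe not in the known set ("unknown" pairs).

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random positive outranks a random negative, with
#' ties counted one half; invariant under strictly monotone transforms of
#' the scores.
#'
#' @param scores numeric vector
#' @param labels binary vector (1 = positive) of the same length
#' @return AUC in [0, 1]
#' @export
#' @examples
#' rank_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))  # 0.75
rank_auc <- function(scores, labels) {
  abort_if(length(scores) != length(labels), "scores and labels differ in length")
  labels <- as.integer(labels != 0)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  abort_if(n_pos == 0 || n_neg == 0,
           "AUC needs at least one positive and one negative")
  r <- rank(scores)   # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Leave-one-out scores for every known and unknown pair
#'
#' Each known association (i, j) is scored with (i, j) hidden from the
#' known set (the configured exclusion mode is then applied to the
#' remainder); unknown pairs are scored against the full known set.
#'
#' @inheritParams score_pair
#' @return object of class \code{loo_result}: list with \code{known}
#'   (data.frame drug, disease, score), \code{matrix} (full
#'   \code{\link{score_all}} output), \code{known_mask} (logical matrix
#'   marking the known cells) and \code{mode}
#' @export
loo_scores <- function(I, D, A, mode = c("strict", "pair", "none")) {
  mode <- match.arg(mode)
  A <- A[A$drug %in% rownames(I) & A$disease %in% rownames(D), , drop = FALSE]
  abort_if(nrow(A) < 2, "leave-one-out needs at least 2 resolvable known pairs")
  full <- score_all(I, D, A, mode)
  loo <- vapply(seq_len(nrow(A)), function(p) {
    as.numeric(score_pair(A$drug[p], A$disease[p], I, D,
                          A[-p, , drop = FALSE], mode))
  }, numeric(1))
  mask <- matrix(FALSE, nrow(I), nrow(D), dimnames = dimnames(full))
  mask[cbind(A$drug, A$disease)] <- TRUE
  structure(list(known = data.frame(drug = A$drug, disease = A$disease,
                                    score = loo, stringsAsFactors = FALSE),
                 matrix = full, known_mask = mask, mode = mode),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("loo_result: %d known pairs, %d unknown pairs (mode %s)\n",
              nrow(x$known), sum(!x$known_mask), x$mode))
  invisible(x)
}

# pooled scores + labels of a loo_result
loo_pool <- function(loo) {
  list(scores = c(loo$known$score, unclass(loo$matrix)[!loo$known_mask]),
       labels = c(rep(1L, nrow(loo$known)), rep(0L, sum(!loo$known_mask))))
}

#' Full-matrix leave-one-out AUC
#'
#' AUC over all known pairs (leave-one-out scored) against all unknown
#' pairs.
#'
#' @param loo a \code{\link{loo_scores}} result
#' @return scalar AUC
#' @export
loo_full_auc <- function(loo) {
  pool <- loo_pool(loo)
  rank_auc(pool$scores, pool$labels)
}

eval_report <- function(scheme, auc_values, n_pos, n_neg, seed = NA,
                        per_entity = NULL) {
  structure(list(scheme = scheme,
                 auc_mean = mean(auc_values),
                 auc_sd = stats::sd(auc_values),
                 auc_values = auc_values,
                 n_pos = n_pos, n_neg = n_neg, seed = seed,
                 per_entity = per_entity),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: mean AUC %.4f over %d value(s) (%d pos / %d neg)\n",
              x$scheme, x$auc_mean, length(x$auc_values), x$n_pos, x$n_neg))
  invisible(x)
}

#' Repeated sampled AUC
#'
#' Per repeat, samples \code{ceiling(fraction * n)} known and unknown
#' pairs without replacement and computes the rank AUC; with
#' \code{fraction = 1} every repeat equals the full-matrix AUC.
#'
#' @param loo a \code{\link{loo_scores}} result
#' @param fraction sampled fraction of each class (default 0.10)
#' @param repeats number of repeats (default 20)
#' @param seed integer seed for the sampling
#' @return an \code{eval_report} with per-repeat AUC values
#' @export
sampled_auc <- function(loo, fraction = 0.10, repeats = 20L, seed = 1L) {
  pos <- loo$known$score
  neg <- unclass(loo$matrix)[!loo$known_mask]
  n_pos <- ceiling(fraction * length(pos))
  n_neg <- ceiling(fraction * length(neg))
  abort_if(n_pos < 1 || n_neg < 1, "degenerate sample: need >= 1 of each class")
  aucs <- with_seed(derive_seed(seed, "sampled-auc"), {
    vapply(seq_len(repeats), function(r) {
      sp <- pos[sample.int(length(pos), n_pos)]
      sn <- neg[sample.int(length(neg), n_neg)]
      rank_auc(c(sp, sn), c(rep(1L, n_pos), rep(0L, n_neg)))
    }, numeric(1))
  })
  eval_report("sampled", aucs, n_pos, n_neg, seed = seed)
}

#' Per-disease or per-drug AUC
#'
#' With \code{axis = "disease"} every disease ranks all drugs (positives:
#' its leave-one-out-scored known drugs; negatives: its unknown drugs);
#' \code{axis = "drug"} is the transpose. Entities lacking a positive or
#' a negative on their axis are skipped with a message and excluded from
#' the mean.
#'
#' @param loo a \code{\link{loo_scores}} result
#' @param axis \code{"disease"} or \code{"drug"}
#' @return an \code{eval_report}; element \code{per_entity} is a
#'   data.frame with one AUC per evaluable entity
#' @export
per_entity_auc <- function(loo, axis = c("disease", "drug")) {
  axis <- match.arg(axis)
  M <- unclass(loo$matrix)
  mask <- loo$known_mask
  if (axis == "drug") { M <- t(M); mask <- t(mask) }
  known_scores <- loo$known$score
  names_known <- if (axis == "disease") loo$known$disease else loo$known$drug
  other_known <- if (axis == "disease") loo$known$drug else loo$known$disease
  entities <- colnames(M)
  res <- lapply(entities, function(e) {
    pos <- known_scores[names_known == e]
    neg <- M[!mask[, e], e]
    if (length(pos) == 0 || length(neg) == 0) return(NULL)
    data.frame(entity = e, auc = rank_auc(c(pos, neg),
                                          c(rep(1L, length(pos)), rep(0L, length(neg)))),
               n_pos = length(pos), n_neg = length(neg),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped > 0) {
    message(sprintf("per_entity_auc: skipped %d %s(s) without both classes",
                    skipped, axis))
  }
  tab <- do.call(rbind, res)
  abort_if(is.null(tab), "no evaluable %s", axis)
  eval_report(paste0("per-", axis), tab$auc, sum(tab$n_pos), sum(tab$n_neg),
              per_entity = tab)
}

#' k-fold cross-validated AUC
#'
#' Known pairs are partitioned into k seeded folds. Per fold, the DDA
#' matrix is rebuilt from the remaining known pairs; test positives are
#' the held-out fold's scores and test negatives are all unknown pairs,
#' both taken from that fold's matrix. With \code{k = nrow(A)} the scheme
#' reduces to scoring each known pair with itself left out.
#'
#' @inheritParams score_pair
#' @param k number of folds (default 5)
#' @param seed integer seed for the fold assignment
#' @return an \code{eval_report} with per-fold AUC values
#' @export
kfold_cv <- function(I, D, A, k = 5L, mode = c("strict", "pair", "none"),
                     seed = 1L) {
  mode <- match.arg(mode)
  A <- A[A$drug %in% rownames(I) & A$disease %in% rownames(D), , drop = FALSE]
  abort_if(nrow(A) < k, "need at least k = %d known pairs, have %d", k, nrow(A))
  folds <- with_seed(derive_seed(seed, "kfold"),
                     sample(rep_len(seq_len(k), nrow(A))))
  unknown_mask <- matrix(TRUE, nrow(I), nrow(D), dimnames = list(rownames(I), rownames(D)))
  unknown_mask[cbind(A$drug, A$disease)] <- FALSE
  aucs <- vapply(seq_len(k), function(f) {
    test <- A[folds == f, , drop = FALSE]
    train <- A[folds != f, , drop = FALSE]
    abort_if(nrow(test) == 0, "fold %d contains no positives", f)
    S <- score_all(I, D, train, mode)
    pos <- unclass(S)[cbind(test$drug, test$disease)]
    neg <- unclass(S)[unknown_mask]
    rank_auc(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))))
  }, numeric(1))
  eval_report("kfold", aucs, nrow(A), sum(unknown_mask), seed = seed)
}
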