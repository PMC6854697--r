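# Drug-disease association (DDA) scoring.
#
# A candidate pair (i, j) is scored by guilt by association: the maximum
# over known associations (i', j') of the geometric mean
# sqrt(I[i, i'] * D[j, j']) of its drug-side and disease-side fused
# similarities. Eligibility of (i', j') depends on the exclusion mode:
#   strict - i' != i AND j' != j (the printed rule; a drug's own other
#            indications never contribute)
#   pair   - (i', j') != (i, j) (only the evaluated pair itself excluded)
#   none   - every known pair eligible
# Cells with no eligible known pair score 0 and are flagged.

eligible_pairs <- function(A, i, j, mode) {
  switch(mode,
         strict = A[A$drug != i & A$disease != j, , drop = FALSE],
         pair   = A[!(A$drug == i & A$disease == j), , drop = FALSE],
         none   = A)
}

#' Score one drug-disease pair
#'
#' @param i drug id (row of \code{I})
#' @param j disease id (row of \code{D})
#' @param I fused drug-drug (DDSI) matrix
#' @param D fused disease-disease (DiDiS) matrix
#' @param A known associations: data.frame with columns \code{drug},
#'   \code{disease}
#' @param mode exclusion mode, \code{"strict"} (default), \code{"pair"}
#'   or \code{"none"}
#' @return scalar score in [0, 1); attribute \code{flagged} is TRUE when
#'   no known pair was eligible (or every eligible product was negative)
#' @export
score_pair <- function(i, j, I, D, A, mode = c("strict", "pair", "none")) {
  mode <- match.arg(mode)
  abort_if(nrow(A) == 0, "the known association set is empty")
  abort_if(!i %in% rownames(I), "unknown drug id '%s'", i)
  abort_if(!j %in% rownames(D), "unknown disease id '%s'", j)
  el <- eligible_pairs(A, i, j, mode)
  el <- el[el$drug %in% rownames(I) & el$disease %in% colnames(D), , drop = FALSE]
  if (nrow(el) == 0) return(structure(0, flagged = TRUE))
  prods <- I[i, el$drug] * D[j, el$disease]
  if (all(prods < 0)) return(structure(0, flagged = TRUE))
  structure(max(sqrt(pmax(prods, 0))), flagged = FALSE)
}

# brute-force reference: per-cell loop over the association set
score_all_bruteforce <- function(I, D, A, mode = c("strict", "pair", "none")) {
  mode <- match.arg(mode)
  drugs <- rownames(I); diseases <- rownames(D)
  S <- matrix(0, length(drugs), length(diseases), dimnames = list(drugs, diseases))
  for (i in drugs) {
    for (j in diseases) {
      S[i, j] <- as.numeric(score_pair(i, j, I, D, A, mode))
    }
  }
  S
}

#' Score every drug-disease pair
#'
#' Computes the full n x m DDA matrix. The implementation accumulates a
#' running maximum of per-association outer products and then repairs the
#' rows/columns touched by the exclusion rule, and is algebraically
#' identical to scoring each cell with \code{\link{score_pair}}.
#'
#' @inheritParams score_pair
#' @return matrix of class \code{dda_matrix} (drugs x diseases) with
#'   attributes \code{mode} and \code{flagged} (logical matrix marking
#'   cells with no eligible known pair)
#' @export
score_all <- function(I, D, A, mode = c("strict", "pair", "none")) {
  mode <- match.arg(mode)
  check_square_labelled(I, "DDSI")
  check_square_labelled(D, "DiDiS")
  abort_if(nrow(A) == 0, "the known association set is empty")
  A <- A[A$drug %in% rownames(I) & A$disease %in% rownames(D), , drop = FALSE]
  abort_if(nrow(A) == 0, "no known association is resolvable against the matrices")
  drugs <- rownames(I); diseases <- rownames(D)
  sqI <- sqrt(pmax(unclass(I), 0))   # sqrt(I*D) == sqrt(I)*sqrt(D) up to rounding
  sqD <- sqrt(pmax(unclass(D), 0))

  max_over <- function(rows_sub, pairs) {
    # running max of outer(sqI[, i'], sqD[, j']) over the given pairs,
    # restricted to drug rows rows_sub; returns rows x m matrix
    acc <- matrix(-Inf, length(rows_sub), length(diseases))
    for (p in seq_len(nrow(pairs))) {
      acc <- pmax(acc, tcrossprod(sqI[rows_sub, pairs$drug[p]],
                                  sqD[, pairs$disease[p]]))
    }
    acc
  }

  S <- max_over(drugs, A)
  rownames(S) <- drugs; colnames(S) <- diseases
  if (mode == "pair") {
    for (p in seq_len(nrow(A))) {
      i <- A$drug[p]; j <- A$disease[p]
      rest <- A[!(A$drug == i & A$disease == j), , drop = FALSE]
      S[i, j] <- if (nrow(rest) == 0) -Inf else
        max(sqI[i, rest$drug] * sqD[j, rest$disease])
    }
  } else if (mode == "strict") {
    a_drugs <- unique(A$drug); a_dis <- unique(A$disease)
    for (d in a_drugs) {
      keep <- A[A$drug != d, , drop = FALSE]
      S[d, ] <- if (nrow(keep) == 0) -Inf else max_over(d, keep)
    }
    for (e in a_dis) {
      keep <- A[A$disease != e, , drop = FALSE]
      other_rows <- setdiff(drugs, a_drugs)
      if (length(other_rows) > 0) {
        S[other_rows, e] <- if (nrow(keep) == 0) -Inf else
          max_over(other_rows, keep)[, match(e, diseases)]
      }
      for (d in a_drugs) {
        both <- keep[keep$drug != d, , drop = FALSE]
        S[d, e] <- if (nrow(both) == 0) -Inf else
          max(sqI[d, both$drug] * sqD[e, both$disease])
      }
    }
  }
  flagged <- !is.finite(S)
  S[flagged] <- 0
  structure(S, class = c("dda_matrix", "matrix"),
            mode = mode, flagged = flagged)
}

#' @export
print.dda_matrix <- function(x, ...) {
  cat(sprintf("dda_matrix: %d drugs x %d diseases (mode %s, %d flagged cell(s))\n",
              nrow(x), ncol(x), attr(x, "mode"), sum(attr(x, "flagged"))))
  invisible(x)
}
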