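# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately share no code with the package
# implementations they check.

# plain double-loop best-match set similarity; equal cardinalities
# average the two orientations
oracle_set_similarity <- function(P, Q) {
  directed <- function(S, L) {
    total <- 0
    for (i in seq_len(nrow(S))) {
      best <- -Inf
      for (j in seq_len(nrow(L))) {
        u <- S[i, ]; v <- L[j, ]
        best <- max(best, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
      }
      total <- total + best
    }
    total
  }
  if (nrow(P) < nrow(Q)) directed(P, Q)
  else if (nrow(Q) < nrow(P)) directed(Q, P)
  else (directed(P, Q) + directed(Q, P)) / 2
}

# from-scratch triple loop over cells and known pairs
oracle_score_all <- function(I, D, A, mode) {
  S <- matrix(0, nrow(I), nrow(D), dimnames = list(rownames(I), rownames(D)))
  for (i in rownames(I)) {
    for (j in rownames(D)) {
      best <- 0
      for (p in seq_len(nrow(A))) {
        ip <- A$drug[p]; jp <- A$disease[p]
        ok <- switch(mode,
                     strict = ip != i && jp != j,
                     pair   = !(ip == i && jp == j),
                     none   = TRUE)
        if (ok) {
          prod <- I[i, ip] * D[j, jp]
          if (prod >= 0) best <- max(best, sqrt(prod))
        }
      }
      S[i, j] <- best
    }
  }
  S
}

# random symmetric matrix shaped like a fused similarity matrix:
# unit diagonal, off-diagonal strictly inside (0, 1)
random_fused_like <- function(n, prefix = "E") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  r <- matrix(stats::runif(n * n, 0.05, 0.95), n, n)
  m <- (r + t(r)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

# random association set over the given universes
random_assoc <- function(drug_ids, disease_ids, n_pairs) {
  df <- unique(data.frame(drug = sample(drug_ids, n_pairs, replace = TRUE),
                          disease = sample(disease_ids, n_pairs, replace = TRUE),
                          stringsAsFactors = FALSE))
  df[order(df$drug, df$disease), , drop = FALSE]
}

# constant-vector ngram table over a tiny alphabet, for hand-checkable
# embeddings: every k-gram maps to `vec`
constant_ngram_table <- function(vec, k = 3, alphabet = c("A", "B", "C", "D", "E", "F", "G")) {
  tab <- ngram_embedding_table(k = k, dim = length(vec), alphabet = alphabet, seed = 1)
  tab$vectors[] <- rep(vec, each = nrow(tab$vectors))
  tab
}

# tiny expression table: values matrix built from per-sample specs
tiny_expression <- function(values, drug_ids, cell = "CL1", logged = TRUE) {
  meta <- data.frame(sample_id = colnames(values),
                     drug_id = drug_ids,
                     cell_line = cell,
                     replicate = stats::ave(seq_along(drug_ids), drug_ids,
                                            FUN = seq_along),
                     stringsAsFactors = FALSE)
  expression_table(values, meta, logged = logged)
}
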