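# Rank AUC and the leave-one-out / sampled / per-entity / k-fold protocols.

test_that("rank AUC matches closed forms and the Mann-Whitney tie rule", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(rank_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(rank_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(rank_auc(c(1, 2), c(1, 1)), "one positive and one negative")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(60)
  for (rep in 1:5) {
    scores <- c(rnorm(20, 1), rnorm(30))
    labels <- c(rep(1, 20), rep(0, 30))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rank_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("rank AUC is invariant under monotone transforms and complements", {
  set.seed(61)
  scores <- runif(40); labels <- rbinom(40, 1, 0.4)
  if (sum(labels) %in% c(0, 40)) labels[1:2] <- c(0, 1)
  a <- rank_auc(scores, labels)
  expect_equal(rank_auc(exp(3 * scores), labels), a, tolerance = 1e-12)
  expect_equal(a + rank_auc(scores, 1 - labels), 1, tolerance = 1e-12)
})

test_that("label shuffling centers the AUC at one half", {
  set.seed(62)
  scores <- runif(120); labels <- c(rep(1, 40), rep(0, 80))
  aucs <- replicate(500, rank_auc(scores, sample(labels)))
  se <- sd(aucs) / sqrt(500)
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})

test_that("leave-one-out equals naive hide-one rescoring", {
  set.seed(63)
  I <- random_fused_like(8, "d"); D <- random_fused_like(6, "s")
  A <- random_assoc(rownames(I), rownames(D), 9)
  loo <- loo_scores(I, D, A, "strict")
  for (p in seq_len(nrow(A))) {
    naive <- oracle_score_all(I, D, A[-p, , drop = FALSE], "strict")
    expect_equal(loo$known$score[p], naive[A$drug[p], A$disease[p]],
                 tolerance = 1e-12)
  }
  # unknown cells carry the full-set scores
  full <- oracle_score_all(I, D, A, "strict")
  expect_equal(unclass(loo$matrix)[!loo$known_mask], full[!loo$known_mask],
               tolerance = 1e-12)
  # with exactly two pairs each known score uses only the other pair
  A2 <- A[1:2, ]
  loo2 <- loo_scores(I, D, A2, "strict")
  expect_equal(loo2$known$score[1],
               as.numeric(score_pair(A2$drug[1], A2$disease[1], I, D,
                                     A2[2, , drop = FALSE], "strict")),
               tolerance = 1e-12)
})

test_that("sampling the whole matrix once reproduces the full AUC", {
  set.seed(64)
  I <- random_fused_like(7, "d"); D <- random_fused_like(7, "s")
  A <- random_assoc(rownames(I), rownames(D), 8)
  loo <- loo_scores(I, D, A, "strict")
  rep1 <- sampled_auc(loo, fraction = 1.0, repeats = 1, seed = 3)
  expect_equal(rep1$auc_mean, loo_full_auc(loo), tolerance = 1e-12)

  r1 <- sampled_auc(loo, fraction = 0.5, repeats = 20, seed = 11)
  r2 <- sampled_auc(loo, fraction = 0.5, repeats = 20, seed = 11)
  expect_identical(r1$auc_values, r2$auc_values)
  # repeated subsampling stays near the full-set AUC
  se <- sd(r1$auc_values) / sqrt(20)
  expect_lt(abs(r1$auc_mean - loo_full_auc(loo)), 3 * se + 0.05)
})

test_that("per-entity AUC ranks within rows or columns and skips degenerates", {
  ids_i <- sprintf("d%d", 1:5); ids_j <- c("s1", "s2")
  I <- matrix(0.2, 5, 5, dimnames = list(ids_i, ids_i)); diag(I) <- 1
  I["d1", "d2"] <- I["d2", "d1"] <- 0.9
  D <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(ids_j, ids_j))
  # d1 <-> s1 known via similar drug d2 also associated with s2's neighbour
  A <- data.frame(drug = c("d1", "d2"), disease = c("s1", "s2"))
  loo <- loo_scores(I, D, A, "strict")
  rep_d <- suppressMessages(per_entity_auc(loo, "disease"))
  expect_true(all(rep_d$per_entity$auc >= 0 & rep_d$per_entity$auc <= 1))
  # the known drug of s1 outranks every unassociated drug
  s1 <- rep_d$per_entity[rep_d$per_entity$entity == "s1", ]
  expect_equal(s1$auc, 1)

  # an entity with no positives is skipped, not counted
  expect_message(per_entity_auc(loo, "drug"), "skipped")
})

test_that("random scores give per-entity means near one half", {
  set.seed(65)
  I <- random_fused_like(25, "d"); D <- random_fused_like(12, "s")
  # random associations carry no structure
  A <- random_assoc(rownames(I), rownames(D), 40)
  loo <- loo_scores(I, D, A, "strict")
  rep_d <- suppressMessages(per_entity_auc(loo, "disease"))
  expect_lt(abs(rep_d$auc_mean - 0.5), 0.15)
})

test_that("k-fold folds are seeded and k = |A| reduces to per-pair leave-one-out", {
  set.seed(66)
  I <- random_fused_like(8, "d"); D <- random_fused_like(6, "s")
  A <- random_assoc(rownames(I), rownames(D), 7)
  r1 <- kfold_cv(I, D, A, k = 3, seed = 5)
  r2 <- kfold_cv(I, D, A, k = 3, seed = 5)
  expect_identical(r1$auc_values, r2$auc_values)

  # naive per-pair scheme: each pair held out, negatives rescored without it
  r_loo <- kfold_cv(I, D, A, k = nrow(A), seed = 9)
  unknown <- matrix(TRUE, 8, 6, dimnames = list(rownames(I), rownames(D)))
  unknown[cbind(A$drug, A$disease)] <- FALSE
  naive <- vapply(seq_len(nrow(A)), function(p) {
    S <- oracle_score_all(I, D, A[-p, , drop = FALSE], "strict")
    rank_auc(c(S[A$drug[p], A$disease[p]], S[unknown]),
             c(1, rep(0, sum(unknown))))
  }, numeric(1))
  expect_equal(sort(r_loo$auc_values), sort(naive), tolerance = 1e-12)
})
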