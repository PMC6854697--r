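# Synthetic generators: determinism, planted structure, file round trips.

test_that("zero noise collapses each cluster to identical entities", {
  co <- generate_cohort(n_drugs = 12, m_diseases = 8, n_clusters = 3,
                        assoc_per_cluster = 4, noise_sd = 0, seed = 2)
  for (c in 1:3) {
    drugs <- names(co$clusters$drug)[co$clusters$drug == c]
    expect_equal(length(unique(co$smiles[drugs])), 1)
    expect_equal(length(unique(vapply(co$targets[drugs], paste, "", collapse = "|"))), 1)
    dg <- compute_dgep_matrix(co$expression, drugs)
    expect_lt(max(abs(sweep(dg, 2, dg[1, ]))), 1e-12)
    dis <- names(co$clusters$disease)[co$clusters$disease == c]
    expect_equal(length(unique(vapply(co$phenotype_annotations[dis],
                                      paste, "", collapse = "|"))), 1)
  }
})

test_that("the same seed reproduces the cohort files byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(n_drugs = 10, m_diseases = 6, n_clusters = 2,
                  assoc_per_cluster = 3, noise_sd = 0.1, seed = 42, dir = d1)
  generate_cohort(n_drugs = 10, m_diseases = 6, n_clusters = 2,
                  assoc_per_cluster = 3, noise_sd = 0.1, seed = 42, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("cohort files parse through the package readers", {
  d <- withr::local_tempdir()
  co <- generate_cohort(n_drugs = 10, m_diseases = 6, n_clusters = 2,
                        assoc_per_cluster = 3, noise_sd = 0.1, seed = 3, dir = d)
  expect_identical(read_smiles_table(co$files$smiles), co$smiles)
  expect_identical(read_grouped_fasta(co$files$targets), co$targets[
    order(names(co$targets))])
  expect_equal(read_expression_table(co$files$expression, co$files$expression_meta,
                                     logged = TRUE)$values,
               co$expression$values, tolerance = 1e-12)
  expect_identical(read_associations(co$files$associations), co$associations)
  ann <- read_term_annotations(co$files$phenotype)
  expect_identical(ann$DI001, co$phenotype_annotations$DI001)
})

test_that("planted associations stay within clusters and near-regular degrees", {
  co <- generate_cohort(n_drugs = 40, m_diseases = 20, n_clusters = 4,
                        assoc_per_cluster = 20, noise_sd = 0.1, seed = 5)
  A <- co$associations
  expect_true(all(co$clusters$drug[A$drug] == co$clusters$disease[A$disease]))
  deg <- table(A$drug)
  expect_lte(max(deg) - min(deg), 2)
  expect_error(generate_cohort(n_drugs = 4, m_diseases = 4, n_clusters = 5),
               "n_clusters")
})

test_that("low-rank expression has the planted spectrum and replicate noise", {
  e0 <- generate_lowrank_expression(n_genes = 40, n_samples_per_condition = 2,
                                    rank = 3, noise_sd = 0, seed = 9,
                                    n_conditions = 10)
  sv <- svd(e0$values)$d
  expect_lt(sv[4], 1e-9)
  # replicates of a condition are identical at zero noise
  expect_equal(e0$values[, "DR001_1"], e0$values[, "DR001_2"], tolerance = 1e-12)

  e1 <- generate_lowrank_expression(n_genes = 40, n_samples_per_condition = 2,
                                    rank = 3, noise_sd = 0.05, seed = 9,
                                    n_conditions = 10)
  diff <- e1$values[, "DR001_1"] - e1$values[, "DR001_2"]
  expect_lt(sd(diff), 4 * 0.05 * sqrt(2))
  expect_gt(sd(diff), 0)

  # PCA with the planted rank reconstructs to the noise floor
  X <- t(e1$values)
  mu <- colMeans(X)
  V <- svd(sweep(X, 2, mu), nu = 0, nv = 3)$v
  rec <- sweep(sweep(X, 2, mu) %*% V %*% t(V), 2, mu, `+`)
  expect_lt(mean((rec - X)^2), 0.05^2)
  expect_error(generate_lowrank_expression(n_genes = 2, rank = 10), "infeasible")
})

test_that("random sequences respect lengths, seeding and the FASTA dialect", {
  tf <- withr::local_tempfile()
  s1 <- generate_random_sequences(5, c(10, 20), seed = 4, path = tf)
  expect_length(s1, 5)
  expect_true(all(nchar(s1) >= 10 & nchar(s1) <= 20))
  s2 <- generate_random_sequences(5, c(10, 20), seed = 4)
  expect_identical(s1, s2)
  back <- read_grouped_fasta(tf)
  expect_equal(length(unlist(back)), 5)
  expect_error(generate_random_sequences(3, c(1, 2)), ">= 3")

  mono <- generate_random_sequences(3, c(9, 9), alphabet = "A", seed = 1)
  tab <- ngram_embedding_table(k = 3, dim = 6, alphabet = c("A", "C"), seed = 1)
  v <- lapply(mono, embed_protein_sequence, table = tab)
  expect_equal(cosine(v[[1]], v[[2]]), 1, tolerance = 1e-12)
})
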