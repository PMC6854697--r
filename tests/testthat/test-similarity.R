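# Cosine matrices, best-match set similarity, min-max fusion, DDSI/DiDiS.

test_that("cosine matches its closed forms and rejects bad input", {
  expect_equal(cosine(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine(c(1, 1), c(1, 0)), 0.7071067812, tolerance = 1e-9)
  expect_error(cosine(c(1, 0), c(0, 0)), "zero vector")
  expect_error(cosine(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("vector feature matrices equal the pairwise loop", {
  m <- vector_feature_matrix(rbind(A = c(1, 0), B = c(0, 1)))
  expect_equal(unclass(m), diag(2), ignore_attr = TRUE)

  dup <- vector_feature_matrix(rbind(A = c(1, 2), B = c(2, 4)))
  expect_equal(dup["A", "B"], 1, tolerance = 1e-12)

  set.seed(40)
  V <- matrix(rnorm(15), 3, 5, dimnames = list(c("A", "B", "C"), NULL))
  M <- vector_feature_matrix(V, "g")
  for (i in 1:3) for (j in 1:3) {
    expect_equal(M[i, j], cosine(V[i, ], V[j, ]), tolerance = 1e-12)
  }
  expect_error(vector_feature_matrix(rbind(A = c(0, 0), B = c(1, 0))), "A")
})

test_that("set similarity sums the smaller set's best matches", {
  expect_equal(set_similarity(rbind(c(1, 0)), rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(set_similarity(rbind(c(1, 0), c(0, 1)),
                              rbind(c(1, 0), c(0, 1), c(0.7071, 0.7071))), 2,
               tolerance = 1e-9)
  expect_equal(set_similarity(rbind(c(1, 0)), rbind(c(0, 1))), 0)
  expect_error(set_similarity(rbind(c(1, 0)), matrix(numeric(), 0, 2)), "nonempty")
})

test_that("set similarity is symmetric and matches the enumeration oracle", {
  set.seed(41)
  for (rep in 1:40) {
    P <- matrix(rnorm(sample(1:4, 1) * 3), ncol = 3)
    Q <- matrix(rnorm(sample(1:4, 1) * 3), ncol = 3)
    expect_equal(set_similarity(P, Q), set_similarity(Q, P), tolerance = 1e-12)
    expect_equal(set_similarity(P, Q), oracle_set_similarity(P, Q), tolerance = 1e-12)
  }
  # equal-cardinality tie resolves to the first argument but stays symmetric
  P <- matrix(rnorm(6), 2, 3); Q <- matrix(rnorm(6), 2, 3)
  expect_equal(set_similarity(P, Q), set_similarity(Q, P), tolerance = 1e-12)
})

test_that("set feature matrix has |P_i| on the raw diagonal", {
  sets <- list(D1 = rbind(c(1, 0), c(0, 1)), D2 = rbind(c(1, 1)))
  M <- set_feature_matrix(sets, "p")
  expect_equal(M["D1", "D1"], 2, tolerance = 1e-12)

  same <- list(A = rbind(c(1, 2)), B = rbind(c(2, 4)), C = rbind(c(0.5, 1)))
  expect_equal(unclass(set_feature_matrix(same)), matrix(1, 3, 3),
               ignore_attr = TRUE, tolerance = 1e-12)

  set.seed(42)
  rnd <- lapply(1:4, function(i) matrix(rnorm(sample(1:3, 1) * 4), ncol = 4))
  names(rnd) <- paste0("D", 1:4)
  M <- set_feature_matrix(rnd)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(M[i, j], oracle_set_similarity(rnd[[i]], rnd[[j]]), tolerance = 1e-12)
  }
})

test_that("min-max fusion reproduces the worked three-value example", {
  # off-diagonal sums {0.2, 0.5, 0.8}: min_const 0.19, max_const 0.81
  m <- matrix(c(1, 0.2, 0.5,
                0.2, 1, 0.8,
                0.5, 0.8, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  f <- fuse_minmax(list(m))
  expect_equal(attr(f, "min_const"), 0.19, tolerance = 1e-12)
  expect_equal(attr(f, "max_const"), 0.81, tolerance = 1e-12)
  expect_equal(f["a", "b"], 0.01 / 0.62, tolerance = 1e-12)   # prints 0.0161290323
  expect_equal(f["a", "c"], 0.5, tolerance = 1e-12)
  expect_equal(f["b", "c"], 0.61 / 0.62, tolerance = 1e-12)   # prints 0.9838709677
  expect_equal(round(c(f["a", "b"], f["b", "c"]), 10),
               c(0.0161290323, 0.9838709677))
  expect_equal(unname(diag(f)), rep(1, 3))
})

test_that("degenerate fusions map off-diagonals to one half", {
  m <- matrix(0.3, 3, 3, dimnames = list(letters[1:3], letters[1:3])); diag(m) <- 1
  f <- fuse_minmax(list(m))
  expect_equal(unique(f[row(f) != col(f)]), 0.5, tolerance = 1e-12)

  set.seed(43)
  r <- matrix(rnorm(9), 3, 3); r <- (r + t(r)) / 2
  dimnames(r) <- list(letters[1:3], letters[1:3])
  f2 <- fuse_minmax(list(r, -r))                 # sums to zero off-diagonal
  expect_equal(unique(round(f2[row(f2) != col(f2)], 12)), 0.5)

  two <- matrix(c(1, 0.4, 0.4, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(f3 <- fuse_minmax(list(two)), "0.5")
  expect_equal(f3["a", "b"], 0.5, tolerance = 1e-12)
})

test_that("fusion invariants hold on random matrices", {
  set.seed(44)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    mats <- lapply(1:sample(1:3, 1), function(i) {
      r <- matrix(rnorm(n * n), n, n); r <- (r + t(r)) / 2
      dimnames(r) <- list(sprintf("e%d", 1:n), sprintf("e%d", 1:n)); r
    })
    f <- fuse_minmax(mats)
    off <- f[row(f) != col(f)]
    expect_true(all(off > 0 & off < 1))
    expect_equal(unname(diag(f)), rep(1, n))
    expect_equal(unclass(f), t(unclass(f)), tolerance = 1e-12, ignore_attr = TRUE)
    # extreme fused values follow from the +-0.01 construction
    S <- Reduce(`+`, mats); soff <- S[row(S) != col(S)]
    rng <- max(soff) - min(soff)
    expect_equal(min(off), 0.01 / (rng + 0.02), tolerance = 1e-9)
    expect_equal(max(off), (rng + 0.01) / (rng + 0.02), tolerance = 1e-9)
    # invariance to adding a constant to every off-diagonal sum
    shifted <- lapply(mats, function(m) { m2 <- m + 0.37; m2 })
    f2 <- fuse_minmax(shifted)
    expect_equal(unclass(f2)[row(f2) != col(f2)], off, tolerance = 1e-9)
  }
})

test_that("DDSI restricts to drugs carrying every requested feature", {
  set.seed(45)
  smiles <- matrix(rnorm(12), 3, 4, dimnames = list(c("D1", "D2", "D3"), NULL))
  dgep <- matrix(rnorm(8), 2, 4, dimnames = list(c("D1", "D2"), NULL))
  prof <- drug_profiles(smiles = smiles, dgep = dgep)

  f_s <- suppressMessages(build_ddsi(prof, "s"))
  expect_equal(dim(f_s), c(3, 3))
  suppressWarnings(
    expect_message(f_sg <- build_ddsi(prof, c("s", "g")), "retained 2 of 3"))
  expect_equal(dim(f_sg), c(2, 2))
  expect_error(build_ddsi(drug_profiles(), "s"), "no drugs carry")
})

test_that("DDSI equals the hand-composed fusion of its feature matrices", {
  set.seed(46)
  ids <- c("D1", "D2", "D3", "D4")
  smiles <- matrix(rnorm(16), 4, 4, dimnames = list(ids, NULL))
  dgep <- matrix(rnorm(12), 4, 3, dimnames = list(ids, NULL))
  sets_p <- lapply(ids, function(i) matrix(rnorm(6), 2, 3)); names(sets_p) <- ids
  sets_e <- lapply(ids, function(i) matrix(rnorm(3), 1, 3)); names(sets_e) <- ids
  prof <- drug_profiles(smiles = smiles, targets = sets_p,
                        enzymes = sets_e, dgep = dgep)
  got <- build_ddsi(prof, c("s", "p", "e", "g"))
  manual <- fuse_minmax(list(vector_feature_matrix(smiles, "s"),
                             set_feature_matrix(sets_p, "p"),
                             set_feature_matrix(sets_e, "e"),
                             vector_feature_matrix(dgep, "g")))
  expect_equal(unclass(got), unclass(manual), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("DiDiS fuses phenotype and genotype over the common diseases", {
  set.seed(47)
  ids <- sprintf("S%d", 1:5)
  ph <- matrix(rnorm(15), 5, 3, dimnames = list(ids, NULL))
  gt <- matrix(rnorm(10), 5, 2, dimnames = list(ids, NULL))
  got <- build_didis(ph, gt)
  manual <- fuse_minmax(list(vector_feature_matrix(ph, "a"),
                             vector_feature_matrix(gt, "d")), kind = "DiDiS")
  expect_equal(unclass(got), unclass(manual), tolerance = 1e-12, ignore_attr = TRUE)

  two <- build_didis(ph[1:2, ], gt[1:2, ]) |> suppressWarnings()
  expect_equal(two["S1", "S2"], 0.5, tolerance = 1e-12)
})
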