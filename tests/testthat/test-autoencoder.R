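# Auto-encoder: configuration contracts, reproducibility, PCA equivalence
# of the linear network, and hyper-parameter search.

test_that("config validation enforces the symmetric bottleneck shape", {
  expect_error(autoencoder_config(layer_units = c(32, 16)), "odd number")
  expect_error(autoencoder_config(layer_units = c(8, 16, 8)), "smallest width")
  expect_error(autoencoder_config(layer_units = c(32, 8, 16)), "smallest width|symmetric")
  expect_error(autoencoder_config(learning_rate = 0), "positive")
  expect_error(autoencoder_config(activations = "tanh"), "unknown activation")
  cfg <- autoencoder_config(layer_units = c(16, 4, 16))
  expect_s3_class(cfg, "autoencoder_config")
})

test_that("a bottleneck at least as wide as the input is rejected", {
  X <- matrix(rnorm(120), 12, 10, dimnames = list(NULL, paste0("g", 1:10)))
  cfg <- autoencoder_config(layer_units = c(16, 10, 16), epochs = 1)
  expect_error(train_dgep_autoencoder(X, cfg), "bottleneck width")
})

test_that("training is reproducible given (seed, config)", {
  set.seed(20)
  X <- matrix(rnorm(30 * 12), 30, 12, dimnames = list(NULL, paste0("g", 1:12)))
  cfg <- autoencoder_config(layer_units = c(8, 3, 8), activations = "elu",
                            epochs = 10, batch_size = 8, seed = 99)
  m1 <- train_dgep_autoencoder(X, cfg)
  m2 <- train_dgep_autoencoder(X, cfg)
  expect_lt(abs(m1$mse$train - m2$mse$train), 1e-8)
  expect_equal(m1$W, m2$W, tolerance = 1e-12)
})

test_that("full-batch training loss is non-increasing on a linear toy", {
  set.seed(21)
  U <- matrix(rnorm(40 * 2), 40, 2); V <- matrix(rnorm(2 * 8), 2, 8)
  X <- U %*% V + matrix(rnorm(320, sd = 0.05), 40, 8)
  colnames(X) <- paste0("g", 1:8)
  cfg <- autoencoder_config(layer_units = c(6, 2, 6), activations = "linear",
                            epochs = 40, batch_size = 1000,   # full batch
                            learning_rate = 2e-4, pretrain = "none", seed = 4)
  m <- train_dgep_autoencoder(X, cfg)
  expect_true(all(diff(m$epoch_loss) <= 1e-8))
})

test_that("a linear auto-encoder attains the PCA reconstruction error", {
  expr <- generate_lowrank_expression(n_genes = 30, n_samples_per_condition = 2,
                                      rank = 3, noise_sd = 0.02, seed = 6,
                                      n_conditions = 29)
  X <- t(expr$values)                       # 60 samples x 30 genes
  cfg <- autoencoder_config(layer_units = c(10, 3, 10), activations = "linear",
                            epochs = 30, batch_size = 16, seed = 17)
  m <- train_dgep_autoencoder(X, cfg)
  # SVD oracle on the training rows, evaluated on the test rows
  tr <- X[m$split_index$train, , drop = FALSE]
  te <- X[m$split_index$test, , drop = FALSE]
  mu <- colMeans(tr)
  V <- svd(sweep(tr, 2, mu), nu = 0, nv = 3)$v
  rec <- sweep(sweep(te, 2, mu) %*% V %*% t(V), 2, mu, `+`)
  pca_mse <- mean((rec - te)^2)
  expect_lt(m$mse$test, 1.10 * pca_mse)
})

test_that("the bottleneck encoding has the configured width and fixed gene order", {
  set.seed(23)
  X <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(NULL, paste0("g", 1:30)))
  cfg <- autoencoder_config(layer_units = c(24, 20, 24), activations = "linear",
                            epochs = 3, seed = 2)
  m <- train_dgep_autoencoder(X, cfg)
  z <- encode_dgep(m, X[1, ])
  expect_length(z, 20)
  permuted <- X[1, c(2:30, 1)]
  expect_error(encode_dgep(m, permuted), "gene order")
})

test_that("encoded training rows reconstruct at the reported training loss", {
  set.seed(24)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("g", 1:10)))
  cfg <- autoencoder_config(layer_units = c(8, 4, 8), activations = "linear",
                            epochs = 15, seed = 31)
  m <- train_dgep_autoencoder(X, cfg)
  tr <- X[m$split_index$train, , drop = FALSE]
  rec <- reposim:::mlp_reconstruct(m, tr)
  expect_equal(mean((rec - tr)^2), m$mse$train, tolerance = 1e-10)
})

test_that("random search returns the single config of a singleton space", {
  set.seed(25)
  X <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("g", 1:8)))
  res <- search_hyperparameters(X, list(layer_units = list(c(6, 2, 6)),
                                        activations = "linear",
                                        batch_size = 8, epochs = 3),
                                n_iter = 10, seed = 5)
  expect_equal(nrow(res$trials), 1)
  expect_equal(res$best_config$layer_units, c(6L, 2L, 6L))
})

test_that("search prefers a bottleneck wide enough for the planted rank", {
  expr <- generate_lowrank_expression(n_genes = 12, n_samples_per_condition = 2,
                                      rank = 3, noise_sd = 0.01, seed = 8,
                                      n_conditions = 19)
  X <- t(expr$values)
  res <- search_hyperparameters(X, list(layer_units = list(c(8, 1, 8), c(8, 4, 8)),
                                        activations = "linear",
                                        batch_size = 16, epochs = 10),
                                n_iter = 6, seed = 7)
  expect_equal(min(res$best_config$layer_units), 4)
  # identical seed reproduces the identical trial sequence
  res2 <- search_hyperparameters(X, list(layer_units = list(c(8, 1, 8), c(8, 4, 8)),
                                         activations = "linear",
                                         batch_size = 16, epochs = 10),
                                 n_iter = 6, seed = 7)
  expect_identical(res$trials, res2$trials)
})
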