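# Stacked auto-encoder for dGEP dimensionality reduction.
#
# A symmetric feed-forward auto-encoder (five hidden layers by default,
# bottleneck 20) trained with mean-squared-error loss and the nadam
# optimiser (adaptive moments with Nesterov momentum, learning rate 0.001).
# Weights are optionally initialised by greedy layer-wise spectral
# pretraining: each encoder layer starts at the principal-subspace
# projection of its input and each decoder layer at the transposed
# back-projection, the classical stacked-auto-encoder initialisation,
# which for all-linear activations starts the network at the PCA optimum
# before fine-tuning. All randomness (splits, weight noise, minibatch
# shuffles) derives from the config seed, so training is reproducible.

activation_fns <- list(
  relu = list(
    f = function(x) pmax(x, 0),
    df = function(x) (x > 0) * 1
  ),
  linear = list(
    f = function(x) x,
    df = function(x) array(1, dim = dim(x))
  ),
  softplus = list(
    f = function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
    df = function(x) 1 / (1 + exp(-x))
  ),
  elu = list(
    f = function(x) ifelse(x > 0, x, expm1(pmin(x, 0))),
    df = function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
  )
)

#' Configure the dGEP auto-encoder
#'
#' @param layer_units hidden-layer widths; must be an odd-length symmetric
#'   vector with its minimum (the bottleneck) in the middle. Default
#'   \code{c(512, 64, 20, 64, 512)}.
#' @param activations activation name(s) from \code{"relu"},
#'   \code{"linear"}, \code{"softplus"}, \code{"elu"}; a scalar is
#'   recycled over the hidden layers. The output layer is always linear.
#' @param batch_size minibatch size
#' @param epochs fine-tuning epochs
#' @param learning_rate nadam learning rate (default 0.001)
#' @param pretrain \code{"spectral"} (greedy layer-wise principal-subspace
#'   initialisation, the default) or \code{"none"} (seeded Glorot noise)
#' @param seed integer seed controlling splits, initialisation and
#'   shuffling
#' @return object of class \code{autoencoder_config}
#' @export
autoencoder_config <- function(layer_units = c(512L, 64L, 20L, 64L, 512L),
                               activations = "relu",
                               batch_size = 32L,
                               epochs = 100L,
                               learning_rate = 0.001,
                               pretrain = c("spectral", "none"),
                               seed = 1L) {
  pretrain <- match.arg(pretrain)
  nh <- length(layer_units)
  abort_if(nh %% 2 == 0, "layer_units must have an odd number of layers")
  mid <- (nh + 1) %/% 2
  abort_if(layer_units[mid] != min(layer_units),
           "the smallest width must sit at the middle (bottleneck) layer")
  abort_if(!identical(as.integer(layer_units), as.integer(rev(layer_units))),
           "layer_units must be symmetric about the bottleneck")
  if (length(activations) == 1) activations <- rep(activations, nh)
  abort_if(length(activations) != nh,
           "need one activation per hidden layer (or a single one recycled)")
  abort_if(!all(activations %in% names(activation_fns)),
           "unknown activation(s): %s",
           paste(setdiff(activations, names(activation_fns)), collapse = ", "))
  abort_if(learning_rate <= 0, "learning_rate must be positive")
  structure(list(layer_units = as.integer(layer_units),
                 activations = activations,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 pretrain = pretrain,
                 seed = as.integer(seed)),
            class = "autoencoder_config")
}

# forward pass; returns list of pre-activations Z and activations H
mlp_forward <- function(X, W, b, acts) {
  H <- vector("list", length(W) + 1)
  Z <- vector("list", length(W))
  H[[1]] <- X
  for (l in seq_along(W)) {
    Z[[l]] <- sweep(H[[l]] %*% W[[l]], 2, b[[l]], `+`)
    H[[l + 1]] <- activation_fns[[acts[l]]]$f(Z[[l]])
  }
  list(H = H, Z = Z)
}

mlp_reconstruct <- function(model, X) {
  mlp_forward(X, model$W, model$b, model$acts)$H[[length(model$W) + 1]]
}

mse <- function(A, B) mean((A - B)^2)

# Glorot-uniform initialisation
init_weights <- function(widths, seed) {
  with_seed(seed, {
    W <- b <- vector("list", length(widths) - 1)
    for (l in seq_len(length(widths) - 1)) {
      lim <- sqrt(6 / (widths[l] + widths[l + 1]))
      W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1], -lim, lim),
                       widths[l], widths[l + 1])
      b[[l]] <- numeric(widths[l + 1])
    }
    list(W = W, b = b)
  })
}

# Greedy layer-wise spectral pretraining: encoder layer l projects onto the
# leading principal directions of its (forward-propagated) input; the
# mirrored decoder layer is its transpose plus the stored column means.
spectral_pretrain <- function(X, W, b, acts) {
  nh <- length(W) - 1          # hidden layers
  mid <- (nh + 1) %/% 2
  H <- X
  for (l in seq_len(mid)) {
    mu <- colMeans(H)
    C <- sweep(H, 2, mu)
    k <- ncol(W[[l]])
    r <- min(k, dim(C))
    V <- svd(C, nu = 0, nv = r)$v
    Wl <- matrix(0, ncol(H), k)
    Wl[, seq_len(r)] <- V
    W[[l]] <- Wl
    b[[l]] <- as.numeric(-crossprod(Wl, mu))
    dec <- length(W) + 1 - l   # mirrored decoder layer
    W[[dec]] <- t(Wl)
    b[[dec]] <- mu
    H <- activation_fns[[acts[l]]]$f(sweep(H %*% Wl, 2, b[[l]], `+`))
  }
  list(W = W, b = b)
}

# one nadam step over a list of parameter arrays
nadam_step <- function(theta, grad, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(theta)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grad[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grad[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^t)
    vhat <- state$v[[i]] / (1 - beta2^t)
    nes <- beta1 * mhat + (1 - beta1) * grad[[i]] / (1 - beta1^t)
    theta[[i]] <- theta[[i]] - lr * nes / (sqrt(vhat) + eps)
  }
  list(theta = theta, state = state)
}

#' Train the dGEP auto-encoder
#'
#' Rows of \code{dgeps} are observations (drugs), columns are genes. The
#' rows are split into training, validation and test subsets (default
#' 60/15/25), the network is fine-tuned with minibatch nadam on MSE, and
#' train/validation/test MSE are reported. Training aborts with
#' diagnostics if the loss becomes non-finite.
#'
#' @param dgeps numeric matrix drugs x genes (>= 10 rows) with column
#'   names (the gene order the model is bound to)
#' @param config an \code{\link{autoencoder_config}}
#' @param split fractions for train/validation/test; must sum to 1
#' @return object of class \code{dgep_autoencoder} with elements
#'   \code{W}, \code{b}, \code{acts}, \code{config}, \code{gene_names},
#'   \code{epoch_loss} (full-training-set MSE after each epoch) and
#'   \code{mse} (list train/val/test)
#' @export
train_dgep_autoencoder <- function(dgeps, config = autoencoder_config(),
                                   split = c(0.60, 0.15, 0.25)) {
  abort_if(!is.matrix(dgeps) || nrow(dgeps) < 10,
           "dgeps must be a matrix with at least 10 rows")
  abort_if(abs(sum(split) - 1) > 1e-9, "split fractions must sum to 1")
  p <- ncol(dgeps)
  bottleneck <- min(config$layer_units)
  abort_if(bottleneck >= p,
           "bottleneck width %d must be smaller than the input width %d",
           bottleneck, p)

  idx <- with_seed(derive_seed(config$seed, "split"), sample.int(nrow(dgeps)))
  n_tr <- max(1L, floor(split[1] * nrow(dgeps)))
  n_va <- max(1L, floor(split[2] * nrow(dgeps)))
  tr <- idx[seq_len(n_tr)]
  va <- idx[n_tr + seq_len(n_va)]
  te <- idx[-seq_len(n_tr + n_va)]
  Xtr <- dgeps[tr, , drop = FALSE]

  widths <- c(p, config$layer_units, p)
  acts <- c(config$activations, "linear")
  par <- init_weights(widths, derive_seed(config$seed, "init"))
  if (config$pretrain == "spectral") {
    par <- spectral_pretrain(Xtr, par$W, par$b, acts)
  }
  W <- par$W; b <- par$b
  zero_like <- function(x) lapply(x, function(a) array(0, dim = dim(a) %||% length(a)))
  st_W <- list(m = zero_like(W), v = zero_like(W))
  st_b <- list(m = lapply(b, function(x) numeric(length(x))),
               v = lapply(b, function(x) numeric(length(x))))

  n <- nrow(Xtr)
  bs <- min(config$batch_size, n)
  epoch_loss <- numeric(config$epochs)
  t_step <- 0L
  shuffle_seed <- derive_seed(config$seed, "shuffle")
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(shuffle_seed + epoch, sample.int(n))
    for (start in seq(1L, n, by = bs)) {
      batch <- ord[start:min(start + bs - 1L, n)]
      X <- Xtr[batch, , drop = FALSE]
      fw <- mlp_forward(X, W, b, acts)
      Y <- fw$H[[length(W) + 1]]
      dH <- 2 * (Y - X) / length(X)
      gW <- vector("list", length(W)); gb <- vector("list", length(W))
      for (l in rev(seq_along(W))) {
        dZ <- dH * activation_fns[[acts[l]]]$df(fw$Z[[l]])
        gW[[l]] <- crossprod(fw$H[[l]], dZ)
        gb[[l]] <- colSums(dZ)
        if (l > 1) dH <- tcrossprod(dZ, W[[l]])
      }
      t_step <- t_step + 1L
      up <- nadam_step(W, gW, st_W, config$learning_rate, t_step)
      W <- up$theta; st_W <- up$state
      up <- nadam_step(b, gb, st_b, config$learning_rate, t_step)
      b <- up$theta; st_b <- up$state
    }
    model_now <- list(W = W, b = b, acts = acts)
    epoch_loss[epoch] <- mse(mlp_reconstruct(model_now, Xtr), Xtr)
    if (!is.finite(epoch_loss[epoch])) {
      stop(sprintf(paste0("auto-encoder loss became non-finite at epoch %d ",
                          "(lr = %g, batch_size = %d); lower the learning rate"),
                   epoch, config$learning_rate, bs), call. = FALSE)
    }
  }

  model <- structure(list(W = W, b = b, acts = acts, config = config,
                          gene_names = colnames(dgeps),
                          split_index = list(train = tr, validation = va, test = te),
                          epoch_loss = epoch_loss),
                     class = "dgep_autoencoder")
  model$mse <- list(
    train = mse(mlp_reconstruct(model, Xtr), Xtr),
    validation = if (length(va) > 0)
      mse(mlp_reconstruct(model, dgeps[va, , drop = FALSE]),
          dgeps[va, , drop = FALSE]) else NA_real_,
    test = if (length(te) > 0)
      mse(mlp_reconstruct(model, dgeps[te, , drop = FALSE]),
          dgeps[te, , drop = FALSE]) else NA_real_)
  model
}

#' @export
print.dgep_autoencoder <- function(x, ...) {
  cat(sprintf("dgep_autoencoder: %s (bottleneck %d), %d epochs\n",
              paste(x$config$layer_units, collapse = "-"),
              min(x$config$layer_units), x$config$epochs))
  cat(sprintf("  MSE  train %.5g  validation %.5g  test %.5g\n",
              x$mse$train, x$mse$validation, x$mse$test))
  invisible(x)
}

#' Encode dGEPs through the trained bottleneck
#'
#' Runs the encoder half of a trained auto-encoder and returns the
#' bottleneck activations (20-dimensional under the default
#' architecture). Gene order must match training; a named input in a
#' different order is an error rather than silently remapped.
#'
#' @param model a trained \code{dgep_autoencoder}
#' @param dgep numeric vector over genes, or a drugs x genes matrix
#' @return numeric vector (or matrix) of bottleneck activations
#' @export
encode_dgep <- function(model, dgep) {
  X <- if (is.matrix(dgep)) dgep else matrix(dgep, nrow = 1,
                                             dimnames = list(NULL, names(dgep)))
  abort_if(ncol(X) != length(model$gene_names),
           "input has %d genes, model expects %d", ncol(X), length(model$gene_names))
  if (!is.null(colnames(X)) && !is.null(model$gene_names)) {
    abort_if(!identical(colnames(X), model$gene_names),
             "gene order differs from the model's training order")
  }
  mid <- (length(model$W)) %/% 2   # encoder layers end at the bottleneck
  H <- X
  for (l in seq_len(mid)) {
    H <- activation_fns[[model$acts[l]]]$f(sweep(H %*% model$W[[l]], 2, model$b[[l]], `+`))
  }
  if (is.matrix(dgep)) H else as.numeric(H)
}

#' Seeded random search over auto-encoder hyper-parameters
#'
#' Samples \code{n_iter} configurations from the given grids, trains each
#' and returns the one with the smallest validation MSE, plus the full
#' trial log. If the space contains a single distinct configuration it is
#' evaluated once.
#'
#' @param dgeps drugs x genes matrix
#' @param search_space list with elements \code{layer_units} (list of
#'   width vectors), \code{activations} (vector of activation names) and
#'   \code{batch_size} (integer vector); optionally \code{epochs} and
#'   \code{learning_rate}
#' @param n_iter number of sampled configurations
#' @param seed integer seed for the sampling sequence and trial training
#' @param split passed to \code{\link{train_dgep_autoencoder}}
#' @return list with \code{best_config}, \code{best_model} and
#'   \code{trials} (data.frame log)
#' @export
search_hyperparameters <- function(dgeps, search_space, n_iter = 100L, seed = 1L,
                                   split = c(0.60, 0.15, 0.25)) {
  abort_if(length(search_space) == 0 || any(lengths(search_space) == 0),
           "empty hyper-parameter search space")
  ss <- list(layer_units = search_space$layer_units %||% list(c(512L, 64L, 20L, 64L, 512L)),
             activations = search_space$activations %||% "relu",
             batch_size = search_space$batch_size %||% 32L,
             epochs = search_space$epochs %||% 50L,
             learning_rate = search_space$learning_rate %||% 0.001)
  n_combos <- prod(lengths(ss))
  n_trials <- if (n_combos == 1) 1L else as.integer(n_iter)
  pick1 <- function(v) v[[sample.int(length(v), 1)]]
  picks <- with_seed(derive_seed(seed, "hyperparam"), {
    lapply(seq_len(n_trials), function(i) {
      list(layer_units = pick1(ss$layer_units),
           activations = pick1(ss$activations),
           batch_size = pick1(ss$batch_size),
           epochs = pick1(ss$epochs),
           learning_rate = pick1(ss$learning_rate))
    })
  })
  trials <- vector("list", n_trials)
  models <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    pk <- picks[[i]]
    cfg <- autoencoder_config(layer_units = pk$layer_units,
                              activations = pk$activations,
                              batch_size = pk$batch_size,
                              epochs = pk$epochs,
                              learning_rate = pk$learning_rate,
                              seed = derive_seed(seed, paste0("trial", i)))
    models[[i]] <- train_dgep_autoencoder(dgeps, cfg, split = split)
    trials[[i]] <- data.frame(trial = i,
                              layer_units = paste(pk$layer_units, collapse = "-"),
                              activation = pk$activations,
                              batch_size = pk$batch_size,
                              epochs = pk$epochs,
                              learning_rate = pk$learning_rate,
                              val_mse = models[[i]]$mse$validation)
  }
  log <- do.call(rbind, trials)
  best <- which.min(log$val_mse)
  list(best_config = models[[best]]$config,
       best_model = models[[best]],
       trials = log)
}
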