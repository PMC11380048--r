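# A small fully connected binary classifier trained with Adam on binary
# cross-entropy: ReLU hidden layers of equal width, inverted dropout after
# each hidden activation, single sigmoid output. Written in vectorized base
# R; the networks here are tiny (tens of units, hundreds of samples), so
# matrix products dominate and BLAS does the work.

#' Hyperparameter record for one ensemble member
#'
#' @param learning_rate Adam step size (> 0).
#' @param n_hidden_layers Number of hidden layers (>= 1).
#' @param hidden_units Units per hidden layer (>= 1).
#' @param dropout Dropout rate after each hidden activation, in \[0, 1).
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Training epochs (>= 1); no early stopping, epochs is a
#'   grid axis.
#' @return A list of class `hyperparams`.
#' @export
hyperparams <- function(learning_rate, n_hidden_layers, hidden_units,
                        dropout, batch_size, epochs) {
  if (!(learning_rate > 0)) stop_config("learning_rate must be > 0",
                                        field = "learning_rate")
  if (!is_count(n_hidden_layers) || n_hidden_layers < 1)
    stop_config("n_hidden_layers must be >= 1", field = "n_hidden_layers")
  if (!is_count(hidden_units) || hidden_units < 1)
    stop_config("hidden_units must be >= 1", field = "hidden_units")
  if (dropout < 0 || dropout >= 1)
    stop_config("dropout must be in [0, 1)", field = "dropout")
  if (!is_count(batch_size) || batch_size < 1)
    stop_config("batch_size must be >= 1", field = "batch_size")
  if (!is_count(epochs) || epochs < 1)
    stop_config("epochs must be >= 1", field = "epochs")
  structure(list(learning_rate = learning_rate,
                 n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "hyperparams")
}

format_hp <- function(hp) {
  sprintf("lr=%g layers=%d units=%d dropout=%g batch=%d epochs=%d",
          hp$learning_rate, hp$n_hidden_layers, hp$hidden_units,
          hp$dropout, hp$batch_size, hp$epochs)
}

# He-initialized parameter list: W[[l]], b[[l]] for hidden layers plus the
# output layer.
mlp_init <- function(p, hp) {
  sizes <- c(p, rep(hp$hidden_units, hp$n_hidden_layers), 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                     fan_in, sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass. Returns output probabilities plus the per-layer activations
# and dropout masks needed for backprop (training = TRUE) or just the
# activations (training = FALSE, no dropout).
mlp_forward <- function(params, X, dropout = 0, training = FALSE) {
  L <- length(params$W)
  A <- vector("list", L + 1)
  Z <- vector("list", L)
  mask <- vector("list", L - 1)
  A[[1]] <- X
  for (l in seq_len(L - 1)) {
    Z[[l]] <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    a <- pmax(Z[[l]], 0)
    if (training && dropout > 0) {
      mask[[l]] <- matrix(stats::runif(length(a)) >= dropout,
                          nrow(a), ncol(a)) / (1 - dropout)
      a <- a * mask[[l]]
    }
    A[[l + 1]] <- a
  }
  Z[[L]] <- sweep(A[[L]] %*% params$W[[L]], 2, params$b[[L]], "+")
  prob <- stats::plogis(Z[[L]])
  list(prob = prob, A = A, Z = Z, mask = mask)
}

mlp_bce <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# One Adam update of params given gradients; state carries first/second
# moment estimates and the step counter.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    for (nm in c("W", "b")) {
      g <- grads[[nm]][[l]]
      state$m[[nm]][[l]] <- beta1 * state$m[[nm]][[l]] + (1 - beta1) * g
      state$v[[nm]][[l]] <- beta2 * state$v[[nm]][[l]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[l]] / bc1
      vhat <- state$v[[nm]][[l]] / bc2
      params[[nm]][[l]] <- params[[nm]][[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# Core training loop on an already-standardized design matrix X (samples x
# features) and 0/1 labels y. Deterministic given the RNG state at entry.
mlp_train <- function(X, y, hp) {
  n <- nrow(X)
  params <- mlp_init(ncol(X), hp)
  zero <- lapply(params$W, function(w) w * 0)
  zerob <- lapply(params$b, function(b) b * 0)
  state <- list(t = 0,
                m = list(W = zero, b = zerob),
                v = list(W = zero, b = zerob))
  L <- length(params$W)
  final_loss <- NA_real_
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = hp$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + hp$batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- mlp_forward(params, Xb, dropout = hp$dropout, training = TRUE)
      loss <- mlp_bce(fw$prob, yb)
      if (!is.finite(loss))
        stop_training(paste0("training diverged (non-finite loss) for ",
                             format_hp(hp)))
      epoch_loss <- epoch_loss + loss * length(idx)
      # backprop: d(BCE)/dz_out = (p - y)/batch
      grads <- list(W = vector("list", L), b = vector("list", L))
      delta <- (fw$prob - yb) / length(idx)
      for (l in rev(seq_len(L))) {
        grads$W[[l]] <- crossprod(fw$A[[l]], delta)
        grads$b[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(params$W[[l]])
          if (hp$dropout > 0) delta <- delta * fw$mask[[l - 1]]
          delta <- delta * (fw$Z[[l - 1]] > 0)
        }
      }
      upd <- adam_step(params, grads, state, lr = hp$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    final_loss <- epoch_loss / n
  }
  list(params = params, final_loss = final_loss)
}

mlp_predict_prob <- function(params, X) {
  as.numeric(mlp_forward(params, X)$prob)
}

# Activations of the last hidden layer (inference mode, no dropout).
mlp_last_hidden <- function(params, X) {
  fw <- mlp_forward(params, X)
  fw$A[[length(params$W)]]
}
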