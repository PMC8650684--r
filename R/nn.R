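# Minimal feed-forward neural networks in base R.
#
# Two architectures back the screening classifiers: a plain dense stack
# (binding-probability classifier) and a residual trunk of identity-skip
# dense blocks (interface pose classifier). Training is full in-package:
# Adam, binary cross-entropy, sigmoid output, deterministic minibatch order
# from a seed, single-threaded.

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

he_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         nrow = fan_in)
}

#' Train a dense feed-forward binary classifier
#'
#' ReLU hidden layers, sigmoid output, binary cross-entropy, Adam. Fully
#' deterministic for a fixed seed (single-threaded, seeded init and
#' minibatch order).
#'
#' @param X Numeric matrix (rows = samples).
#' @param y 0/1 labels.
#' @param hidden Hidden layer widths.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed RNG seed.
#' @return Object of class `vsc_nn` (`type = "dense"`) with weights and the
#'   per-epoch training-loss history.
#' @export
mlp_train <- function(X, y, hidden = c(512L, 256L, 128L, 64L), epochs = 60L,
                      lr = 1e-3, batch_size = 128L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  d <- ncol(X)
  sizes <- c(d, hidden, 1L)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- he_init(sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    params <- c(W, b)
    nW <- length(W)
    st <- adam_new(params)
    n <- nrow(X)
    loss_hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        fw <- mlp_forward(params[seq_len(nW)], params[nW + seq_len(nW)], Xb)
        grads <- mlp_backward(params[seq_len(nW)], fw, yb)
        upd <- adam_step(params, grads, st, lr)
        params <- upd$params; st <- upd$state
      }
      p <- mlp_forward(params[seq_len(nW)], params[nW + seq_len(nW)], X)$p
      loss_hist[ep] <- bce_loss(p, y)
    }
    structure(list(type = "dense", W = params[seq_len(nW)],
                   b = params[nW + seq_len(nW)], hidden = hidden,
                   dim_in = d, loss_history = loss_hist,
                   seed = as.integer(seed)),
              class = "vsc_nn")
  })
}

mlp_forward <- function(W, b, X) {
  L <- length(W)
  Z <- vector("list", L); A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) relu(Z[[l]]) else Z[[l]]
  }
  list(Z = Z, A = A, p = sigmoid(Z[[L]])[, 1])
}

mlp_backward <- function(W, fw, y) {
  L <- length(W)
  n <- length(y)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- matrix((fw$p - y) / n, ncol = 1)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(W[[l]])) * (fw$Z[[l - 1L]] > 0)
    }
  }
  c(dW, db)
}

#' Train a residual dense binary classifier
#'
#' An entry layer projects the input to `width`, followed by `blocks`
#' residual blocks (dense-ReLU-dense plus an identity skip connection, then
#' ReLU) and a sigmoid head. Same optimizer and determinism contract as
#' [mlp_train()].
#'
#' @inheritParams mlp_train
#' @param width Trunk width.
#' @param blocks Number of residual blocks.
#' @return Object of class `vsc_nn` (`type = "residual"`).
#' @export
resnet_train <- function(X, y, width = 32L, blocks = 4L, epochs = 80L,
                         lr = 1e-3, batch_size = 64L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  d <- ncol(X)
  with_seed(seed, {
    params <- list(W0 = he_init(d, width), b0 = numeric(width))
    for (bk in seq_len(blocks)) {
      params[[paste0("W1_", bk)]] <- he_init(width, width)
      params[[paste0("b1_", bk)]] <- numeric(width)
      params[[paste0("W2_", bk)]] <- he_init(width, width)
      params[[paste0("b2_", bk)]] <- numeric(width)
    }
    params$Wh <- he_init(width, 1L)
    params$bh <- numeric(1L)
    st <- adam_new(params)
    n <- nrow(X)
    loss_hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fw <- resnet_forward(params, X[idx, , drop = FALSE], blocks)
        grads <- resnet_backward(params, fw, y[idx], blocks)
        upd <- adam_step(params, grads, st, lr)
        params <- upd$params; st <- upd$state
      }
      loss_hist[ep] <- bce_loss(resnet_forward(params, X, blocks)$p, y)
    }
    structure(list(type = "residual", params = params, width = width,
                   blocks = blocks, dim_in = d, loss_history = loss_hist,
                   seed = as.integer(seed)),
              class = "vsc_nn")
  })
}

resnet_forward <- function(p, X, blocks) {
  Z0 <- sweep(X %*% p$W0, 2, p$b0, `+`)
  A <- relu(Z0)
  cache <- list(X = X, Z0 = Z0, blocks = vector("list", blocks))
  for (bk in seq_len(blocks)) {
    Ain <- A
    Z1 <- sweep(Ain %*% p[[paste0("W1_", bk)]], 2, p[[paste0("b1_", bk)]], `+`)
    H1 <- relu(Z1)
    Z2 <- sweep(H1 %*% p[[paste0("W2_", bk)]], 2, p[[paste0("b2_", bk)]],
                `+`) + Ain
    A <- relu(Z2)
    cache$blocks[[bk]] <- list(Ain = Ain, Z1 = Z1, H1 = H1, Z2 = Z2)
  }
  Zh <- sweep(A %*% p$Wh, 2, p$bh, `+`)
  cache$Atop <- A
  cache$p <- sigmoid(Zh)[, 1]
  cache
}

resnet_backward <- function(p, fw, y, blocks) {
  n <- length(y)
  g <- stats::setNames(vector("list", length(p)), names(p))
  dZh <- matrix((fw$p - y) / n, ncol = 1)
  g$Wh <- crossprod(fw$Atop, dZh)
  g$bh <- colSums(dZh)
  dA <- dZh %*% t(p$Wh)
  for (bk in rev(seq_len(blocks))) {
    cb <- fw$blocks[[bk]]
    dZ2 <- dA * (cb$Z2 > 0)
    g[[paste0("W2_", bk)]] <- crossprod(cb$H1, dZ2)
    g[[paste0("b2_", bk)]] <- colSums(dZ2)
    dH1 <- dZ2 %*% t(p[[paste0("W2_", bk)]])
    dZ1 <- dH1 * (cb$Z1 > 0)
    g[[paste0("W1_", bk)]] <- crossprod(cb$Ain, dZ1)
    g[[paste0("b1_", bk)]] <- colSums(dZ1)
    dA <- dZ1 %*% t(p[[paste0("W1_", bk)]]) + dZ2  # identity skip gradient
  }
  dZ0 <- dA * (fw$Z0 > 0)
  g$W0 <- crossprod(fw$X, dZ0)
  g$b0 <- colSums(dZ0)
  g[names(p)]
}

#' Predict class-1 probabilities from a trained network
#'
#' @param model A `vsc_nn` from [mlp_train()] or [resnet_train()].
#' @param X Matrix (or single vector) of inputs.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
nn_predict <- function(model, X) {
  stopifnot(inherits(model, "vsc_nn"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$dim_in) {
    stopf("input has %d columns; model expects %d", ncol(X), model$dim_in)
  }
  if (model$type == "dense") {
    mlp_forward(model$W, model$b, X)$p
  } else {
    resnet_forward(model$params, X, model$blocks)$p
  }
}
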