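# Compact convolutional network for single-trial EEG decoding.
#
# Architecture: (1) a spatial convolution whose kernel spans all channels at
# one timepoint, collapsing the channel axis into n_filters feature maps;
# dropout 0.5; (2) a temporal convolution with a 1 x 25 kernel (valid
# padding, stride 1) across the feature maps; dropout 0.5; (3) flatten and a
# single dense unit with sigmoid output.  Forward and backward passes are
# vectorised over the batch: a batch of trials (B x C x T) is laid out as a
# C x (T*B) matrix so both convolutions become small matrix products.

NET_ACTIVATIONS <- c("relu", "softmax", "softplus", "tanh", "selu", "elu")
NET_OPTIMIZERS <- c("adam", "sgd", "rmsprop")
NET_LOSSES <- c("binary_crossentropy", "poisson", "kl_divergence")
NET_LEARNING_RATES <- c(1e-2, 1e-3, 1e-4)
NET_FILTERS <- 4:8

#' Hyperparameter specification of the decoding network
#'
#' Validated container for the network hyperparameters.  All values must
#' lie in the random-search space: activation in (relu, softmax, softplus,
#' tanh, selu, elu), 4--8 filters, optimizer in (adam, sgd, rmsprop),
#' learning rate in (1e-2, 1e-3, 1e-4), loss in (binary crossentropy,
#' poisson, KL divergence).  Dropout 0.5, 80 training epochs, batch size 32
#' and a temporal kernel of 25 samples are fixed protocol constants but can
#' be overridden (e.g. reduced epochs for small simulations).
#'
#' An elementwise "softmax" hidden activation is unusual; it is applied
#' across the filter axis at every timepoint, and selecting it emits a
#' note.
#'
#' @param activation,n_filters,optimizer,learning_rate,loss Search-space
#'   members, see above.
#' @param dropout,epochs,batch_size,temporal_kernel Protocol constants.
#' @return Object of class `net_spec`.
#' @export
net_spec <- function(activation = "relu", n_filters = 6L,
                     optimizer = "adam", learning_rate = 1e-3,
                     loss = "binary_crossentropy", dropout = 0.5,
                     epochs = 80L, batch_size = 32L, temporal_kernel = 25L) {
  activation <- match.arg(activation, NET_ACTIVATIONS)
  optimizer <- match.arg(optimizer, NET_OPTIMIZERS)
  loss <- match.arg(loss, NET_LOSSES)
  stopifnot(n_filters %in% NET_FILTERS,
            learning_rate %in% NET_LEARNING_RATES,
            dropout >= 0, dropout < 1, epochs >= 1, batch_size >= 1,
            temporal_kernel >= 1)
  if (activation == "softmax") {
    message("note: softmax used as hidden activation (applied across the ",
            "filter axis)")
  }
  structure(
    list(activation = activation, n_filters = as.integer(n_filters),
         optimizer = optimizer, learning_rate = learning_rate, loss = loss,
         dropout = dropout, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         temporal_kernel = as.integer(temporal_kernel)),
    class = "net_spec"
  )
}

#' Initialize the decoding network
#'
#' Builds the weight set for given input dimensions with Glorot-uniform
#' initialization.  Output extents follow valid-convolution arithmetic:
#' the spatial layer maps C x T input to feature maps of extent 1 x T, the
#' temporal layer to 1 x (T - 24) (for the default kernel of 25).
#'
#' @param spec A [net_spec()].
#' @param n_channels,n_times Input dimensions; `n_times` must exceed the
#'   temporal kernel.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `eeg_net`: weights `W1` (C x F), `b1`, `W2`
#'   (K x F x F), `b2`, `W3` ((T-K+1)*F), `b3`, plus `spec` and `dims`.
#' @export
build_net <- function(spec, n_channels, n_times, seed = 1L) {
  stopifnot(inherits(spec, "net_spec"))
  n_channels <- as.integer(n_channels)
  n_times <- as.integer(n_times)
  K <- spec$temporal_kernel
  if (n_times <= K) {
    stop("n_times must exceed the temporal kernel (", K, ")")
  }
  F_ <- spec$n_filters
  T2 <- n_times - K + 1L
  glorot <- function(n, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    runif(n, -lim, lim)
  }
  params <- with_seed(seed, list(
    W1 = matrix(glorot(n_channels * F_, n_channels, F_), n_channels, F_),
    b1 = numeric(F_),
    W2 = array(glorot(K * F_ * F_, K * F_, F_), c(K, F_, F_)),
    b2 = numeric(F_),
    W3 = glorot(T2 * F_, T2 * F_, 1L),
    b3 = 0
  ))
  structure(
    list(params = params, spec = spec,
         dims = list(C = n_channels, T = n_times, T2 = T2, F = F_, K = K),
         init_seed = as.integer(seed)),
    class = "eeg_net"
  )
}

#' Trainable parameter count of the decoding network
#'
#' Closed form: `C*F + F` (spatial layer) + `K*F^2 + F` (temporal layer) +
#' `(T-K+1)*F + 1` (dense output).
#'
#' @param net An [build_net()] object.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1L)))
}

act_forward <- function(Z, name) {
  switch(name,
    relu = pmax(Z, 0),
    softplus = log1p(exp(-abs(Z))) + pmax(Z, 0),
    tanh = tanh(Z),
    selu = {
      s <- 1.0507009873554805
      a <- 1.6732632423543772
      ifelse(Z > 0, s * Z, s * a * (exp(Z) - 1))
    },
    elu = ifelse(Z > 0, Z, exp(Z) - 1),
    softmax = {
      E <- exp(sweep(Z, 2L, apply(Z, 2L, max), `-`))
      sweep(E, 2L, colSums(E), `/`)
    }
  )
}

act_backward <- function(dA, Z, A, name) {
  switch(name,
    relu = dA * (Z > 0),
    softplus = dA / (1 + exp(-Z)),
    tanh = dA * (1 - A^2),
    selu = {
      s <- 1.0507009873554805
      a <- 1.6732632423543772
      dA * ifelse(Z > 0, s, A + s * a)
    },
    elu = dA * ifelse(Z > 0, 1, A + 1),
    softmax = A * sweep(dA, 2L, colSums(A * dA), `-`)
  )
}

# columns of the C x (T*B) layout touched by temporal-kernel offset k
conv_cols <- function(T_, T2, B, k) {
  as.vector(outer(seq_len(T2) + (k - 1L), (seq_len(B) - 1L) * T_, `+`))
}

# Forward pass.  Xm: C x (T*B) batch layout.  When training, dropout masks
# (inverted scaling) are drawn from the current RNG stream.
net_forward <- function(params, Xm, B, dims, spec, train = FALSE) {
  F_ <- dims$F; T_ <- dims$T; T2 <- dims$T2; K <- dims$K
  rate <- spec$dropout
  Z1 <- crossprod(params$W1, Xm) + params$b1
  A1_pre <- act_forward(Z1, spec$activation)
  A1 <- A1_pre
  M1 <- NULL
  if (train && rate > 0) {
    M1 <- matrix(runif(length(A1)) >= rate, nrow(A1), ncol(A1)) / (1 - rate)
    A1 <- A1 * M1
  }
  Z2 <- matrix(params$b2, F_, T2 * B)
  for (k in seq_len(K)) {
    Z2 <- Z2 + crossprod(params$W2[k, , ], A1[, conv_cols(T_, T2, B, k),
                                              drop = FALSE])
  }
  A2_pre <- act_forward(Z2, spec$activation)
  A2 <- A2_pre
  M2 <- NULL
  if (train && rate > 0) {
    M2 <- matrix(runif(length(A2)) >= rate, nrow(A2), ncol(A2)) / (1 - rate)
    A2 <- A2 * M2
  }
  flat <- matrix(A2, F_ * T2, B)
  z3 <- as.vector(crossprod(flat, params$W3)) + params$b3
  p <- 1 / (1 + exp(-z3))
  list(p = p, Z1 = Z1, A1 = A1, A1_pre = A1_pre, M1 = M1,
       Z2 = Z2, A2 = A2, A2_pre = A2_pre, M2 = M2,
       flat = flat, z3 = z3)
}

# Gradient of the loss with respect to the pre-sigmoid unit, per trial.
loss_grad_z <- function(p, y, loss) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  switch(loss,
    binary_crossentropy = pc - y,
    poisson = (1 - y / pc) * pc * (1 - pc),
    kl_divergence = -y * (1 - pc)
  )
}

net_loss <- function(p, y, loss) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  switch(loss,
    binary_crossentropy = mean(-y * log(pc) - (1 - y) * log(1 - pc)),
    poisson = mean(pc - y * log(pc)),
    kl_divergence = mean(y * log(pmax(y, eps) / pc))
  )
}

# Backward pass; returns mean-over-batch gradients for every parameter.
net_backward <- function(params, Xm, y, fw, B, dims, spec) {
  F_ <- dims$F; T_ <- dims$T; T2 <- dims$T2; K <- dims$K
  dz3 <- loss_grad_z(fw$p, y, spec$loss) / B
  dW3 <- as.vector(fw$flat %*% dz3)
  db3 <- sum(dz3)
  dflat <- params$W3 %*% t(dz3)
  dA2 <- matrix(dflat, F_, T2 * B)
  if (!is.null(fw$M2)) dA2 <- dA2 * fw$M2
  dZ2 <- act_backward(dA2, fw$Z2, fw$A2_pre, spec$activation)
  db2 <- rowSums(dZ2)
  dW2 <- array(0, c(K, F_, F_))
  dA1 <- matrix(0, F_, T_ * B)
  for (k in seq_len(K)) {
    cols <- conv_cols(T_, T2, B, k)
    A1k <- fw$A1[, cols, drop = FALSE]
    dW2[k, , ] <- A1k %*% t(dZ2)
    dA1[, cols] <- dA1[, cols] + params$W2[k, , ] %*% dZ2
  }
  if (!is.null(fw$M1)) dA1 <- dA1 * fw$M1
  dZ1 <- act_backward(dA1, fw$Z1, fw$A1_pre, spec$activation)
  dW1 <- Xm %*% t(dZ1)
  db1 <- rowSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

make_optimizer <- function(name, lr) {
  state <- NULL
  step <- 0L
  list(
    update = function(params, grads) {
      step <<- step + 1L
      if (is.null(state)) {
        state <<- lapply(grads, function(g) {
          list(m = g * 0, v = g * 0)
        })
      }
      for (nm in names(params)) {
        g <- grads[[nm]]
        if (name == "sgd") {
          params[[nm]] <- params[[nm]] - lr * g
        } else if (name == "rmsprop") {
          state[[nm]]$v <<- 0.9 * state[[nm]]$v + 0.1 * g^2
          params[[nm]] <- params[[nm]] -
            lr * g / (sqrt(state[[nm]]$v) + 1e-7)
        } else { # adam
          state[[nm]]$m <<- 0.9 * state[[nm]]$m + 0.1 * g
          state[[nm]]$v <<- 0.999 * state[[nm]]$v + 0.001 * g^2
          mhat <- state[[nm]]$m / (1 - 0.9^step)
          vhat <- state[[nm]]$v / (1 - 0.999^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-7)
        }
      }
      params
    }
  )
}

# B x C x T array -> C x (T*B) matrix (columns grouped per trial)
tensor_to_batch <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2L, 3L, 1L)), d[2L], d[3L] * d[1L])
}

#' Train the decoding network
#'
#' Mini-batch training with the spec's optimizer, loss and dropout.  Data
#' order is shuffled every epoch; shuffling, dropout and weight
#' initialization all derive from `net$init_seed` and `seed`, so training
#' is fully reproducible.
#'
#' @param net An [build_net()] network.
#' @param X Array trials x channels x time (standardized).
#' @param y Numeric 0/1 labels (1 = congruent).
#' @param seed Seed for shuffling and dropout.
#' @param epochs Optional override of `spec$epochs`.
#' @return The network with trained parameters and a `history` of epoch
#'   losses.
#' @export
train_net <- function(net, X, y, seed = 1L, epochs = NULL) {
  stopifnot(inherits(net, "eeg_net"), dim(X)[1L] == length(y))
  spec <- net$spec
  dims <- net$dims
  n <- length(y)
  epochs <- epochs %||% spec$epochs
  bs <- min(spec$batch_size, n)
  params <- net$params
  opt <- make_optimizer(spec$optimizer, spec$learning_rate)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = bs)) {
        take <- ord[start:min(start + bs - 1L, n)]
        B <- length(take)
        Xm <- tensor_to_batch(X[take, , , drop = FALSE])
        fw <- net_forward(params, Xm, B, dims, spec, train = TRUE)
        grads <- net_backward(params, Xm, y[take], fw, B, dims, spec)
        params <- opt$update(params, grads)
        losses <- c(losses, net_loss(fw$p, y[take], spec$loss))
      }
      history[ep] <- mean(losses)
    }
  })
  net$params <- params
  net$history <- history
  net
}

#' Predict congruency probabilities for trials
#'
#' @param net A trained [train_net()] network.
#' @param X Array trials x channels x time (standardized like the training
#'   data).
#' @return Numeric vector of sigmoid outputs in (0, 1).
#' @export
predict_net <- function(net, X) {
  stopifnot(inherits(net, "eeg_net"))
  B <- dim(X)[1L]
  fw <- net_forward(net$params, tensor_to_batch(X), B, net$dims, net$spec,
                    train = FALSE)
  fw$p
}
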