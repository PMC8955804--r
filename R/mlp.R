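# Minimal fully-connected network with ReLU hidden layers, trained by Adam
# on mean-squared error. Written with plain matrix ops; sized for the tiny
# calibration networks (3 inputs -> 20 -> 30 -> 20 -> 4 outputs).

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    n <- length(sizes) - 1
    W <- vector("list", n); b <- vector("list", n)
    for (i in seq_len(n)) {
      # He-normal init for the ReLU layers
      W[[i]] <- matrix(rnorm(sizes[i] * sizes[i + 1], sd = sqrt(2 / sizes[i])),
                       sizes[i], sizes[i + 1])
      b[[i]] <- numeric(sizes[i + 1])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

mlp_n_params <- function(net) {
  sum(vapply(net$W, length, 0L)) + sum(vapply(net$b, length, 0L))
}

mlp_forward <- function(net, X, keep = FALSE) {
  n <- length(net$W)
  acts <- vector("list", n + 1)
  acts[[1]] <- X
  A <- X
  for (i in seq_len(n)) {
    Z <- sweep(A %*% net$W[[i]], 2, net$b[[i]], `+`)
    A <- if (i < n) pmax(Z, 0) else Z  # linear output layer
    acts[[i + 1]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

# one Adam step on batch (X, Y); state carries first/second moments and t
mlp_step <- function(net, state, X, Y, lr) {
  n <- length(net$W)
  fw <- mlp_forward(net, X, keep = TRUE)
  m <- nrow(X)
  delta <- 2 * (fw$out - Y) / (m * ncol(Y))   # d(MSE)/d(out)
  gW <- vector("list", n); gb <- vector("list", n)
  for (i in rev(seq_len(n))) {
    A_prev <- fw$acts[[i]]
    gW[[i]] <- crossprod(A_prev, delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- (delta %*% t(net$W[[i]])) * (fw$acts[[i]] > 0)
    }
  }
  state$t <- state$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (i in seq_len(n)) {
    state$mW[[i]] <- b1 * state$mW[[i]] + (1 - b1) * gW[[i]]
    state$vW[[i]] <- b2 * state$vW[[i]] + (1 - b2) * gW[[i]]^2
    net$W[[i]] <- net$W[[i]] -
      lr * (state$mW[[i]] / corr1) / (sqrt(state$vW[[i]] / corr2) + eps)
    state$mb[[i]] <- b1 * state$mb[[i]] + (1 - b1) * gb[[i]]
    state$vb[[i]] <- b2 * state$vb[[i]] + (1 - b2) * gb[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (state$mb[[i]] / corr1) / (sqrt(state$vb[[i]] / corr2) + eps)
  }
  list(net = net, state = state)
}

mlp_train <- function(X, Y, hidden = c(20, 30, 20), epochs = 30, seed = 1L,
                      lr = 1e-3, batch_size = 32) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  sizes <- c(ncol(X), hidden, ncol(Y))
  net <- mlp_init(sizes, seed)
  zeros <- function(tpl) lapply(tpl, function(p) array(0, dim = dim(p) %||% length(p)))
  state <- list(mW = zeros(net$W), vW = zeros(net$W),
                mb = lapply(net$b, function(p) numeric(length(p))),
                vb = lapply(net$b, function(p) numeric(length(p))),
                t = 0)
  n <- nrow(X)
  loss_history <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        res <- mlp_step(net, state, X[idx, , drop = FALSE],
                        Y[idx, , drop = FALSE], lr)
        net <- res$net; state <- res$state
      }
      loss <- mean((mlp_forward(net, X) - Y)^2)
      if (!is.finite(loss)) {
        stop("mlp_train: training diverged at epoch ", ep,
             " (last finite loss ",
             format(if (ep > 1) loss_history[ep - 1] else NA), ")")
      }
      loss_history[ep] <- loss
    }
  })
  list(net = net, loss_history = loss_history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
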