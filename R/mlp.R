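# Minimal multilayer perceptron for binary targets: Glorot-uniform
# initialisation, ReLU or tanh hidden activations, sigmoid output with
# log loss, L2 penalty, Adam updates on shuffled mini-batches, and
# early stopping on the training loss (stop when the epoch loss has not
# improved by more than `tol` for `n_iter_no_change` consecutive epochs).
# Training is deterministic given the R RNG state.

mlp_fit <- function(X, y, hidden = 16L, activation = c("relu", "tanh"),
                    lr = 0.001, batch_size = 5L, max_iter = 550L,
                    alpha = 1e-4, tol = 1e-4, n_iter_no_change = 10L) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop("mlp_fit needs both classes present in the target")
  sizes <- c(ncol(X), as.integer(hidden), 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    bound <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -bound, bound),
                     sizes[l], sizes[l + 1])
    b[[l]] <- matrix(stats::runif(sizes[l + 1], -bound, bound), 1L, sizes[l + 1])
  }
  # Adam state
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(w) w * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  act <- if (activation == "relu") function(z) pmax(z, 0) else tanh
  act_grad <- if (activation == "relu") {
    function(a) (a > 0) * 1
  } else {
    function(a) 1 - a^2
  }
  best <- Inf; no_improve <- 0L; n_epochs <- 0L
  for (epoch in seq_len(max_iter)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    epoch_loss <- 0
    for (s in starts) {
      take <- idx[s:min(s + batch_size - 1L, n)]
      Xb <- X[take, , drop = FALSE]
      yb <- y[take]
      nb <- length(take)
      # forward
      A <- vector("list", L + 1L)
      A[[1]] <- Xb
      for (l in seq_len(L - 1L))
        A[[l + 1L]] <- act(sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+"))
      zout <- sweep(A[[L]] %*% W[[L]], 2L, b[[L]], "+")
      p <- 1 / (1 + exp(-zout))
      pc <- pmin(pmax(p, 1e-10), 1 - 1e-10)
      loss <- -mean(yb * log(pc) + (1 - yb) * log(1 - pc)) +
        0.5 * alpha * sum(vapply(W, function(w) sum(w^2), numeric(1))) / nb
      epoch_loss <- epoch_loss + loss * nb
      # backward
      delta <- (p - yb) / nb            # column vector (nb x 1)
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + alpha * W[[l]] / nb
        gb <- matrix(colSums(delta), 1L)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * act_grad(A[[l]])
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / bc1) / (sqrt(vb[[l]] / bc2) + eps)
      }
    }
    epoch_loss <- epoch_loss / n
    n_epochs <- epoch
    if (epoch_loss > best - tol) no_improve <- no_improve + 1L else no_improve <- 0L
    if (epoch_loss < best) best <- epoch_loss
    if (no_improve >= n_iter_no_change) break
  }
  structure(list(W = W, b = b, activation = activation, sizes = sizes,
                 n_epochs = n_epochs, final_loss = best),
            class = "compens2d_mlp")
}

mlp_prob <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$sizes[1])
    stop("feature matrix has ", ncol(X), " columns, model expects ",
         model$sizes[1])
  L <- length(model$W)
  act <- if (model$activation == "relu") function(z) pmax(z, 0) else tanh
  A <- X
  for (l in seq_len(L - 1L))
    A <- act(sweep(A %*% model$W[[l]], 2L, model$b[[l]], "+"))
  z <- sweep(A %*% model$W[[L]], 2L, model$b[[L]], "+")
  as.numeric(1 / (1 + exp(-z)))
}
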