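# Minimal dense linear-algebra neural network layers used by the WGAN-GP.
#
# Layout convention: a batch of n samples of shape (M positions x C channels)
# is stored as a (M*C) x n matrix, position-major (the block of rows for
# position t holds its C channels). Conv1D with kernel size 2, stride 1 and
# same-length (right zero) padding then reads: Y_t = W0 X_t + W1 X_{t+1} + b,
# with X_{M+1} = 0. All layers keep explicit caches for backpropagation.

# ---- tensor <-> matrix -----------------------------------------------------

# (n, M, C) array -> (M*C) x n matrix, row index = (m-1)*C + c
tensor_to_mat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(3, 2, 1)), nrow = d[2] * d[3], ncol = d[1])
}

# (M*C) x n matrix -> (n, M, C) array
mat_to_tensor <- function(x, M, C) {
  n <- ncol(x)
  aperm(array(x, dim = c(C, M, n)), c(3, 2, 1))
}

# ---- parameter initialization ---------------------------------------------

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

conv_init <- function(Cin, Cout) {
  fan_in <- 2 * Cin; fan_out <- 2 * Cout
  list(W0 = glorot_uniform(Cout, Cin, fan_in, fan_out),
       W1 = glorot_uniform(Cout, Cin, fan_in, fan_out),
       b = rep(0, Cout))
}

dense_init <- function(nin, nout) {
  list(W = glorot_uniform(nout, nin, nin, nout), b = rep(0, nout))
}

# ---- Conv1D (kernel 2, stride 1, same padding) -----------------------------

conv_forward <- function(W0, W1, b, X, M, Cin, Cout) {
  n <- ncol(X)
  Y <- matrix(0, M * Cout, n)
  for (t in seq_len(M)) {
    xt <- X[((t - 1) * Cin + 1):(t * Cin), , drop = FALSE]
    yt <- W0 %*% xt
    if (t < M) {
      xt1 <- X[(t * Cin + 1):((t + 1) * Cin), , drop = FALSE]
      yt <- yt + W1 %*% xt1
    }
    Y[((t - 1) * Cout + 1):(t * Cout), ] <- yt + b
  }
  Y
}

# returns list(dX, dW0, dW1, db)
conv_backward <- function(W0, W1, X, dY, M, Cin, Cout) {
  dW0 <- matrix(0, Cout, Cin); dW1 <- matrix(0, Cout, Cin)
  db <- rep(0, Cout)
  dX <- matrix(0, nrow(X), ncol(X))
  for (t in seq_len(M)) {
    rows_y <- ((t - 1) * Cout + 1):(t * Cout)
    rows_x <- ((t - 1) * Cin + 1):(t * Cin)
    dyt <- dY[rows_y, , drop = FALSE]
    xt <- X[rows_x, , drop = FALSE]
    dW0 <- dW0 + tcrossprod(dyt, xt)
    db <- db + rowSums(dyt)
    dX[rows_x, ] <- dX[rows_x, ] + crossprod(W0, dyt)
    if (t < M) {
      rows_x1 <- (t * Cin + 1):((t + 1) * Cin)
      xt1 <- X[rows_x1, , drop = FALSE]
      dW1 <- dW1 + tcrossprod(dyt, xt1)
      dX[rows_x1, ] <- dX[rows_x1, ] + crossprod(W1, dyt)
    }
  }
  list(dX = dX, dW0 = dW0, dW1 = dW1, db = db)
}

# Full (M*Cout) x (M*Cin) linear operator of the convolution (used by the
# analytic gradient-penalty backward pass).
conv_matrix <- function(W0, W1, M) {
  Cout <- nrow(W0); Cin <- ncol(W0)
  A <- matrix(0, M * Cout, M * Cin)
  for (t in seq_len(M)) {
    A[((t - 1) * Cout + 1):(t * Cout), ((t - 1) * Cin + 1):(t * Cin)] <- W0
    if (t < M)
      A[((t - 1) * Cout + 1):(t * Cout), (t * Cin + 1):((t + 1) * Cin)] <- W1
  }
  A
}

# Fold a gradient on the full operator back onto the shared kernels.
conv_matrix_grad <- function(dA, M, Cin, Cout) {
  dW0 <- matrix(0, Cout, Cin); dW1 <- matrix(0, Cout, Cin)
  for (t in seq_len(M)) {
    rows <- ((t - 1) * Cout + 1):(t * Cout)
    dW0 <- dW0 + dA[rows, ((t - 1) * Cin + 1):(t * Cin), drop = FALSE]
    if (t < M)
      dW1 <- dW1 + dA[rows, (t * Cin + 1):((t + 1) * Cin), drop = FALSE]
  }
  list(dW0 = dW0, dW1 = dW1)
}

# ---- Batch normalization (per channel over positions and batch) ------------

# X: (M*f) x n; returns list(Y, cache, run) where run holds updated running
# moments. Training mode normalizes by batch statistics (biased variance);
# inference mode uses the running moments.
bn_forward <- function(gamma, beta, run_mean, run_var, X, f, M,
                       training, momentum = 0.99, eps = 1e-3) {
  n <- ncol(X)
  Xc <- X; dim(Xc) <- c(f, M * n)
  if (training) {
    mu <- rowMeans(Xc)
    v <- rowMeans(Xc * Xc) - mu^2
    v <- pmax(v, 0)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (Xc - mu) * ivar
  Y <- gamma * xhat + beta
  dim(Y) <- c(f * M, n)
  list(Y = Y, cache = list(xhat = xhat, ivar = ivar, f = f, M = M, n = n,
                           training = training),
       run_mean = run_mean, run_var = run_var)
}

# dY: (M*f) x n -> list(dX, dgamma, dbeta)
bn_backward <- function(gamma, cache, dY) {
  f <- cache$f; M <- cache$M; n <- cache$n
  dYc <- dY; dim(dYc) <- c(f, M * n)
  xhat <- cache$xhat
  dgamma <- rowSums(dYc * xhat)
  dbeta <- rowSums(dYc)
  dxhat <- dYc * gamma
  if (cache$training) {
    Nn <- M * n
    dX <- (cache$ivar / Nn) * (Nn * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dX <- dxhat * cache$ivar
  }
  dim(dX) <- c(f * M, n)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- optimizers ------------------------------------------------------------

# Parameters and gradients are named lists of numeric arrays with identical
# shapes; optimizer state mirrors the structure.

optimizer_init <- function(params, kind = c("adam", "rmsprop")) {
  kind <- match.arg(kind)
  zeros <- lapply(params, function(p) p * 0)
  if (kind == "adam") list(kind = kind, t = 0L, m = zeros, v = zeros)
  else list(kind = kind, v = zeros)
}

optimizer_step <- function(state, params, grads, lr,
                           beta1 = 0.5, beta2 = 0.9, rho = 0.9, eps = 1e-7) {
  if (state$kind == "adam") {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (nm in names(params)) {
      g <- grads[[nm]]
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
      params[[nm]] <- params[[nm]] -
        lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    }
  } else {
    for (nm in names(params)) {
      g <- grads[[nm]]
      state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g * g
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(state$v[[nm]]) + eps)
    }
  }
  list(state = state, params = params)
}

# elementwise sum of two named gradient lists (shapes preserved)
grads_add <- function(a, b, w = 1) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + w * b[[nm]]
  a
}

grads_scale <- function(a, w) lapply(a, function(g) g * w)
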