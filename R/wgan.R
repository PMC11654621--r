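# WGAN with gradient penalty over (N, M, C) mini-batch tensors.
#
# Generator: noise (latent_dim) -> dense to an M-position sequence ->
# Conv1D(f1) -> BN -> ReLU -> Conv1D(f2) -> BN -> ReLU -> Conv1D(C, linear).
# Critic: Conv1D(g1) -> ReLU -> Conv1D(g2) -> ReLU -> Dense(1). All
# convolutions use kernel size 2, stride 1 and same-length padding along the
# modality axis (channels = embedding dimensions). The critic deliberately has
# no batch normalization, which would invalidate the per-sample gradient
# penalty.
#
# Because every activation is ReLU (piecewise linear), the critic's gradient
# with respect to its input is, at fixed activation masks, an explicit product
# of masked convolution operators; the parameter gradient of the gradient
# penalty (a double backward) is therefore available in closed form and is
# implemented analytically below (verified against finite differences in the
# test suite).

#' Training configuration for the WGAN-GP
#'
#' @param steps Generator updates to perform.
#' @param N Mini-batch size (default 256).
#' @param n_candidates Candidate mini-batches scored per target modality in
#'   unpaired mode (default 50).
#' @param critic_updates Critic updates per generator update (default 5).
#' @param gp_weight Gradient-penalty coefficient lambda (default 10).
#' @param latent_dim Generator noise dimensionality (default 64).
#' @param gen_filters First two Conv1D filter counts of the generator
#'   (default `c(512, 128)`); the third layer always has C filters.
#' @param critic_filters Conv1D filter counts of the critic (default
#'   `c(128, 512)`).
#' @param gen_lr,gen_beta1,gen_beta2,gen_eps Adam settings for the generator
#'   (defaults 0.001, 0.5, 0.9, 1e-07).
#' @param critic_lr RMSprop learning rate for the critic (default 0.0005).
#' @param strategy Candidate sampling strategy for pre-matching.
#' @param bn_momentum,bn_eps Batch-normalization momentum and epsilon
#'   (defaults 0.99 and 1e-3).
#' @param seed Integer seed controlling initialization and every stochastic
#'   step of training.
#' @param nan_policy `"abort"` (raise on a non-finite loss) or `"restart"`
#'   (re-seed and retry up to 3 times).
#' @param ema_decay Exponential-moving-average decay applied to the generator
#'   weights; the averaged weights are the ones used for generation, which
#'   damps the step-to-step oscillation of adversarial training (set 0 to
#'   disable and generate from the raw final weights).
#' @return A `TrainConfig` list.
#' @export
train_config <- function(steps = 1000L, N = 256L, n_candidates = 50L,
                         critic_updates = 5L, gp_weight = 10,
                         latent_dim = 64L, gen_filters = c(512L, 128L),
                         critic_filters = c(128L, 512L),
                         gen_lr = 0.001, gen_beta1 = 0.5, gen_beta2 = 0.9,
                         gen_eps = 1e-07, critic_lr = 0.0005,
                         strategy = c("window", "random"),
                         bn_momentum = 0.99, bn_eps = 1e-3,
                         seed = 1L, nan_policy = c("abort", "restart"),
                         ema_decay = 0.995) {
  strategy <- match.arg(strategy)
  nan_policy <- match.arg(nan_policy)
  stopifnot(steps >= 1, N >= 2, critic_updates >= 1, gp_weight > 0,
            gen_lr > 0, critic_lr > 0, length(gen_filters) >= 2,
            length(critic_filters) == 2)
  structure(list(steps = as.integer(steps), N = as.integer(N),
                 n_candidates = as.integer(n_candidates),
                 critic_updates = as.integer(critic_updates),
                 gp_weight = gp_weight, latent_dim = as.integer(latent_dim),
                 gen_filters = as.integer(gen_filters[1:2]),
                 critic_filters = as.integer(critic_filters),
                 gen_lr = gen_lr, gen_beta1 = gen_beta1, gen_beta2 = gen_beta2,
                 gen_eps = gen_eps, critic_lr = critic_lr,
                 strategy = strategy, bn_momentum = bn_momentum,
                 bn_eps = bn_eps, seed = as.integer(seed),
                 nan_policy = nan_policy, ema_decay = ema_decay),
            class = "TrainConfig")
}

# ---- generator -------------------------------------------------------------

#' Build an (untrained) generator
#'
#' @param M Number of modalities (>= 2).
#' @param C Embedding width per modality.
#' @param latent_dim Noise input length.
#' @param filters First two Conv1D filter counts; the output layer has C.
#' @param bn_momentum,bn_eps Batch-norm settings.
#' @return A `scbridge_generator` object (parameters drawn from the current
#'   RNG state with Glorot-uniform initialization).
#' @export
build_generator <- function(M, C, latent_dim = 64L, filters = c(512L, 128L),
                            bn_momentum = 0.99, bn_eps = 1e-3) {
  M <- as.integer(M); C <- as.integer(C)
  if (M < 2L) stop("a multimodal generator needs M >= 2 (kernel size 2 ",
                   "convolutions need at least 2 positions under same padding)")
  if (C < 1L) stop("C must be >= 1")
  f1 <- as.integer(filters[1]); f2 <- as.integer(filters[2])
  d <- dense_init(latent_dim, M * latent_dim)
  c1 <- conv_init(latent_dim, f1)
  c2 <- conv_init(f1, f2)
  c3 <- conv_init(f2, C)
  params <- list(dense_W = d$W, dense_b = d$b,
                 conv1_W0 = c1$W0, conv1_W1 = c1$W1, conv1_b = c1$b,
                 bn1_gamma = rep(1, f1), bn1_beta = rep(0, f1),
                 conv2_W0 = c2$W0, conv2_W1 = c2$W1, conv2_b = c2$b,
                 bn2_gamma = rep(1, f2), bn2_beta = rep(0, f2),
                 conv3_W0 = c3$W0, conv3_W1 = c3$W1, conv3_b = c3$b)
  structure(list(M = M, C = C, latent_dim = as.integer(latent_dim),
                 filters = c(f1, f2, C),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 params = params,
                 run = list(bn1_mean = rep(0, f1), bn1_var = rep(1, f1),
                            bn2_mean = rep(0, f2), bn2_var = rep(1, f2))),
            class = "scbridge_generator")
}

# Z: latent_dim x n. Returns list(Y = (M*C) x n, cache, gen) — gen carries
# updated BN running moments when training.
gen_forward <- function(gen, Z, training = FALSE) {
  p <- gen$params
  M <- gen$M; C <- gen$C
  ld <- gen$latent_dim; f1 <- gen$filters[1]; f2 <- gen$filters[2]
  X0 <- p$dense_W %*% Z + p$dense_b
  C1 <- conv_forward(p$conv1_W0, p$conv1_W1, p$conv1_b, X0, M, ld, f1)
  b1 <- bn_forward(p$bn1_gamma, p$bn1_beta, gen$run$bn1_mean, gen$run$bn1_var,
                   C1, f1, M, training, gen$bn_momentum, gen$bn_eps)
  H1 <- pmax(b1$Y, 0)
  C2 <- conv_forward(p$conv2_W0, p$conv2_W1, p$conv2_b, H1, M, f1, f2)
  b2 <- bn_forward(p$bn2_gamma, p$bn2_beta, gen$run$bn2_mean, gen$run$bn2_var,
                   C2, f2, M, training, gen$bn_momentum, gen$bn_eps)
  H2 <- pmax(b2$Y, 0)
  Y <- conv_forward(p$conv3_W0, p$conv3_W1, p$conv3_b, H2, M, f2, C)
  if (training) {
    gen$run$bn1_mean <- b1$run_mean; gen$run$bn1_var <- b1$run_var
    gen$run$bn2_mean <- b2$run_mean; gen$run$bn2_var <- b2$run_var
  }
  list(Y = Y,
       cache = list(Z = Z, X0 = X0, C1 = C1, bn1 = b1, H1 = H1,
                    C2 = C2, bn2 = b2, H2 = H2),
       gen = gen)
}

# dY: (M*C) x n gradient on the generator output; returns named grads.
gen_backward <- function(gen, cache, dY) {
  p <- gen$params
  M <- gen$M; C <- gen$C
  ld <- gen$latent_dim; f1 <- gen$filters[1]; f2 <- gen$filters[2]
  g3 <- conv_backward(p$conv3_W0, p$conv3_W1, cache$H2, dY, M, f2, C)
  dB2 <- g3$dX * (cache$bn2$Y > 0)
  bb2 <- bn_backward(p$bn2_gamma, cache$bn2$cache, dB2)
  g2 <- conv_backward(p$conv2_W0, p$conv2_W1, cache$H1, bb2$dX, M, f1, f2)
  dB1 <- g2$dX * (cache$bn1$Y > 0)
  bb1 <- bn_backward(p$bn1_gamma, cache$bn1$cache, dB1)
  g1 <- conv_backward(p$conv1_W0, p$conv1_W1, cache$X0, bb1$dX, M, ld, f1)
  list(dense_W = tcrossprod(g1$dX, cache$Z), dense_b = rowSums(g1$dX),
       conv1_W0 = g1$dW0, conv1_W1 = g1$dW1, conv1_b = g1$db,
       bn1_gamma = bb1$dgamma, bn1_beta = bb1$dbeta,
       conv2_W0 = g2$dW0, conv2_W1 = g2$dW1, conv2_b = g2$db,
       bn2_gamma = bb2$dgamma, bn2_beta = bb2$dbeta,
       conv3_W0 = g3$dW0, conv3_W1 = g3$dW1, conv3_b = g3$db)
}

#' Run a generator on noise
#'
#' @param gen A `scbridge_generator`.
#' @param Z Noise matrix, `n x latent_dim` (rows are cells).
#' @param training Use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`, deterministic inference).
#' @return Array `(n, M, C)` of synthetic embeddings.
#' @export
generator_predict <- function(gen, Z, training = FALSE) {
  out <- gen_forward(gen, t(as.matrix(Z)), training = training)
  mat_to_tensor(out$Y, gen$M, gen$C)
}

# ---- critic ----------------------------------------------------------------

#' Build an (untrained) critic
#'
#' The critic maps an `(n, M, C)` batch to one unbounded real score per
#' sample. It contains no batch normalization: the gradient penalty is defined
#' per sample and batch statistics would couple samples.
#'
#' @param M,C As in [build_generator()].
#' @param filters The two Conv1D filter counts (default `c(128, 512)`).
#' @return A `scbridge_critic` object.
#' @export
build_critic <- function(M, C, filters = c(128L, 512L)) {
  M <- as.integer(M); C <- as.integer(C)
  if (M < 2L) stop("the critic needs M >= 2 positions for its kernel-2 convolutions")
  g1 <- as.integer(filters[1]); g2 <- as.integer(filters[2])
  c1 <- conv_init(C, g1)
  c2 <- conv_init(g1, g2)
  d <- dense_init(M * g2, 1L)
  params <- list(conv1_W0 = c1$W0, conv1_W1 = c1$W1, conv1_b = c1$b,
                 conv2_W0 = c2$W0, conv2_W1 = c2$W1, conv2_b = c2$b,
                 dense_w = as.numeric(d$W), dense_b = 0)
  structure(list(M = M, C = C, filters = c(g1, g2), params = params),
            class = "scbridge_critic")
}

# X: (M*C) x n. Returns scores and caches.
critic_forward <- function(critic, X) {
  p <- critic$params
  M <- critic$M; C <- critic$C
  g1 <- critic$filters[1]; g2 <- critic$filters[2]
  C1 <- conv_forward(p$conv1_W0, p$conv1_W1, p$conv1_b, X, M, C, g1)
  H1 <- pmax(C1, 0)
  C2 <- conv_forward(p$conv2_W0, p$conv2_W1, p$conv2_b, H1, M, g1, g2)
  H2 <- pmax(C2, 0)
  s <- as.numeric(crossprod(H2, p$dense_w)) + p$dense_b
  list(s = s, cache = list(X = X, C1 = C1, H1 = H1, C2 = C2, H2 = H2))
}

#' Score a batch with the critic
#'
#' @param critic A `scbridge_critic`.
#' @param x Array `(n, M, C)`.
#' @return Numeric vector of n scores.
#' @export
critic_score <- function(critic, x) {
  critic_forward(critic, tensor_to_mat(x))$s
}

# ds: length-n vector dL/ds_i. Returns list(grads, dX).
critic_backward <- function(critic, cache, ds) {
  p <- critic$params
  M <- critic$M; C <- critic$C
  g1 <- critic$filters[1]; g2 <- critic$filters[2]
  dH2 <- outer(p$dense_w, ds)
  dC2 <- dH2 * (cache$C2 > 0)
  gb2 <- conv_backward(p$conv2_W0, p$conv2_W1, cache$H1, dC2, M, g1, g2)
  dC1 <- gb2$dX * (cache$C1 > 0)
  gb1 <- conv_backward(p$conv1_W0, p$conv1_W1, cache$X, dC1, M, C, g1)
  grads <- list(conv1_W0 = gb1$dW0, conv1_W1 = gb1$dW1, conv1_b = gb1$db,
                conv2_W0 = gb2$dW0, conv2_W1 = gb2$dW1, conv2_b = gb2$db,
                dense_w = as.numeric(cache$H2 %*% ds), dense_b = sum(ds))
  list(grads = grads, dX = gb1$dX)
}

# Gradient of critic scores with respect to the input, per sample (columns).
critic_input_grad <- function(critic, cache, ds = NULL) {
  p <- critic$params
  n <- ncol(cache$X)
  if (is.null(ds)) ds <- rep(1, n)
  dH2 <- outer(p$dense_w, ds)
  dC2 <- dH2 * (cache$C2 > 0)
  gb2 <- conv_backward(p$conv2_W0, p$conv2_W1, cache$H1, dC2,
                       critic$M, critic$filters[1], critic$filters[2])
  dC1 <- gb2$dX * (cache$C1 > 0)
  gb1 <- conv_backward(p$conv1_W0, p$conv1_W1, cache$X, dC1,
                       critic$M, critic$C, critic$filters[1])
  gb1$dX
}

# ---- losses ----------------------------------------------------------------

#' Wasserstein critic loss
#'
#' `mean(fake_scores) - mean(real_scores) + lambda * gp`.
#'
#' @param real_scores,fake_scores Non-empty numeric score vectors.
#' @param gp Gradient-penalty value (scalar >= 0).
#' @param lambda Penalty weight (default 10).
#' @return Scalar loss.
#' @export
critic_loss <- function(real_scores, fake_scores, gp = 0, lambda = 10) {
  stopifnot(length(real_scores) > 0, length(fake_scores) > 0)
  mean(fake_scores) - mean(real_scores) + lambda * gp
}

#' Wasserstein generator loss
#'
#' `-mean(fake_scores)`.
#'
#' @param fake_scores Non-empty numeric vector of critic scores on generated
#'   samples.
#' @return Scalar loss.
#' @export
generator_loss <- function(fake_scores) {
  stopifnot(length(fake_scores) > 0)
  -mean(fake_scores)
}

#' Gradient penalty of a critic between real and fake batches
#'
#' Per sample, an interpolate `xhat = e * real + (1 - e) * fake` is drawn with
#' `e ~ Uniform(0, 1)`, and the penalty is the mean over samples of
#' `(||grad_xhat critic(xhat)||_2 - 1)^2`, the norm taken over the full
#' `M x C` sample.
#'
#' For a `scbridge_critic` the input gradient is computed analytically by
#' backpropagation. Alternatively `critic` may be a list with elements
#' `score(x)` and `grad(x)` (both taking and returning `(n, M, C)`-shaped
#' arrays, `grad` returning per-sample input gradients) — used for closed-form
#' test oracles.
#'
#' @param critic A `scbridge_critic`, or a `list(score =, grad =)` pair.
#' @param real,fake Arrays `(n, M, C)` of identical shape.
#' @param eps Optional length-n vector of interpolation draws (defaults to
#'   fresh uniforms; expose for deterministic checks).
#' @return Scalar penalty (>= 0), with attribute `"grad_norms"`.
#' @export
gradient_penalty <- function(critic, real, fake, eps = NULL) {
  stopifnot(identical(dim(real), dim(fake)))
  n <- dim(real)[1]
  if (is.null(eps)) eps <- runif(n)
  xhat <- real * eps + fake * (1 - eps)     # eps recycles over the first dim
  if (inherits(critic, "scbridge_critic")) {
    Xh <- tensor_to_mat(xhat)
    fw <- critic_forward(critic, Xh)
    G <- critic_input_grad(critic, fw$cache)
    norms <- sqrt(colSums(G * G))
  } else {
    G <- critic$grad(xhat)
    norms <- sqrt(apply(G * G, 1, sum))
  }
  pen <- mean((norms - 1)^2)
  attr(pen, "grad_norms") <- norms
  pen
}

# Penalty value plus analytic parameter gradients (double backward). Masks are
# taken at the interpolates; conv biases and the dense bias do not influence
# the input gradient and receive zero.
gradient_penalty_backward <- function(critic, xhat_mat) {
  p <- critic$params
  M <- critic$M; C <- critic$C
  g1 <- critic$filters[1]; g2 <- critic$filters[2]
  n <- ncol(xhat_mat)
  fw <- critic_forward(critic, xhat_mat)
  M1 <- (fw$cache$C1 > 0) * 1
  M2 <- (fw$cache$C2 > 0) * 1
  A1 <- conv_matrix(p$conv1_W0, p$conv1_W1, M)
  A2 <- conv_matrix(p$conv2_W0, p$conv2_W1, M)
  V <- M2 * p$dense_w                        # columns: mask_i * w
  Zm <- M1 * crossprod(A2, V)                # (M*g1) x n
  G <- crossprod(A1, Zm)                     # input gradients, (M*C) x n
  norms <- sqrt(colSums(G * G))
  pen <- mean((norms - 1)^2)
  coef <- ifelse(norms > 1e-12, 2 * (norms - 1) / norms, 0)
  R <- sweep(G, 2, coef, `*`)                # dp_i / dG_i
  U1 <- A1 %*% R
  Q <- M1 * U1
  U2 <- A2 %*% Q
  S <- M2 * U2
  dA1 <- tcrossprod(Zm, R) / n
  dA2 <- tcrossprod(V, Q) / n
  k1 <- conv_matrix_grad(dA1, M, C, g1)
  k2 <- conv_matrix_grad(dA2, M, g1, g2)
  grads <- list(conv1_W0 = k1$dW0, conv1_W1 = k1$dW1, conv1_b = rep(0, g1),
                conv2_W0 = k2$dW0, conv2_W1 = k2$dW1, conv2_b = rep(0, g2),
                dense_w = rowSums(S) / n, dense_b = 0)
  list(penalty = pen, grads = grads, norms = norms)
}

# ---- training --------------------------------------------------------------

#' Train the WGAN-GP on a multiomic study
#'
#' Per generator step, `critic_updates` critic updates are performed, each on a
#' freshly assembled `MiniBatchTensor` (pre-matched across modalities in
#' unpaired mode, barcode-aligned in paired mode), followed by one generator
#' update. Losses are recorded per update. A non-finite loss triggers the
#' configured `nan_policy`: `"abort"` raises a descriptive error, `"restart"`
#' re-seeds (seed + 1000 * attempt) and retries up to 3 times.
#'
#' @param study A `MultiomicStudy` (eigenmaps are computed on demand for
#'   unpaired studies).
#' @param config A `TrainConfig` from [train_config()].
#' @return A `TrainedModel`: generator, critic, loss history
#'   (`critic_loss` per critic update, `generator_loss` per step), config and
#'   a fingerprint of the study.
#' @export
train_wgan <- function(study, config = train_config()) {
  stopifnot(inherits(study, "MultiomicStudy"), inherits(config, "TrainConfig"))
  for (v in study$modalities)
    if (n_cells(v) < config$N)
      stop("modality '", v$name, "' has fewer than N = ", config$N, " cells")
  if (!study$paired &&
      any(vapply(study$modalities, function(v) is.null(v$eigenmap), logical(1))))
    study <- prepare_study(study, regularize = TRUE)
  attempts <- if (config$nan_policy == "restart") 4L else 1L
  last_err <- NULL
  for (att in seq_len(attempts)) {
    seed <- config$seed + 1000L * (att - 1L)
    res <- tryCatch(train_wgan_once(study, config, seed),
                    scbridge_nan = function(e) e)
    if (!inherits(res, "condition")) {
      res$restarts <- att - 1L
      return(res)
    }
    last_err <- res
  }
  stop(conditionMessage(last_err))
}

train_wgan_once <- function(study, config, seed) {
  M <- n_modalities(study); C <- study$C
  with_seed(seed, {
    gen <- build_generator(M, C, config$latent_dim, config$gen_filters,
                           config$bn_momentum, config$bn_eps)
    critic <- build_critic(M, C, config$critic_filters)
    opt_g <- optimizer_init(gen$params, "adam")
    opt_c <- optimizer_init(critic$params, "rmsprop")
    ema <- NULL
    closs <- numeric(0)
    gloss <- numeric(0)
    nan_stop <- function(what, step) {
      cond <- structure(class = c("scbridge_nan", "error", "condition"),
                        list(message = paste0("non-finite ", what,
                                              " loss at generator step ", step,
                                              " (training collapsed; consider fewer ",
                                              "filters, a larger N or another seed)"),
                             call = NULL))
      stop(cond)
    }
    for (step in seq_len(config$steps)) {
      for (j in seq_len(config$critic_updates)) {
        tensor <- assemble_minibatch_tensor(study, N = config$N,
                                            n_candidates = config$n_candidates,
                                            strategy = config$strategy)
        Xr <- tensor_to_mat(tensor$data)
        Z <- matrix(rnorm(config$latent_dim * config$N), config$latent_dim)
        gf <- gen_forward(gen, Z, training = TRUE)
        gen <- gf$gen
        Xf <- gf$Y
        fw_r <- critic_forward(critic, Xr)
        fw_f <- critic_forward(critic, Xf)
        n <- config$N
        eps <- runif(n)
        xhat <- sweep(Xr, 2, eps, `*`) + sweep(Xf, 2, 1 - eps, `*`)
        gp <- gradient_penalty_backward(critic, xhat)
        loss <- mean(fw_f$s) - mean(fw_r$s) + config$gp_weight * gp$penalty
        if (!is.finite(loss)) nan_stop("critic", step)
        gr <- critic_backward(critic, fw_r$cache, rep(-1 / n, n))$grads
        gfk <- critic_backward(critic, fw_f$cache, rep(1 / n, n))$grads
        grads <- grads_add(grads_add(gr, gfk), gp$grads, config$gp_weight)
        up <- optimizer_step(opt_c, critic$params, grads, lr = config$critic_lr)
        opt_c <- up$state; critic$params <- up$params
        closs <- c(closs, loss)
      }
      Z <- matrix(rnorm(config$latent_dim * config$N), config$latent_dim)
      gf <- gen_forward(gen, Z, training = TRUE)
      gen <- gf$gen
      fw_f <- critic_forward(critic, gf$Y)
      loss_g <- -mean(fw_f$s)
      if (!is.finite(loss_g)) nan_stop("generator", step)
      dY <- critic_input_grad(critic, fw_f$cache,
                              ds = rep(-1 / config$N, config$N))
      ggrads <- gen_backward(gen, gf$cache, dY)
      up <- optimizer_step(opt_g, gen$params, ggrads, lr = config$gen_lr,
                           beta1 = config$gen_beta1, beta2 = config$gen_beta2,
                           eps = config$gen_eps)
      opt_g <- up$state; gen$params <- up$params
      if (config$ema_decay > 0) {
        # warmup schedule min(d, (1+t)/(10+t)): tracks the raw weights
        # closely early on, approaches the configured decay later, so short
        # runs are not dominated by the initial transient
        d <- min(config$ema_decay, (1 + step) / (10 + step))
        if (is.null(ema)) ema <- gen$params
        else for (nm in names(ema))
          ema[[nm]] <- d * ema[[nm]] + (1 - d) * gen$params[[nm]]
      }
      gloss <- c(gloss, loss_g)
    }
    if (!is.null(ema)) {
      gen$raw_params <- gen$params
      gen$params <- ema
    }
    structure(list(generator = gen, critic = critic,
                   loss_history = list(critic = closs, generator = gloss),
                   config = config, seed_used = seed,
                   modality_names = vapply(study$modalities, `[[`, "", "name"),
                   n_reference = n_cells(study$modalities[[study$reference_index]]),
                   study_fingerprint = list(M = M, C = C,
                                            n_cells = vapply(study$modalities, n_cells, integer(1)),
                                            paired = study$paired)),
              class = "TrainedModel")
  })
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel: M=%d, C=%d, %d generator steps, final losses c=%.3f g=%.3f\n",
              x$study_fingerprint$M, x$study_fingerprint$C,
              length(x$loss_history$generator),
              tail(x$loss_history$critic, 1), tail(x$loss_history$generator, 1)))
  invisible(x)
}

#' Generate synthetic multimodal cells from a trained model
#'
#' @param model A `TrainedModel`.
#' @param n_syn Number of synthetic cells (default: the size of the reference
#'   modality at training time). 0 yields an empty, well-formed output.
#' @param seed Seed for the noise draw.
#' @return A `SyntheticMultiomicOutput`.
#' @export
generate_cells <- function(model, n_syn = NULL, seed = 1L) {
  stopifnot(inherits(model, "TrainedModel"))
  if (is.null(n_syn)) n_syn <- model$n_reference
  n_syn <- as.integer(n_syn)
  if (n_syn < 0L) stop("n_syn must be >= 0")
  gen <- model$generator
  emb <- with_seed(seed, {
    if (n_syn == 0L) {
      array(0, dim = c(0L, gen$M, gen$C))
    } else {
      Z <- matrix(rnorm(gen$latent_dim * n_syn), gen$latent_dim)
      mat_to_tensor(gen_forward(gen, Z, training = FALSE)$Y, gen$M, gen$C)
    }
  })
  synthetic_output(emb, model$modality_names,
                   model_label = factor(rep("model_1", n_syn)),
                   provenance = list(seed = seed,
                                     steps = length(model$loss_history$generator),
                                     config_digest = config_digest(model$config)))
}

#' Semisupervised training: one model per batch label
#'
#' Trains an independent WGAN-GP per batch label on that batch's cells only
#' (every modality must carry batch labels over a common label set) and
#' concatenates the generated cells, recording the batch of origin as
#' `model_label`. Batches with fewer than N cells in any modality are skipped
#' with a warning.
#'
#' @param study A `MultiomicStudy` whose views have `batch_labels`.
#' @param config A `TrainConfig`.
#' @param n_syn Synthetic cells per batch model (default N).
#' @return A `SyntheticMultiomicOutput` with one `model_label` level per
#'   trained batch, plus attribute `"models"` (the per-batch `TrainedModel`s).
#' @export
train_semisupervised <- function(study, config = train_config(), n_syn = NULL) {
  stopifnot(inherits(study, "MultiomicStudy"))
  labs <- lapply(study$modalities, `[[`, "batch_labels")
  if (any(vapply(labs, is.null, logical(1))))
    stop("semisupervised training requires batch_labels on every modality")
  lev <- levels(labs[[1]])
  for (l in labs) if (!identical(levels(l), lev))
    stop("batch label sets differ across modalities")
  if (is.null(n_syn)) n_syn <- config$N
  outs <- list(); models <- list()
  for (b in lev) {
    views <- lapply(study$modalities, function(v) {
      keep <- which(v$batch_labels == b)
      subset_view(v, keep)
    })
    sizes <- vapply(views, n_cells, integer(1))
    if (any(sizes < config$N)) {
      warning("batch '", b, "' has fewer than N = ", config$N,
              " cells in some modality; skipped")
      next
    }
    sub <- multiomic_study(views, paired = study$paired,
                           reference_index = study$reference_index, C = study$C)
    model <- train_wgan(sub, config)
    out_b <- generate_cells(model, n_syn = n_syn, seed = config$seed + match(b, lev))
    out_b$model_label <- factor(rep(b, n_syn), levels = lev)
    outs[[b]] <- out_b
    models[[b]] <- model
  }
  if (!length(outs)) stop("no batch had enough cells to train on")
  emb <- do.call(abind1, lapply(outs, `[[`, "embeddings"))
  lab <- factor(unlist(lapply(outs, function(o) as.character(o$model_label))),
                levels = lev)
  res <- synthetic_output(emb, outs[[1]]$modality_names, model_label = lab,
                          provenance = list(seed = config$seed,
                                            batches = names(outs),
                                            config_digest = config_digest(config)))
  attr(res, "models") <- models
  res
}

# bind (n, M, C) arrays along the first dimension
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n_tot <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, dim = c(n_tot, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    if (np > 0) out[(at + 1):(at + np), , ] <- p
    at <- at + np
  }
  out
}

# restrict a ModalityView to a subset of cells (graph re-indexed)
subset_view <- function(v, keep) {
  modality_view(name = v$name,
                embedding = v$embedding[keep, , drop = FALSE],
                neighbor_graph = v$neighbor_graph[keep, keep, drop = FALSE],
                cell_ids = v$cell_ids[keep],
                features = if (!is.null(v$features)) v$features[keep, , drop = FALSE],
                feature_ids = v$feature_ids,
                cell_labels = if (!is.null(v$cell_labels)) droplevels_keep(v$cell_labels[keep]),
                batch_labels = if (!is.null(v$batch_labels)) v$batch_labels[keep])
}

droplevels_keep <- function(f) factor(as.character(f), levels = levels(f))

config_digest <- function(config) {
  x <- unclass(config)
  paste0("cfg-", substr(digest_vec(unlist(x, use.names = TRUE)), 1, 12))
}

# order-stable checksum without external digest packages
digest_vec <- function(x) {
  s <- paste(names(x), as.character(x), sep = "=", collapse = ";")
  raw <- utf8ToInt(s)
  h <- 5381
  for (r in raw) h <- (h * 33 + r) %% 2147483647
  sprintf("%08x%04x", as.integer(h), length(raw) %% 65536)
}

#' Hyperparameter sweep over filter counts and embedding widths
#'
#' Builds the cross product of candidate Conv1D filter counts and embedding
#' widths, trains one short model per combination and reports whether training
#' collapsed to non-finite losses (a known failure mode of narrow/wide
#' configurations).
#'
#' @param study A `MultiomicStudy` whose embeddings have at least
#'   `max(C_grid)` columns.
#' @param filters_grid Candidate filter counts (default
#'   `c(8, 32, 64, 128, 256, 512)`).
#' @param C_grid Candidate embedding widths (default `c(5, 10, 15)`).
#' @param base_config A `TrainConfig` supplying everything else.
#' @return A data.frame with one row per combination: filters, C, whether the
#'   run finished, and the final losses (NA on collapse).
#' @export
sweep_grid <- function(study, filters_grid = c(8L, 32L, 64L, 128L, 256L, 512L),
                       C_grid = c(5L, 10L, 15L), base_config = train_config(steps = 5L)) {
  grid <- expand.grid(filters = filters_grid, C = C_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- grid$filters[i]; Cw <- grid$C[i]
    res <- tryCatch({
      sub <- multiomic_study(study$modalities, paired = study$paired,
                             reference_index = study$reference_index, C = Cw)
      cfg <- base_config
      cfg$gen_filters <- c(f, f)
      cfg$critic_filters <- c(f, f)
      cfg$nan_policy <- "abort"
      m <- train_wgan(sub, cfg)
      data.frame(filters = f, C = Cw, ok = TRUE,
                 critic_loss = tail(m$loss_history$critic, 1),
                 generator_loss = tail(m$loss_history$generator, 1))
    }, error = function(e) {
      data.frame(filters = f, C = Cw, ok = FALSE,
                 critic_loss = NA_real_, generator_loss = NA_real_)
    })
    res
  })
  do.call(rbind, rows)
}
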