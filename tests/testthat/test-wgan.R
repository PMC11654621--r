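test_that("generator maps noise to (n, M, C) with deterministic inference", {
  withr::with_seed(31, {
    gen <- build_generator(M = 2L, C = 10L, latent_dim = 8L,
                           filters = c(16L, 8L))
    Z <- matrix(rnorm(4 * 8), 4, 8)
  })
  out <- generator_predict(gen, Z)
  expect_equal(dim(out), c(4L, 2L, 10L))
  # identical noise rows give identical outputs in inference mode
  Z2 <- Z[c(1, 1, 2, 2), ]
  out2 <- generator_predict(gen, Z2)
  expect_equal(out2[1, , ], out2[2, , ])
  expect_equal(out2[3, , ], out2[4, , ])
  # all-zero parameters produce all-zero output
  gen0 <- gen
  gen0$params <- lapply(gen0$params, function(p) p * 0)
  expect_true(all(generator_predict(gen0, Z) == 0))
  expect_error(build_generator(M = 1L, C = 3L), "M >= 2")
})

test_that("critic yields one differentiable score per sample", {
  withr::with_seed(32, {
    critic <- build_critic(M = 2L, C = 10L, filters = c(8L, 16L))
    x <- array(rnorm(8 * 2 * 10), c(8, 2, 10))
  })
  s <- critic_score(critic, x)
  expect_length(s, 8L)
  # zero parameters: every score equals the head bias
  c0 <- critic
  c0$params <- lapply(c0$params, function(p) p * 0)
  c0$params$dense_b <- 1.5
  expect_equal(critic_score(c0, x), rep(1.5, 8))
  # input gradient exists and is finite
  fw <- scbridge:::critic_forward(critic, scbridge:::tensor_to_mat(x))
  g <- scbridge:::critic_input_grad(critic, fw$cache)
  expect_true(all(is.finite(g)))
  expect_equal(dim(g), c(20L, 8L))
})

test_that("the critic is structurally free of batch normalization", {
  critic <- build_critic(2L, 5L, filters = c(4L, 8L))
  expect_false(any(grepl("bn", names(critic$params))))
  expect_null(critic$run)
})

test_that("gradient penalty matches closed-form critics", {
  withr::with_seed(33, {
    real <- array(rnorm(6 * 2 * 5), c(6, 2, 5))
    fake <- array(rnorm(6 * 2 * 5), c(6, 2, 5))
  })
  # critic(x) = x[1,1]: unit gradient everywhere -> penalty 0
  unitc <- list(score = function(x) x[, 1, 1],
                grad = function(x) { g <- x * 0; g[, 1, 1] <- 1; g })
  expect_equal(as.numeric(gradient_penalty(unitc, real, fake)), 0)
  # critic(x) = 2 x[1,1]: penalty (2-1)^2 = 1
  twoc <- list(score = function(x) 2 * x[, 1, 1],
               grad = function(x) { g <- x * 0; g[, 1, 1] <- 2; g })
  expect_equal(as.numeric(gradient_penalty(twoc, real, fake)), 1)
  # constant critic: zero gradient -> penalty 1
  constc <- list(score = function(x) rep(7, dim(x)[1]),
                 grad = function(x) x * 0)
  expect_equal(as.numeric(gradient_penalty(constc, real, fake)), 1)
})

test_that("penalty from the analytic path agrees with the generic formula", {
  withr::with_seed(34, {
    critic <- build_critic(2L, 6L, filters = c(5L, 7L))
    critic$params$conv1_b <- rnorm(5, sd = 0.3)
    critic$params$conv2_b <- rnorm(7, sd = 0.3)
    real <- array(rnorm(10 * 2 * 6), c(10, 2, 6))
    fake <- array(rnorm(10 * 2 * 6), c(10, 2, 6))
    eps <- runif(10)
  })
  p1 <- gradient_penalty(critic, real, fake, eps = eps)
  xhat_mat <- scbridge:::tensor_to_mat(real * eps + fake * (1 - eps))
  p2 <- scbridge:::gradient_penalty_backward(critic, xhat_mat)
  expect_equal(as.numeric(p1), p2$penalty, tolerance = 1e-12)
})

test_that("critic and generator losses follow the Wasserstein arithmetic", {
  expect_equal(critic_loss(c(1, 1), c(0, 0), gp = 0), -1)
  expect_equal(critic_loss(c(2, 4), c(2, 4), gp = 0), 0)
  expect_equal(critic_loss(c(1, 1), c(1, 1), gp = 1, lambda = 10), 10)
  expect_equal(generator_loss(c(2, 4)), -3)
  expect_equal(generator_loss(0), 0)
  expect_equal(generator_loss(c(-1, 1)), 0)
  expect_error(generator_loss(numeric(0)))
})

test_that("analytic critic gradients (including the GP double backward) match finite differences", {
  withr::with_seed(35, {
    M <- 2L; C <- 3L; n <- 6L
    critic <- build_critic(M, C, filters = c(4L, 5L))
    critic$params$conv1_b <- rnorm(4, sd = 0.3)
    critic$params$conv2_b <- rnorm(5, sd = 0.3)
    real <- array(rnorm(n * M * C), c(n, M, C))
    fake <- array(rnorm(n * M * C), c(n, M, C))
    eps <- runif(n)
  })
  lambda <- 10
  Xr <- scbridge:::tensor_to_mat(real)
  Xf <- scbridge:::tensor_to_mat(fake)
  xhat <- sweep(Xr, 2, eps, `*`) + sweep(Xf, 2, 1 - eps, `*`)
  loss_fn <- function(params) {
    cr <- critic; cr$params <- params
    sr <- scbridge:::critic_forward(cr, Xr)$s
    sf <- scbridge:::critic_forward(cr, Xf)$s
    gp <- scbridge:::gradient_penalty_backward(cr, xhat)$penalty
    mean(sf) - mean(sr) + lambda * gp
  }
  fw_r <- scbridge:::critic_forward(critic, Xr)
  fw_f <- scbridge:::critic_forward(critic, Xf)
  gr <- scbridge:::critic_backward(critic, fw_r$cache, rep(-1 / n, n))$grads
  gf <- scbridge:::critic_backward(critic, fw_f$cache, rep(1 / n, n))$grads
  gp <- scbridge:::gradient_penalty_backward(critic, xhat)
  ga <- scbridge:::grads_add(scbridge:::grads_add(gr, gf), gp$grads, lambda)
  h <- 1e-6
  for (nm in names(critic$params)) {
    p <- critic$params[[nm]]
    gnum <- p * 0
    for (i in seq_along(p)) {
      pp <- critic$params; pp[[nm]][i] <- p[i] + h
      pm <- critic$params; pm[[nm]][i] <- p[i] - h
      gnum[i] <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
    }
    expect_lt(max(abs(gnum - ga[[nm]])), 1e-5)
  }
})

test_that("analytic generator gradients match finite differences through batch norm", {
  withr::with_seed(36, {
    M <- 2L; C <- 3L; n <- 6L
    critic <- build_critic(M, C, filters = c(4L, 5L))
    gen <- build_generator(M, C, latent_dim = 4L, filters = c(5L, 4L))
    gen$params$conv1_b <- rnorm(5, sd = 0.3)
    Z <- matrix(rnorm(4 * n), 4, n)
  })
  loss_fn <- function(params) {
    g2 <- gen; g2$params <- params
    out <- scbridge:::gen_forward(g2, Z, training = TRUE)
    -mean(scbridge:::critic_forward(critic, out$Y)$s)
  }
  out <- scbridge:::gen_forward(gen, Z, training = TRUE)
  fw <- scbridge:::critic_forward(critic, out$Y)
  dY <- scbridge:::critic_input_grad(critic, fw$cache, ds = rep(-1 / n, n))
  ga <- scbridge:::gen_backward(gen, out$cache, dY)
  h <- 1e-6
  for (nm in names(gen$params)) {
    p <- gen$params[[nm]]
    gnum <- p * 0
    for (i in seq_along(p)) {
      pp <- gen$params; pp[[nm]][i] <- p[i] + h
      pm <- gen$params; pm[[nm]][i] <- p[i] - h
      gnum[i] <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
    }
    expect_lt(max(abs(gnum - ga[[nm]])), 1e-5)
  }
})

test_that("one training step records the advertised loss bookkeeping", {
  st <- small_paired_study()
  cfg <- train_config(steps = 1L, N = 32L, gen_filters = c(8L, 8L),
                      critic_filters = c(8L, 16L), critic_updates = 5L,
                      seed = 37L)
  model <- train_wgan(st, cfg)
  expect_length(model$loss_history$generator, 1L)
  expect_length(model$loss_history$critic, 5L)
  expect_true(all(is.finite(unlist(model$loss_history))))
})

test_that("training is deterministic under a fixed seed", {
  st <- small_paired_study()
  cfg <- train_config(steps = 3L, N = 32L, gen_filters = c(8L, 8L),
                      critic_filters = c(8L, 16L), seed = 38L)
  m1 <- train_wgan(st, cfg)
  m2 <- train_wgan(st, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  o1 <- generate_cells(m1, n_syn = 10L, seed = 1L)
  o2 <- generate_cells(m2, n_syn = 10L, seed = 1L)
  expect_identical(o1$embeddings, o2$embeddings)
})

test_that("generation respects n_syn, seeds, and rejects negatives", {
  model <- small_model()
  expect_equal(dim(generate_cells(model, n_syn = 0L)$embeddings)[1], 0L)
  out <- generate_cells(model, n_syn = 17L, seed = 4L)
  expect_equal(dim(out$embeddings), c(17L, 2L, 10L))
  expect_true(all(is.finite(out$embeddings)))
  out2 <- generate_cells(model, n_syn = 17L, seed = 4L)
  expect_identical(out$embeddings, out2$embeddings)
  expect_error(generate_cells(model, n_syn = -1L), "n_syn")
  # default n_syn follows the reference modality size
  expect_equal(dim(generate_cells(model, seed = 1L)$embeddings)[1],
               n_cells(small_study()$modalities[[1]]))
})

test_that("semisupervised training emits one labelled block per batch", {
  pop <- latent_population(K = 2L, d_latent = 4L, within_sd = 1, seed = 40L)
  renders <- list(modality_render(diag(4), embed_noise_sd = 0.2, name = "A"),
                  modality_render(diag(4), embed_noise_sd = 0.2, name = "B"))
  st <- generate_study(pop, renders, n_cells = 240L, paired = FALSE,
                       batches = list(b1 = rep(-8, 4), b2 = rep(8, 4)),
                       seed = 41L, knn = 8L)
  st <- prepare_study(st, regularize = TRUE)
  cfg <- train_config(steps = 250L, N = 32L, gen_filters = c(16L, 8L),
                      critic_filters = c(16L, 32L), seed = 42L)
  out <- train_semisupervised(st, cfg, n_syn = 40L)
  expect_equal(nlevels(out$model_label), 2L)
  expect_equal(as.numeric(table(out$model_label)), c(40, 40))
  expect_equal(dim(out$embeddings), c(80L, 2L, 4L))
  # well-separated batches: most synthetic cells sit among their own batch
  ref <- st$modalities[[1]]
  nn <- scbridge:::knn_query(ref$embedding, modality_slice(out, 1), 1L)
  agree <- mean(as.character(ref$batch_labels[nn$index[, 1]]) ==
                  as.character(out$model_label))
  expect_gte(agree, 0.9)
})

test_that("the hyperparameter sweep reports one row per configuration", {
  st <- small_paired_study()
  cfg <- train_config(steps = 2L, N = 32L, seed = 44L)
  res <- withr::with_seed(44, sweep_grid(st, filters_grid = c(8L, 16L),
                                         C_grid = c(5L, 10L),
                                         base_config = cfg))
  expect_equal(nrow(res), 4L)
  expect_setequal(names(res), c("filters", "C", "ok", "critic_loss",
                                "generator_loss"))
  expect_true(all(is.finite(res$critic_loss[res$ok])))
  # requested widths are capped by the study's rank
  expect_true(all(res$C %in% c(5L, 10L)))
})

test_that("a batch below the mini-batch size is skipped with a warning", {
  st <- small_study()
  st$modalities <- lapply(st$modalities, function(v) {
    v$batch_labels <- factor(c("tiny", rep("big", n_cells(v) - 1L)),
                             levels = c("big", "tiny"))
    v
  })
  cfg <- train_config(steps = 2L, N = 48L, gen_filters = c(8L, 8L),
                      critic_filters = c(8L, 16L), seed = 43L)
  expect_warning(out <- train_semisupervised(st, cfg, n_syn = 10L), "skipped")
  expect_equal(as.character(unique(out$model_label)), "big")
})
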