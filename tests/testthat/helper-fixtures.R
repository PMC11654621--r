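# Shared fixtures, built in code and memoized per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) assign(key, expr, envir = fixture_env)
  get(key, envir = fixture_env)
}

# unpaired 3-population study (fast; shared across modules). 1000 cells: large
# enough that the eigenmap orientation alignment across modalities is driven
# by geometry rather than sampling noise.
small_study <- function() memo("small_study", {
  prepare_study(standard_fixture(n_cells = 1000L, seed = 101L, n_features = 30L),
                regularize = TRUE)
})

# paired variant
small_paired_study <- function() memo("small_paired", {
  standard_fixture(n_cells = 300L, paired = TRUE, seed = 102L, n_features = 20L)
})

# zero-noise study: features are an exact softplus map of the embedding
noiseless_study <- function() memo("noiseless_study", {
  pop <- latent_population(K = 3L, d_latent = 4L, within_sd = 1, center_scale = 8,
                           seed = 3L)
  load1 <- diag(1, 4, 4)
  renders <- list(
    modality_render(load1, embed_noise_sd = 0, n_features = 25L,
                    feature_noise_sd = 0, name = "RNA", seed = 4L),
    modality_render(load1, embed_noise_sd = 0, n_features = 0L,
                    name = "ATAC", seed = 5L)
  )
  generate_study(pop, renders, n_cells = 300L, seed = 6L)
})

# features with strong planted cluster markers; returns list(features, labels)
planted_marker_data <- function(n_per = 80L, n_types = 3L, n_markers = 20L,
                                n_noise = 30L, effect = 3, noise_sd = 0.5,
                                seed = 77L) {
  withr::with_seed(seed, {
    n <- n_per * n_types
    labels <- factor(rep(paste0("type_", seq_len(n_types)), each = n_per))
    f_tot <- n_types * n_markers + n_noise
    X <- matrix(abs(rnorm(n * f_tot, sd = noise_sd)), n, f_tot)
    for (t in seq_len(n_types)) {
      rows <- which(labels == paste0("type_", t))
      cols <- ((t - 1) * n_markers + 1):(t * n_markers)
      X[rows, cols] <- X[rows, cols] + effect
    }
    colnames(X) <- c(paste0("marker_", rep(seq_len(n_types), each = n_markers),
                            "_", rep(seq_len(n_markers), n_types)),
                     paste0("noise_", seq_len(n_noise)))
    list(features = X, labels = labels,
         marker_cols = lapply(seq_len(n_types), function(t)
           colnames(X)[((t - 1) * n_markers + 1):(t * n_markers)]))
  })
}

# tiny deterministic trained model on the small study (shared by bridge tests)
small_model <- function() memo("small_model", {
  cfg <- train_config(steps = 60L, N = 48L, gen_filters = c(32L, 16L),
                      critic_filters = c(32L, 64L), seed = 11L)
  train_wgan(small_study(), cfg)
})
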