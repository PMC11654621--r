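# Simulator of multimodal single-cell studies with known ground truth.
#
# The generative model: K latent cell populations (isotropic Gaussians in a
# d_latent-dimensional biology space) observed through modality-specific
# linear maps plus Gaussian noise. Paired studies reuse one latent draw for
# every modality (shared barcodes); unpaired studies draw independent cells
# from the same population. Optional batch structure adds offsets in latent
# space before rendering, emulating sample-of-origin effects.

#' Specify latent cell populations
#'
#' @param K Number of populations (clusters).
#' @param proportions Simplex vector of length K (must sum to 1 within 1e-9);
#'   defaults to equal proportions.
#' @param centers `K x d_latent` matrix of population centres; defaults to
#'   well-separated random centres scaled by `center_scale`.
#' @param within_sd Within-population standard deviation (isotropic), > 0.
#' @param d_latent Latent dimensionality (used when `centers` is `NULL`).
#' @param center_scale Scale of the default random centres.
#' @param seed Seed used only to draw default centres.
#'
#' @return A `LatentPopulationSpec` list.
#' @export
latent_population <- function(K = 3L, proportions = NULL, centers = NULL,
                              within_sd = 1, d_latent = 8L, center_scale = 6,
                              seed = 11L) {
  K <- as.integer(K)
  if (is.null(proportions)) proportions <- rep(1 / K, K)
  if (length(proportions) != K)
    stop("proportions must have length K")
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions <= 0))
    stop("proportions must be a strictly positive simplex vector (sum 1 within 1e-9)")
  if (within_sd <= 0) stop("within_sd must be > 0")
  if (is.null(centers)) {
    centers <- with_seed(seed, matrix(rnorm(K * d_latent, sd = center_scale), K, d_latent))
  }
  centers <- as.matrix(centers)
  if (nrow(centers) != K) stop("centers must have K rows")
  structure(list(K = K, proportions = as.numeric(proportions),
                 centers = centers, within_sd = within_sd,
                 d_latent = ncol(centers)),
            class = "LatentPopulationSpec")
}

#' Specify how a modality renders latent cells
#'
#' The embedding is `latent %*% load_matrix` plus isotropic Gaussian noise.
#' Features are `softplus(embedding %*% feature_map)` plus noise (softplus
#' keeps them non-negative, loosely mimicking normalized expression); set
#' `feature_nonlinearity = "linear"` for exactness tests.
#'
#' @param load_matrix `d_latent x C` map from latent space to the embedding.
#' @param embed_noise_sd Non-negative embedding noise sd.
#' @param n_features Number of rendered features (0 disables features).
#' @param feature_map Optional `C x n_features` non-negative map; defaults to a
#'   sparse random non-negative map.
#' @param feature_noise_sd Non-negative feature noise sd.
#' @param feature_nonlinearity `"softplus"` (default) or `"linear"`.
#' @param name Modality name.
#' @param seed Seed used only to draw a default `feature_map`.
#'
#' @return A `ModalityRenderSpec` list.
#' @export
modality_render <- function(load_matrix, embed_noise_sd = 0.1,
                            n_features = 0L, feature_map = NULL,
                            feature_noise_sd = 0.1,
                            feature_nonlinearity = c("softplus", "linear"),
                            name = "modality", seed = 13L) {
  feature_nonlinearity <- match.arg(feature_nonlinearity)
  load_matrix <- as.matrix(load_matrix)
  C <- ncol(load_matrix)
  n_features <- as.integer(n_features)
  if (embed_noise_sd < 0 || feature_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (n_features > 0L && is.null(feature_map)) {
    feature_map <- with_seed(seed, {
      fm <- matrix(runif(C * n_features), C, n_features)
      fm[fm < 0.7] <- 0                      # sparse non-negative loading
      fm
    })
  }
  if (!is.null(feature_map)) {
    feature_map <- as.matrix(feature_map)
    if (nrow(feature_map) != C) stop("feature_map must have C rows")
    if (ncol(feature_map) != n_features) stop("feature_map must have n_features columns")
    if (any(feature_map < 0)) stop("feature_map must be non-negative")
  }
  structure(list(load_matrix = load_matrix, embed_noise_sd = embed_noise_sd,
                 n_features = n_features, feature_map = feature_map,
                 feature_noise_sd = feature_noise_sd,
                 feature_nonlinearity = feature_nonlinearity, name = name),
            class = "ModalityRenderSpec")
}

#' Draw latent cells from a population spec
#'
#' Cluster sizes are multinomial with the spec's proportions; cells are drawn
#' from isotropic Gaussians at their population centre.
#'
#' @param spec A `LatentPopulationSpec`.
#' @param n Number of cells (>= 1).
#' @return List with `latent` (`n x d_latent`) and `cluster` (factor length n).
#' @export
sample_latent <- function(spec, n) {
  stopifnot(inherits(spec, "LatentPopulationSpec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  sizes <- as.vector(rmultinom(1, n, spec$proportions))
  cluster <- rep(seq_len(spec$K), sizes)
  latent <- spec$centers[cluster, , drop = FALSE] +
    matrix(rnorm(n * spec$d_latent, sd = spec$within_sd), n, spec$d_latent)
  # shuffle so cluster blocks are not contiguous
  ord <- sample.int(n)
  list(latent = latent[ord, , drop = FALSE],
       cluster = factor(paste0("pop_", cluster[ord])))
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Render a modality view from latent cells
#'
#' @param latent `n x d_latent` latent matrix.
#' @param spec A `ModalityRenderSpec`.
#' @param cluster Optional ground-truth cluster factor attached as
#'   `cell_labels`.
#' @param batch Optional batch factor attached as `batch_labels`.
#' @param cell_ids Optional barcodes.
#' @param knn Neighbourhood size for the kNN graph.
#' @return A `ModalityView` with ground-truth labels attached.
#' @export
render_modality <- function(latent, spec, cluster = NULL, batch = NULL,
                            cell_ids = NULL, knn = 15L) {
  stopifnot(inherits(spec, "ModalityRenderSpec"))
  latent <- as.matrix(latent)
  if (ncol(latent) != nrow(spec$load_matrix))
    stop("latent dimensionality does not match the render spec's load_matrix")
  n <- nrow(latent)
  emb <- latent %*% spec$load_matrix
  if (spec$embed_noise_sd > 0)
    emb <- emb + matrix(rnorm(length(emb), sd = spec$embed_noise_sd), n)
  features <- NULL
  if (spec$n_features > 0L) {
    lin <- emb %*% spec$feature_map
    features <- if (spec$feature_nonlinearity == "softplus") softplus(lin) else lin
    if (spec$feature_noise_sd > 0)
      features <- features + matrix(rnorm(length(features), sd = spec$feature_noise_sd), n)
  }
  modality_view(name = spec$name, embedding = emb, cell_ids = cell_ids,
                features = features, cell_labels = cluster,
                batch_labels = batch, knn = knn)
}

#' Generate a full multimodal study with known ground truth
#'
#' Paired mode reuses one latent draw for every modality (shared barcodes);
#' unpaired mode draws an independent sample per modality from the same latent
#' population, so modalities share biology but not cells. Batch offsets, when
#' given, are added in latent space before rendering and recorded as
#' `batch_labels`.
#'
#' @param pop A `LatentPopulationSpec`.
#' @param renders List of `ModalityRenderSpec` (length M >= 2).
#' @param n_cells Integer vector of per-modality cell counts (recycled; paired
#'   mode requires equal counts).
#' @param paired Logical.
#' @param batches Optional named list of latent offset vectors, one per batch
#'   label; cells are assigned to batches uniformly.
#' @param seed Integer seed; the same seed yields a byte-identical study.
#' @param knn Neighbourhood size for kNN graphs.
#' @param reference_index Reference modality for the study.
#'
#' @return A `MultiomicStudy` whose views carry ground-truth `cell_labels`.
#' @export
generate_study <- function(pop, renders, n_cells = 3000L, paired = FALSE,
                           batches = NULL, seed = 1L, knn = 15L,
                           reference_index = 1L) {
  stopifnot(inherits(pop, "LatentPopulationSpec"))
  M <- length(renders)
  if (M < 2L) stop("need at least two modality render specs")
  n_cells <- rep(as.integer(n_cells), length.out = M)
  if (paired && length(unique(n_cells)) != 1L)
    stop("paired mode requires equal cell counts across modalities")
  with_seed(seed, {
    draw_batch <- function(n) {
      if (is.null(batches)) return(NULL)
      factor(sample(names(batches), n, replace = TRUE), levels = names(batches))
    }
    offset_latent <- function(latent, batch) {
      if (is.null(batch)) return(latent)
      off <- do.call(rbind, batches)[as.integer(batch), , drop = FALSE]
      latent + off
    }
    views <- vector("list", M)
    if (paired) {
      n <- n_cells[1]
      drawn <- sample_latent(pop, n)
      batch <- draw_batch(n)
      latent <- offset_latent(drawn$latent, batch)
      ids <- sprintf("BC%06d", seq_len(n))
      for (m in seq_len(M)) {
        views[[m]] <- render_modality(latent, renders[[m]], cluster = drawn$cluster,
                                      batch = batch, cell_ids = ids, knn = knn)
      }
    } else {
      for (m in seq_len(M)) {
        n <- n_cells[m]
        drawn <- sample_latent(pop, n)
        batch <- draw_batch(n)
        latent <- offset_latent(drawn$latent, batch)
        ids <- sprintf("%s_%06d", renders[[m]]$name, seq_len(n))
        views[[m]] <- render_modality(latent, renders[[m]], cluster = drawn$cluster,
                                      batch = batch, cell_ids = ids, knn = knn)
      }
    }
    multiomic_study(views, paired = paired, reference_index = reference_index)
  })
}

#' The standard simulated fixture
#'
#' A convenience wrapper producing the default desk-scale study used throughout
#' the documentation and tests: K = 3 latent populations in 8 latent
#' dimensions, rendered into two modalities ("RNA"-like with features and
#' "ATAC"-like) with 10 embedding dimensions each. Orthonormal-ish load
#' matrices keep the population geometry; small isotropic noise is added.
#'
#' @param n_cells Cells per modality (default 3000).
#' @param paired Logical (default `FALSE`).
#' @param seed Study seed.
#' @param n_features Features on the first modality (default 60).
#' @param within_sd Within-population sd (default 1).
#' @param batches Optional named list of latent batch offsets (see
#'   [generate_study()]).
#' @param knn kNN graph size.
#' @return A `MultiomicStudy`.
#' @export
standard_fixture <- function(n_cells = 3000L, paired = FALSE, seed = 1L,
                             n_features = 60L, within_sd = 1, batches = NULL,
                             knn = 15L) {
  # The populations sit along a differentiation-like axis with mild lateral
  # offsets (~4-4.7 sd between neighbours): distinct clusters whose kNN graph
  # stays connected and whose coarse order is carried by a single axis. Both
  # properties are operating assumptions of the eigenmap ordering — a
  # disconnected graph degenerates the first nontrivial eigenvector, and two
  # clusters placed symmetrically about the leading axis cannot be told apart
  # by its one retained component. Spacings and population proportions are
  # deliberately unequal, as in real tissues; the resulting asymmetry of the
  # eigenmap value distribution is also what anchors the cross-modality
  # orientation alignment (a perfectly symmetric arrangement would leave the
  # orientation statistically undetermined).
  centers <- matrix(0, 3, 8)
  centers[, 1] <- c(-4.6, 0, 4)
  centers[, 2] <- c(-0.75, 1.5, -0.75)
  pop <- latent_population(K = 3L, d_latent = 8L, within_sd = within_sd,
                           proportions = c(0.45, 0.30, 0.25),
                           centers = centers)
  loads <- with_seed(101L, list(
    qr.Q(qr(matrix(rnorm(10 * 8), 10, 8)))[, 1:8],
    qr.Q(qr(matrix(rnorm(10 * 8), 10, 8)))[, 1:8]
  ))
  renders <- list(
    modality_render(t(loads[[1]]), embed_noise_sd = 0.3, n_features = n_features,
                    name = "RNA", seed = 21L),
    modality_render(t(loads[[2]]), embed_noise_sd = 0.3, n_features = 0L,
                    name = "ATAC", seed = 22L)
  )
  generate_study(pop, renders, n_cells = n_cells, paired = paired,
                 batches = batches, seed = seed, knn = knn)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
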