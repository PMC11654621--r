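# Mini-batch pre-matching across modalities.
#
# Unpaired modalities share no cells, so mini-batches presented jointly to the
# GAN must be matched by structure rather than by barcode. Each modality's
# cells are ordered by the first nontrivial eigenvector of the symmetric
# normalized graph Laplacian of its kNN graph (the Laplacian eigenmap first
# component, which sorts cells by local graph structure). A source mini-batch
# is drawn from the reference modality; a Bayesian ridge regressor fitted on
# the source (embedding -> eigenmap value) scores candidate mini-batches from
# each other modality, and the best-scoring candidate is coupled with the
# source.

#' Laplacian-eigenmap ordering of a modality
#'
#' Computes the first nontrivial eigenvector of the symmetric normalized
#' Laplacian `L = I - D^{-1/2} W D^{-1/2}` of the view's affinity graph
#' (equivalently the second-largest eigenvector of `D^{-1/2} W D^{-1/2}`),
#' picks the canonical sign so that the vector's sum is >= 0 (first non-zero
#' entry positive on an exact tie), and stores both the eigenmap vector and the
#' ascending ordering on the view.
#'
#' @param view A `ModalityView`.
#' @param regularize If `TRUE`, a uniform affinity `eps = 1e-8` is added
#'   between all cell pairs so that a disconnected graph becomes connected;
#'   otherwise a disconnected graph is an error.
#' @return The view with `$eigenmap` (numeric vector) and `$eigenmap_order`
#'   (integer permutation, ascending eigenmap value) filled in.
#' @export
eigenmap_order <- function(view, regularize = FALSE) {
  stopifnot(inherits(view, "ModalityView"))
  W <- view$neighbor_graph
  n <- nrow(W)
  if (n < 3L) stop("eigenmap ordering needs at least 3 cells")
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    W, mode = "undirected", weighted = TRUE))
  eps <- 0
  if (comp$no > 1L) {
    if (!regularize)
      stop("neighbor graph has ", comp$no,
           " connected components; re-run with regularize = TRUE ",
           "to add a uniform affinity of 1e-8")
    eps <- 1e-8
  }
  d <- Matrix::rowSums(W) + eps * (n - 1)
  dis <- 1 / sqrt(d)
  v2 <- if (n <= 200L) {
    S <- Matrix::Diagonal(x = dis) %*% W %*% Matrix::Diagonal(x = dis)
    S <- as.matrix(S) + eps * outer(dis, dis)
    diag(S) <- diag(S) - eps * dis^2         # affinity added between pairs only
    es <- eigen(S, symmetric = TRUE)
    es$vectors[, 2]
  } else {
    # matrix-free S v = D^{-1/2} (W + eps(11' - I)) D^{-1/2} v
    matvec <- function(x, args = NULL) {
      y <- dis * as.vector(W %*% (dis * x))
      if (eps > 0) y <- y + eps * dis * (sum(dis * x) - dis * x)
      y
    }
    init <- sin(seq_len(n))                  # fixed start vector: deterministic
    es <- RSpectra::eigs_sym(matvec, k = 2, n = n, which = "LA",
                             opts = list(initvec = init, tol = 1e-10))
    if (length(es$values) < 2)
      stop("eigensolver failed to converge on the neighbor graph")
    es$vectors[, 2]
  }
  s <- sum(v2)
  if (abs(s) < 1e-12) {
    nz <- which(abs(v2) > 1e-12)[1]
    if (!is.na(nz) && v2[nz] < 0) v2 <- -v2
  } else if (s < 0) v2 <- -v2
  view$eigenmap <- as.numeric(v2)
  view$eigenmap_order <- order(view$eigenmap, seq_along(v2))
  view
}

#' Fit a Bayesian ridge regressor by evidence maximization
#'
#' Linear-Gaussian model `y = X w + b + noise` with a Gaussian prior on `w`;
#' the noise precision `alpha` and weight precision `lambda` are set by
#' iterative evidence (type-II likelihood) maximization with conjugate Gamma
#' hyperpriors (shape/rate 1e-6), convergence when the L1 change in `w` drops
#' below `tol`.
#'
#' @param X `N x C` numeric matrix.
#' @param y Numeric vector of length N.
#' @param tol Convergence tolerance on the coefficients (default 1e-3).
#' @param max_iter Maximum update iterations (default 300).
#' @return A `RidgeModel` list with `weights`, `intercept`, `alpha` (noise
#'   precision) and `lambda` (weight precision).
#' @export
fit_minibatch_regressor <- function(X, y, tol = 1e-3, max_iter = 300L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in the regression inputs")
  n <- nrow(X); C <- ncol(X)
  if (length(y) != n) stop("X and y disagree on N")
  if (n <= C)
    warning("N <= C: evidence maximization may be ill-conditioned")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  sv <- svd(Xc)
  s2 <- sv$d^2
  uty <- crossprod(sv$u, yc)                  # U' y
  a1 <- a2 <- l1 <- l2 <- 1e-6                # Gamma hyperpriors
  vy <- var(y) * (n - 1) / n
  alpha <- if (is.finite(vy) && vy > 0) 1 / vy else 1
  lambda <- 1
  w_old <- rep(Inf, C)
  for (iter in seq_len(max_iter)) {
    shrink <- sv$d / (s2 + lambda / alpha)
    w <- sv$v %*% (shrink * uty)
    gamma_eff <- sum(alpha * s2 / (alpha * s2 + lambda))
    rss <- sum((yc - Xc %*% w)^2)
    lambda <- (gamma_eff + 2 * l1) / (sum(w^2) + 2 * l2)
    alpha <- (n - gamma_eff + 2 * a1) / (rss + 2 * a2)
    if (sum(abs(w - w_old)) < tol) break
    w_old <- w
  }
  structure(list(weights = as.numeric(w),
                 intercept = ym - sum(xm * as.numeric(w)),
                 alpha = alpha, lambda = lambda, n_iter = iter),
            class = "RidgeModel")
}

#' Predict from a RidgeModel
#' @param object A `RidgeModel`.
#' @param newdata `N x C` matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.RidgeModel <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$weights + object$intercept)
}

#' Score a candidate mini-batch under a fitted regressor
#'
#' The score is the coefficient of determination (R^2) of the regressor's
#' predictions of the candidate's eigenmap values from its embedding: 1 is a
#' perfect structural match, values can be negative, and a zero-variance
#' candidate scores 0 by convention.
#'
#' @param model A `RidgeModel`.
#' @param Xc Candidate `N x C` embedding rows.
#' @param yc Candidate eigenmap values (length N).
#' @return A real score (<= 1).
#' @export
score_candidate <- function(model, Xc, yc) {
  yc <- as.numeric(yc)
  tss <- sum((yc - mean(yc))^2)
  if (tss <= 0) return(0)
  pred <- predict(model, Xc)
  1 - sum((yc - pred)^2) / tss
}

# Draw candidate index sets from a view whose eigenmap is computed.
# strategy "window": contiguous windows of N cells at uniform random offsets in
# the eigenmap-sorted order (so each candidate is a structurally coherent
# neighbourhood); "random": unordered random subsets, then sorted by eigenmap.
draw_candidates <- function(view, N, n_candidates,
                            strategy = c("window", "random")) {
  strategy <- match.arg(strategy)
  n <- n_cells(view)
  if (n < N) stop("modality '", view$name, "' has fewer than N = ", N,
                  " cells; choose a smaller batch size")
  ord <- view$eigenmap_order
  if (strategy == "window") {
    offs <- sample.int(n - N + 1L, n_candidates, replace = TRUE)
    lapply(offs, function(o) ord[o:(o + N - 1L)])
  } else {
    lapply(seq_len(n_candidates), function(i) {
      idx <- sample.int(n, N)
      idx[order(view$eigenmap[idx], idx)]
    })
  }
}

#' Select the best-matching mini-batch from a target modality
#'
#' Fits the Bayesian ridge regressor on the source batch (embedding X vs
#' eigenmap y), draws `n_candidates` candidate batches from the target and
#' returns the indices of the highest-scoring candidate (ties broken by the
#' first candidate drawn).
#'
#' @param source_X Source batch embedding (`N x C`).
#' @param source_y Source batch eigenmap values (length N).
#' @param target A `ModalityView` with its eigenmap computed.
#' @param n_candidates Number of candidate batches (default 50).
#' @param N Mini-batch size (default 256); the target must have >= N cells.
#' @param strategy Candidate sampling strategy, `"window"` (default) or
#'   `"random"`.
#' @return Integer vector of N target cell indices, ordered by eigenmap value.
#' @export
select_matching_minibatch <- function(source_X, source_y, target,
                                      n_candidates = 50L, N = 256L,
                                      strategy = c("window", "random")) {
  strategy <- match.arg(strategy)
  if (is.null(target$eigenmap))
    stop("target modality needs eigenmap_order() first")
  model <- fit_minibatch_regressor(source_X, source_y)
  cands <- draw_candidates(target, N, n_candidates, strategy)
  scores <- vapply(cands, function(idx) {
    score_candidate(model, target$embedding[idx, , drop = FALSE],
                    target$eigenmap[idx])
  }, numeric(1))
  cands[[which.max(scores)]]                  # which.max: first max wins
}

#' Assemble one (N, M, C) training tensor from a study
#'
#' Unpaired mode: a source batch is drawn from the reference modality
#' (a contiguous window of the eigenmap-sorted order under the default
#' strategy), and every other modality contributes its best-matching candidate
#' batch via [select_matching_minibatch()]; each batch's rows are ordered by
#' ascending eigenmap value before stacking. Paired mode: cells are sorted
#' lexicographically by barcode and one shared random index set is used for all
#' modalities, skipping the pre-match.
#'
#' @param study A `MultiomicStudy`; unpaired studies must have eigenmaps
#'   computed on every view (see [prepare_study()]).
#' @param N Mini-batch size (default 256).
#' @param n_candidates Candidates per target modality (default 50).
#' @param strategy Candidate sampling strategy.
#' @return A `MiniBatchTensor`: list with `data` (array `N x M x C`) and
#'   `source_indices` (per-modality integer vectors).
#' @export
assemble_minibatch_tensor <- function(study, N = 256L, n_candidates = 50L,
                                      strategy = c("window", "random")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(study, "MultiomicStudy"))
  M <- n_modalities(study)
  C <- study$C
  N <- as.integer(N)
  data <- array(0, dim = c(N, M, C))
  idx_list <- vector("list", M)
  if (study$paired) {
    n <- n_cells(study$modalities[[1]])
    if (n < N) stop("study has fewer than N cells")
    shared <- sort(sample.int(n, N))
    for (m in seq_len(M)) {
      v <- study$modalities[[m]]
      ord <- order(v$cell_ids)               # lexicographic barcode order
      idx <- ord[shared]
      data[, m, ] <- v$embedding[idx, , drop = FALSE]
      idx_list[[m]] <- idx
    }
  } else {
    ref_i <- study$reference_index
    ref <- study$modalities[[ref_i]]
    if (is.null(ref$eigenmap))
      stop("unpaired study needs eigenmaps; call prepare_study() first")
    src_idx <- draw_candidates(ref, N, 1L, strategy)[[1]]
    src_X <- ref$embedding[src_idx, , drop = FALSE]
    src_y <- ref$eigenmap[src_idx]
    data[, ref_i, ] <- src_X
    idx_list[[ref_i]] <- src_idx
    for (m in setdiff(seq_len(M), ref_i)) {
      tgt <- study$modalities[[m]]
      idx <- select_matching_minibatch(src_X, src_y, tgt,
                                       n_candidates = n_candidates, N = N,
                                       strategy = strategy)
      data[, m, ] <- tgt$embedding[idx, , drop = FALSE]
      idx_list[[m]] <- idx
    }
  }
  structure(list(data = data, source_indices = idx_list, N = N, M = M, C = C),
            class = "MiniBatchTensor")
}

#' Precompute eigenmap orderings on every modality of a study
#'
#' Computes each view's Laplacian eigenmap and then aligns the eigenmap
#' orientations across modalities. An eigenvector's sign is a gauge freedom:
#' the per-view canonical sign makes each modality deterministic but says
#' nothing about whether two modalities run in the same direction, and the
#' mini-batch scoring matches eigenmap value ranges across modalities, so a
#' flipped orientation would systematically couple opposite ends of the two
#' orderings. Since the modalities observe the same underlying cell
#' population, their eigenmap value distributions should agree; each
#' non-reference modality is therefore flipped when the quantile profile of
#' its negated eigenmap is closer (least squares over 101 quantiles, the
#' discrete 1-d Wasserstein criterion) to the reference profile than the
#' unflipped one. Symmetric distributions make the choice immaterial.
#'
#' @param study A `MultiomicStudy`.
#' @param regularize Passed to [eigenmap_order()].
#' @return The study with aligned eigenmaps and orderings cached on each view.
#' @export
prepare_study <- function(study, regularize = FALSE) {
  stopifnot(inherits(study, "MultiomicStudy"))
  study$modalities <- lapply(study$modalities, eigenmap_order,
                             regularize = regularize)
  probs <- seq(0, 1, length.out = 101L)
  ref_q <- quantile(study$modalities[[study$reference_index]]$eigenmap,
                    probs, names = FALSE)
  for (m in seq_along(study$modalities)) {
    if (m == study$reference_index) next
    v <- study$modalities[[m]]
    q_keep <- quantile(v$eigenmap, probs, names = FALSE)
    q_flip <- quantile(-v$eigenmap, probs, names = FALSE)
    if (sum((q_flip - ref_q)^2) < sum((q_keep - ref_q)^2)) {
      v$eigenmap <- -v$eigenmap
      v$eigenmap_order <- order(v$eigenmap, seq_along(v$eigenmap))
      study$modalities[[m]] <- v
    }
  }
  study
}
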