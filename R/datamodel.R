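#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t crossprod forceSymmetric
#' @importFrom stats rnorm runif rmultinom sd var quantile setNames p.adjust
#'   pnorm wilcox.test
#' @importFrom utils head tail modifyList
NULL

# ---------------------------------------------------------------------------
# ModalityView: a single molecular layer (RNA, ATAC, ...) observed on a set of
# cells: a low-dimensional embedding (e.g. PCA scores), a weighted kNN graph
# over the same cells, and optional features / labels.
# ---------------------------------------------------------------------------

#' Construct a ModalityView
#'
#' A ModalityView holds everything the integration needs to know about one
#' modality: the per-cell embedding used for training (cells x C, e.g. PCA
#' scores), a symmetric weighted k-nearest-neighbour graph over the same cells,
#' and optionally the raw feature matrix, cell-type labels and batch labels.
#' The first nontrivial Laplacian eigenvector of the graph (used to order cells
#' before mini-batch sampling) is computed lazily by [eigenmap_order()] and
#' cached on the view.
#'
#' @param name Modality name (e.g. `"RNA"`).
#' @param embedding Numeric matrix, cells x C. Row names, when present, are
#'   used as cell identifiers.
#' @param neighbor_graph Symmetric non-negative sparse adjacency (`dgCMatrix`
#'   or dense matrix) with zero diagonal, or `NULL` to build a kNN graph from
#'   the embedding with [knn_graph()].
#' @param cell_ids Character vector of unique barcodes; defaults to the
#'   embedding row names or `cell_1..cell_n`.
#' @param features Optional numeric matrix, cells x F.
#' @param feature_ids Optional character vector of length F.
#' @param cell_labels,batch_labels Optional per-cell factors.
#' @param knn Neighbourhood size used when the graph must be built (default 15).
#'
#' @return An object of class `ModalityView`.
#' @export
modality_view <- function(name, embedding, neighbor_graph = NULL,
                          cell_ids = NULL, features = NULL, feature_ids = NULL,
                          cell_labels = NULL, batch_labels = NULL, knn = 15L) {
  embedding <- as.matrix(embedding)
  storage.mode(embedding) <- "double"
  n <- nrow(embedding)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(embedding)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n)
    stop("length(cell_ids) must equal nrow(embedding)")
  if (is.null(neighbor_graph)) {
    neighbor_graph <- knn_graph(embedding, k = knn)
  } else {
    neighbor_graph <- as_symmetric_graph(neighbor_graph)
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (nrow(features) != n)
      stop("features must have one row per cell")
    if (is.null(feature_ids)) {
      feature_ids <- colnames(features)
      if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(ncol(features)))
    }
    if (length(feature_ids) != ncol(features))
      stop("length(feature_ids) must equal ncol(features)")
    feature_ids <- as.character(feature_ids)
  }
  if (!is.null(cell_labels)) {
    cell_labels <- as.factor(cell_labels)
    if (length(cell_labels) != n) stop("cell_labels must have one entry per cell")
  }
  if (!is.null(batch_labels)) {
    batch_labels <- as.factor(batch_labels)
    if (length(batch_labels) != n) stop("batch_labels must have one entry per cell")
  }
  view <- structure(list(
    name = as.character(name)[1],
    cell_ids = cell_ids,
    embedding = embedding,
    neighbor_graph = neighbor_graph,
    eigenmap = NULL,
    eigenmap_order = NULL,
    features = features,
    feature_ids = feature_ids,
    cell_labels = cell_labels,
    batch_labels = batch_labels
  ), class = "ModalityView")
  validate_modality_view(view)
  view
}

#' Validate a ModalityView's invariants
#'
#' Checks the structural invariants: matching dimensions between cell ids,
#' embedding and graph; graph symmetry (within 1e-8), non-negative weights and
#' zero diagonal; a finite eigenmap of the right length when present.
#'
#' @param view A `ModalityView`.
#' @return The view, invisibly; errors otherwise.
#' @export
validate_modality_view <- function(view) {
  stopifnot(inherits(view, "ModalityView"))
  n <- length(view$cell_ids)
  if (nrow(view$embedding) != n)
    stop("embedding row count must equal number of cell ids")
  if (!all(is.finite(view$embedding)))
    stop("embedding contains non-finite values")
  g <- view$neighbor_graph
  if (nrow(g) != n || ncol(g) != n)
    stop("neighbor_graph dimension must equal number of cells")
  if (any(Matrix::diag(g) != 0))
    stop("neighbor_graph must have a zero diagonal")
  asym <- max(abs(g - Matrix::t(g)))
  if (asym > 1e-8)
    stop("neighbor_graph must be symmetric (max asymmetry ", format(asym), ")")
  if (length(g@x) && min(g@x) < 0)
    stop("neighbor_graph weights must be non-negative")
  if (!is.null(view$eigenmap)) {
    if (length(view$eigenmap) != n || !all(is.finite(view$eigenmap)))
      stop("eigenmap must be a finite vector of length n_cells")
  }
  invisible(view)
}

#' @export
print.ModalityView <- function(x, ...) {
  cat(sprintf("ModalityView '%s': %d cells, %d embedding dims\n",
              x$name, length(x$cell_ids), ncol(x$embedding)))
  cat(sprintf("  graph: %d edges; eigenmap: %s; features: %s; labels: %s\n",
              length(x$neighbor_graph@x) / 2L,
              if (is.null(x$eigenmap)) "not computed" else "cached",
              if (is.null(x$features)) "none" else paste0(ncol(x$features), " features"),
              if (is.null(x$cell_labels)) "none" else paste0(nlevels(x$cell_labels), " levels")))
  invisible(x)
}

#' Number of cells in a ModalityView
#' @param view A `ModalityView`.
#' @return Integer cell count.
#' @export
n_cells <- function(view) length(view$cell_ids)

# Coerce an adjacency to sparse symmetric with zero diagonal; directed kNN
# edges are symmetrized by the maximum of the two directions.
as_symmetric_graph <- function(g) {
  g <- methods::as(methods::as(methods::as(g, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (max(abs(g - Matrix::t(g))) > 1e-8) {
    warning("neighbor graph is not symmetric; symmetrizing by maximum weight")
    g <- pmax_sparse(g, Matrix::t(g))
  }
  Matrix::diag(g) <- 0
  Matrix::drop0(g)
}

# Element-wise maximum of two non-negative sparse matrices.
pmax_sparse <- function(a, b) {
  d <- (a + b + abs(a - b)) / 2
  methods::as(d, "CsparseMatrix")
}

# ---------------------------------------------------------------------------
# MultiomicStudy: an ordered collection of modality views
# ---------------------------------------------------------------------------

#' Assemble a MultiomicStudy from modality views
#'
#' Harmonizes M >= 2 modality views into a study: every embedding is truncated
#' to a common width C, where C is at most the smallest matrix rank of any
#' modality's embedding (a rank-deficient embedding cannot support more
#' informative dimensions than its rank). In paired mode all modalities must
#' carry an identical barcode set; in unpaired mode barcodes are namespaced by
#' modality and may collide freely.
#'
#' @param modalities List of `ModalityView` objects (length >= 2).
#' @param paired Logical; `TRUE` when all modalities were measured on the same
#'   cells (shared barcodes).
#' @param reference_index Index of the reference modality used as the source of
#'   mini-batch pre-matching (conventionally RNA; default 1).
#' @param C Optional requested embedding width; silently capped at the minimum
#'   embedding rank across modalities.
#'
#' @return An object of class `MultiomicStudy` with elements `modalities`,
#'   `paired`, `reference_index` and `C`.
#' @export
multiomic_study <- function(modalities, paired = FALSE, reference_index = 1L,
                            C = NULL) {
  if (!is.list(modalities) || length(modalities) < 2L)
    stop("a MultiomicStudy requires at least M = 2 modalities")
  lapply(modalities, validate_modality_view)
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(modalities))
    stop("reference_index out of range")
  ranks <- vapply(modalities, function(v) qr(v$embedding)$rank, integer(1))
  widths <- vapply(modalities, function(v) ncol(v$embedding), integer(1))
  cmax <- min(ranks, widths)
  if (is.null(C)) C <- cmax
  C <- min(as.integer(C), cmax)
  if (C < 1L) stop("common embedding width C must be >= 1")
  modalities <- lapply(modalities, function(v) {
    if (ncol(v$embedding) > C) {
      v$embedding <- v$embedding[, seq_len(C), drop = FALSE]
    }
    v
  })
  if (paired) {
    ids <- lapply(modalities, `[[`, "cell_ids")
    if (any(vapply(ids, anyDuplicated, integer(1)) > 0L))
      stop("paired mode forbids duplicate barcodes within a modality")
    ref <- sort(ids[[1]])
    for (i in seq_along(ids)[-1]) {
      if (!identical(sort(ids[[i]]), ref))
        stop("paired mode requires an identical barcode set in every modality")
    }
  }
  structure(list(modalities = modalities, paired = paired,
                 reference_index = reference_index, C = C),
            class = "MultiomicStudy")
}

#' @export
print.MultiomicStudy <- function(x, ...) {
  cat(sprintf("MultiomicStudy: M=%d modalities, C=%d, %s, reference='%s'\n",
              length(x$modalities), x$C,
              if (x$paired) "paired" else "unpaired",
              x$modalities[[x$reference_index]]$name))
  for (v in x$modalities) print(v)
  invisible(x)
}

#' Number of modalities in a study
#' @param study A `MultiomicStudy`.
#' @return Integer M.
#' @export
n_modalities <- function(study) length(study$modalities)

# ---------------------------------------------------------------------------
# SyntheticMultiomicOutput: generated cells
# ---------------------------------------------------------------------------

#' Construct a SyntheticMultiomicOutput
#'
#' The container for generated cells: an `(n_syn, M, C)` embedding tensor whose
#' modality slices live in the same embedding spaces as the training data,
#' optional per-modality reconstructed feature matrices, a model-of-origin
#' label (used by semisupervised training), and provenance.
#'
#' @param embeddings Numeric array `(n_syn, M, C)`.
#' @param modality_names Character vector of length M.
#' @param reconstructed_features Optional named list of `n_syn x F_m` matrices.
#' @param model_label Factor of length `n_syn`; defaults to a single level
#'   `"model_1"`.
#' @param provenance Named list (config digest, seed, training steps, ...).
#'
#' @return An object of class `SyntheticMultiomicOutput`.
#' @export
synthetic_output <- function(embeddings, modality_names,
                             reconstructed_features = NULL,
                             model_label = NULL, provenance = list()) {
  stopifnot(is.array(embeddings), length(dim(embeddings)) == 3L)
  if (!all(is.finite(embeddings)))
    stop("synthetic embeddings must be finite")
  n <- dim(embeddings)[1]
  M <- dim(embeddings)[2]
  if (length(modality_names) != M)
    stop("modality_names must have one entry per modality slice")
  if (is.null(model_label)) model_label <- factor(rep("model_1", n))
  model_label <- as.factor(model_label)
  if (length(model_label) != n)
    stop("model_label must have one entry per synthetic cell")
  if (!is.null(reconstructed_features)) {
    stopifnot(is.list(reconstructed_features))
    for (fm in reconstructed_features)
      if (!is.null(fm) && nrow(fm) != n)
        stop("reconstructed feature matrices must have n_syn rows")
  }
  structure(list(embeddings = embeddings,
                 modality_names = as.character(modality_names),
                 reconstructed_features = reconstructed_features,
                 model_label = model_label,
                 provenance = provenance),
            class = "SyntheticMultiomicOutput")
}

#' Extract one modality's synthetic embedding slice
#'
#' @param out A `SyntheticMultiomicOutput`.
#' @param m Modality index or name.
#' @return An `n_syn x C` matrix in that modality's embedding space.
#' @export
modality_slice <- function(out, m) {
  stopifnot(inherits(out, "SyntheticMultiomicOutput"))
  if (is.character(m)) m <- match(m, out$modality_names)
  if (is.na(m) || m < 1 || m > dim(out$embeddings)[2])
    stop("unknown modality")
  sl <- out$embeddings[, m, , drop = FALSE]
  matrix(sl, nrow = dim(out$embeddings)[1], ncol = dim(out$embeddings)[3])
}

#' @export
print.SyntheticMultiomicOutput <- function(x, ...) {
  d <- dim(x$embeddings)
  cat(sprintf("SyntheticMultiomicOutput: %d cells x %d modalities x %d dims; %d model label(s)\n",
              d[1], d[2], d[3], nlevels(x$model_label)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# kNN helpers shared across modules (exact, Euclidean)
# ---------------------------------------------------------------------------

#' Symmetric weighted kNN graph from an embedding
#'
#' Builds an exact Euclidean k-nearest-neighbour graph and symmetrizes it by
#' the maximum of the two directed edges. Edge weights are Gaussian affinities
#' `exp(-d^2 / sigma_i^2)` with a per-cell bandwidth equal to the distance to
#' the k-th neighbour, so that weights are in (0, 1] and adapt to local
#' density.
#'
#' @param embedding Numeric matrix, cells x C.
#' @param k Number of neighbours (default 15).
#' @return A sparse symmetric `dgCMatrix` adjacency with zero diagonal.
#' @export
knn_graph <- function(embedding, k = 15L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  k <- min(as.integer(k), n - 1L)
  if (k < 1L) stop("need at least 2 cells to build a kNN graph")
  nn <- FNN::get.knn(embedding, k = k)
  sigma <- pmax(nn$nn.dist[, k], 1e-12)
  w <- exp(-(nn$nn.dist^2) / sigma^2)
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn$nn.index))
  x <- as.vector(t(w))
  g <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  g <- pmax_sparse(g, Matrix::t(g))
  Matrix::diag(g) <- 0
  Matrix::drop0(g)
}

# k nearest rows of `ref` for each row of `query` (exact). Returns list with
# index (nq x k) and dist (nq x k).
knn_query <- function(ref, query, k) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(ref)) stop("k must be between 1 and the number of reference points")
  nn <- FNN::get.knnx(data = as.matrix(ref), query = as.matrix(query), k = k)
  list(index = nn$nn.index, dist = nn$nn.dist)
}

# Majority vote over a neighbour index matrix (nq x k) into labels (factor).
# Ties broken by the lexicographically smallest label. Returns list(label,
# confidence = fraction of the k votes won).
knn_majority <- function(neighbor_index, labels) {
  labels <- as.factor(labels)
  lev <- sort(levels(labels))
  k <- ncol(neighbor_index)
  votes <- matrix(as.character(labels)[neighbor_index], nrow = nrow(neighbor_index))
  pick <- character(nrow(votes))
  conf <- numeric(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    tab <- table(factor(votes[i, ], levels = lev))
    best <- which(tab == max(tab))[1]       # levels sorted -> lexicographic tie-break
    pick[i] <- lev[best]
    conf[i] <- as.numeric(tab[best]) / k
  }
  list(label = factor(pick, levels = levels(labels)), confidence = conf)
}
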