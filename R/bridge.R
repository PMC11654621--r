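# Using synthetic multimodal cells as bridges.
#
# The GAN emits embeddings, not features; features are imputed by kNN
# regression from real cells of the same modality (k = 2 by default). Labels
# travel source modality -> synthetic cells -> target modality by two rounds
# of kNN majority voting, which is how a synthetic paired dataset links two
# real unimodal datasets that share no cells.

#' Fit a kNN feature regressor on a modality
#'
#' Stores the modality's embedding and features; a prediction for a query
#' point is the unweighted mean of the features of its k nearest training
#' cells (Euclidean distance in the embedding).
#'
#' @param view A `ModalityView` with features.
#' @param k Number of neighbours (default 2).
#' @return A `FeatureRegressor`.
#' @export
fit_feature_regressor <- function(view, k = 2L) {
  stopifnot(inherits(view, "ModalityView"))
  if (is.null(view$features))
    stop("modality '", view$name, "' carries no features to regress")
  k <- as.integer(k)
  if (k < 1L || k > n_cells(view))
    stop("k must be between 1 and the number of training cells (", n_cells(view), ")")
  structure(list(embedding = view$embedding, features = view$features,
                 feature_ids = view$feature_ids, k = k, modality = view$name),
            class = "FeatureRegressor")
}

#' Predict features for query embeddings
#' @param object A `FeatureRegressor`.
#' @param newdata Query matrix (`n x C`) in the regressor's embedding space.
#' @param ... Unused.
#' @return `n x F` matrix of imputed features.
#' @export
predict.FeatureRegressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$embedding))
    stop("query dimensionality (", ncol(newdata), ") does not match the ",
         "regressor's embedding (", ncol(object$embedding), ")")
  if (nrow(newdata) == 0L)
    return(matrix(0, 0L, ncol(object$features),
                  dimnames = list(NULL, object$feature_ids)))
  nn <- knn_query(object$embedding, newdata, object$k)
  out <- matrix(0, nrow(newdata), ncol(object$features))
  for (j in seq_len(object$k))
    out <- out + object$features[nn$index[, j], , drop = FALSE]
  out <- out / object$k
  colnames(out) <- object$feature_ids
  out
}

#' Reconstruct features for synthetic cells
#'
#' Applies a fitted [fit_feature_regressor()] to the matching modality slice
#' of a synthetic output and attaches the imputed features. Each imputed value
#' is a mean of k observed values, so predictions stay within the per-feature
#' range of the training data.
#'
#' @param reg A `FeatureRegressor`.
#' @param out A `SyntheticMultiomicOutput`.
#' @param modality_index Index (or name) of the modality slice to reconstruct.
#' @return The output with `reconstructed_features[[modality]]` filled in.
#' @export
reconstruct_features <- function(reg, out, modality_index) {
  stopifnot(inherits(reg, "FeatureRegressor"),
            inherits(out, "SyntheticMultiomicOutput"))
  slice <- modality_slice(out, modality_index)
  pred <- predict(reg, slice)
  if (is.null(out$reconstructed_features)) out$reconstructed_features <- list()
  nm <- if (is.character(modality_index)) modality_index
        else out$modality_names[modality_index]
  out$reconstructed_features[[nm]] <- pred
  out
}

#' Transfer labels across modalities through a synthetic bridge
#'
#' Stage 1: every synthetic cell takes the majority label of its k nearest
#' source cells, comparing the bridge's source-modality slice against the
#' source embedding. Stage 2: every target cell takes the majority label of
#' its k nearest synthetic cells in the target-modality slice. Ties break to
#' the lexicographically smallest label; per-stage agreement fractions are
#' recorded and multiplied into a combined confidence.
#'
#' @param source A `ModalityView` with `cell_labels`.
#' @param bridge A `SyntheticMultiomicOutput` holding both modality slices.
#' @param target A `ModalityView`.
#' @param source_index,target_index Modality indices (or names) of the source
#'   and target slices within the bridge (defaults 1 and 2).
#' @param k Neighbours per voting stage (default 15).
#' @return A `LabelTransferResult`: `labels` (factor over target cells),
#'   `confidence` (combined), `stage1_confidence` (per synthetic cell),
#'   `stage2_confidence` (per target cell), `synthetic_labels`, and a `path`
#'   description.
#' @export
transfer_labels <- function(source, bridge, target,
                            source_index = 1L, target_index = 2L, k = 15L) {
  stopifnot(inherits(source, "ModalityView"), inherits(target, "ModalityView"),
            inherits(bridge, "SyntheticMultiomicOutput"))
  if (is.null(source$cell_labels))
    stop("source modality carries no cell labels")
  n_syn <- dim(bridge$embeddings)[1]
  if (n_syn == 0L) stop("bridge contains no synthetic cells")
  k1 <- min(as.integer(k), n_cells(source))
  k2 <- min(as.integer(k), n_syn)
  syn_src <- modality_slice(bridge, source_index)
  nn1 <- knn_query(source$embedding, syn_src, k1)
  stage1 <- knn_majority(nn1$index, source$cell_labels)
  syn_tgt <- modality_slice(bridge, target_index)
  nn2 <- knn_query(syn_tgt, target$embedding, k2)
  stage2 <- knn_majority(nn2$index, stage1$label)
  mean_stage1 <- rowMeans(matrix(stage1$confidence[nn2$index], ncol = k2))
  structure(list(labels = stage2$label,
                 confidence = stage2$confidence * mean_stage1,
                 stage1_confidence = stage1$confidence,
                 stage2_confidence = stage2$confidence,
                 synthetic_labels = stage1$label,
                 k = c(stage1 = k1, stage2 = k2),
                 path = sprintf("%s -> synthetic -> %s", source$name, target$name)),
            class = "LabelTransferResult")
}

#' @export
print.LabelTransferResult <- function(x, ...) {
  cat(sprintf("LabelTransferResult (%s): %d cells, %d label levels, mean confidence %.3f\n",
              x$path, length(x$labels), nlevels(x$labels), mean(x$confidence)))
  invisible(x)
}

#' Filter synthetic cells by model-label consistency
#'
#' For semisupervised outputs (one generative model per batch), batch identity
#' is transferred from the real reference-modality cells to each synthetic
#' cell by kNN majority vote, and only synthetic cells whose transferred batch
#' equals their model of origin are retained. Inconsistent cells are the ones
#' a batch-specific model placed in a region of the embedding occupied by
#' another batch.
#'
#' @param out A `SyntheticMultiomicOutput` with a `model_label`.
#' @param study The training `MultiomicStudy` whose reference modality has
#'   `batch_labels`.
#' @param k Neighbours for the vote (default 15).
#' @return The filtered `SyntheticMultiomicOutput`, with attributes
#'   `"retained_fraction"` and `"transferred_batch"`.
#' @export
filter_by_model_label <- function(out, study, k = 15L) {
  stopifnot(inherits(out, "SyntheticMultiomicOutput"),
            inherits(study, "MultiomicStudy"))
  ref <- study$modalities[[study$reference_index]]
  if (is.null(ref$batch_labels))
    stop("the reference modality carries no batch_labels")
  if (is.null(out$model_label))
    stop("synthetic output carries no model_label")
  n_syn <- dim(out$embeddings)[1]
  if (n_syn == 0L) return(out)
  k <- min(as.integer(k), n_cells(ref))
  slice <- modality_slice(out, study$reference_index)
  nn <- knn_query(ref$embedding, slice, k)
  vote <- knn_majority(nn$index, ref$batch_labels)
  keep <- as.character(vote$label) == as.character(out$model_label)
  res <- synthetic_output(out$embeddings[keep, , , drop = FALSE],
                          out$modality_names,
                          reconstructed_features = if (!is.null(out$reconstructed_features))
                            lapply(out$reconstructed_features,
                                   function(f) f[keep, , drop = FALSE]),
                          model_label = droplevels_keep(out$model_label[keep]),
                          provenance = c(out$provenance,
                                         list(filter = "model_label_consistency", k = k)))
  attr(res, "retained_fraction") <- mean(keep)
  attr(res, "transferred_batch") <- vote$label
  res
}
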