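# Readers/writers for the containers the tool touches: AnnData h5ad files
# (the lingua franca of the Python single-cell stack; written here with the
# anndata on-disk spec so files round-trip through either ecosystem) and
# plain delimited-text directories. Embeddings round-trip losslessly (HDF5
# doubles; text uses 17 significant digits).

# ---- low-level h5ad helpers ------------------------------------------------

h5_sattr <- function(obj, name, val)
  rhdf5::h5writeAttribute(val, obj, name, variableLengthString = TRUE,
                          asScalar = TRUE)

h5_aattr <- function(obj, name, val) {
  if (length(val)) rhdf5::h5writeAttribute(val, obj, name,
                                           variableLengthString = TRUE)
  else rhdf5::h5writeAttribute(numeric(0), obj, name)
}

h5_enc <- function(h5, path, type, version = "0.2.0") {
  did <- rhdf5::H5Oopen(h5, path)
  h5_sattr(did, "encoding-type", type)
  h5_sattr(did, "encoding-version", version)
  rhdf5::H5Oclose(did)
}

h5_write_string <- function(x, h5, path) {
  rhdf5::h5write(x, h5, path, variableLengthString = TRUE)
  h5_enc(h5, path, "string-array")
}

# numeric matrix in R orientation (rows = cells): h5py sees (cells, cols)
h5_write_obs_matrix <- function(x, h5, path) {
  rhdf5::h5write(t(x), h5, path)
  h5_enc(h5, path, "array")
}

h5_write_dataframe <- function(h5, path, index, columns = list()) {
  g <- rhdf5::H5Gcreate(h5, path)
  h5_sattr(g, "encoding-type", "dataframe")
  h5_sattr(g, "encoding-version", "0.2.0")
  h5_sattr(g, "_index", "_index")
  h5_aattr(g, "column-order", names(columns))
  rhdf5::H5Gclose(g)
  h5_write_string(index, h5, paste0(path, "/_index"))
  for (nm in names(columns)) {
    col <- columns[[nm]]
    sub <- paste0(path, "/", nm)
    if (is.numeric(col)) {
      rhdf5::h5write(as.double(col), h5, sub)
      h5_enc(h5, sub, "array")
    } else {
      h5_write_string(as.character(col), h5, sub)
    }
  }
}

h5_write_dict_group <- function(h5, path) {
  g <- rhdf5::H5Gcreate(h5, path)
  h5_sattr(g, "encoding-type", "dict")
  h5_sattr(g, "encoding-version", "0.1.0")
  rhdf5::H5Gclose(g)
}

# symmetric sparse adjacency as CSR (CSC slots of a symmetric dgCMatrix double
# as CSR)
h5_write_csr <- function(g_mat, h5, path) {
  m <- methods::as(methods::as(g_mat, "generalMatrix"), "CsparseMatrix")
  g <- rhdf5::H5Gcreate(h5, path)
  h5_sattr(g, "encoding-type", "csr_matrix")
  h5_sattr(g, "encoding-version", "0.1.0")
  rhdf5::h5writeAttribute(as.integer(dim(m)), g, "shape")
  rhdf5::H5Gclose(g)
  rhdf5::h5write(as.double(m@x), h5, paste0(path, "/data"))
  rhdf5::h5write(as.integer(m@i), h5, paste0(path, "/indices"))
  rhdf5::h5write(as.integer(m@p), h5, paste0(path, "/indptr"))
}

h5_read_csr <- function(path, name, n) {
  data <- as.numeric(rhdf5::h5read(path, paste0(name, "/data")))
  indices <- as.integer(rhdf5::h5read(path, paste0(name, "/indices")))
  indptr <- as.integer(rhdf5::h5read(path, paste0(name, "/indptr")))
  # CSR of A equals CSC of t(A); transpose back
  Matrix::t(Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                 dims = c(n, n)))
}

# ---- ModalityView <-> h5ad -------------------------------------------------

#' Write a ModalityView to an AnnData h5ad file
#'
#' The embedding goes to `obsm/<embedding_key>`, the neighbour graph to
#' `obsp/<graph_key>` (CSR), features (when present) to `X` with `var` holding
#' the feature ids, labels and the cached eigenmap to `obs` columns. Files are
#' readable by Python `anndata`.
#'
#' @param view A `ModalityView`.
#' @param path Output file path (`.h5ad`).
#' @param embedding_key Name of the embedding slot (default `"X_pca"`).
#' @param graph_key Name of the graph slot (default `"distances"`).
#' @return `path`, invisibly.
#' @export
write_modality_h5ad <- function(view, path, embedding_key = "X_pca",
                                graph_key = "distances") {
  stopifnot(inherits(view, "ModalityView"))
  unlink(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  h5_sattr(h5, "encoding-type", "anndata")
  h5_sattr(h5, "encoding-version", "0.1.0")
  n <- n_cells(view)
  cols <- list()
  if (!is.null(view$cell_labels)) cols$cell_label <- as.character(view$cell_labels)
  if (!is.null(view$batch_labels)) cols$batch_label <- as.character(view$batch_labels)
  if (!is.null(view$eigenmap)) cols$eigenmap <- view$eigenmap
  h5_write_dataframe(h5, "obs", view$cell_ids, cols)
  if (!is.null(view$features)) {
    h5_write_obs_matrix(view$features, h5, "X")
    h5_write_dataframe(h5, "var", view$feature_ids)
  } else {
    h5_write_dataframe(h5, "var", character(0))
  }
  h5_write_dict_group(h5, "obsm")
  h5_write_obs_matrix(view$embedding, h5, paste0("obsm/", embedding_key))
  h5_write_dict_group(h5, "obsp")
  h5_write_csr(view$neighbor_graph, h5, paste0("obsp/", graph_key))
  h5_write_dict_group(h5, "uns")
  h5_write_string(view$name, h5, "uns/modality_name")
  invisible(path)
}

#' Load one modality from an h5ad file or a delimited-text directory
#'
#' For h5ad input the embedding is read from `obsm/<embedding_key>`; a missing
#' slot raises an error naming the slots that are available. The neighbour
#' graph is read from `obsp/<graph_key>` when present, otherwise built from
#' the embedding by k-nearest neighbours; a non-symmetric stored graph is
#' symmetrized by maximum weight with a warning. A directory input must
#' contain `embedding.csv` (first column `cell_id`) and may contain
#' `graph.csv` (columns `i`, `j`, `weight`; 1-based), `features.csv` and
#' `obs.csv` (columns `cell_id`, and optionally `cell_label`, `batch_label`).
#'
#' @param path File (`.h5ad`/`.h5`) or directory.
#' @param embedding_key Embedding slot name (default `"X_pca"`).
#' @param graph_key Graph slot name (default `"distances"`).
#' @param name Modality name override (default: stored name or basename).
#' @param C Optional truncation of the embedding to its first C columns.
#' @param knn Neighbourhood size when the graph must be built (default 15).
#' @return A validated `ModalityView`.
#' @export
load_modality <- function(path, embedding_key = "X_pca",
                          graph_key = "distances", name = NULL, C = NULL,
                          knn = 15L) {
  if (dir.exists(path)) {
    view <- load_modality_dir(path, name = name, knn = knn)
  } else if (grepl("\\.h5(ad)?$", path)) {
    view <- load_modality_h5ad(path, embedding_key, graph_key, name, knn)
  } else {
    stop("unsupported input: ", path,
         " (expected an .h5ad file or a directory of delimited matrices)")
  }
  if (!is.null(C) && ncol(view$embedding) > C)
    view$embedding <- view$embedding[, seq_len(C), drop = FALSE]
  validate_modality_view(view)
  view
}

load_modality_h5ad <- function(path, embedding_key, graph_key, name, knn) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  slot_names <- function(group) ls$name[ls$group == paste0("/", group)]
  obsm <- slot_names("obsm")
  if (!embedding_key %in% obsm)
    stop("embedding slot '", embedding_key, "' not found; available obsm ",
         "slots: ", if (length(obsm)) paste(obsm, collapse = ", ") else "(none)")
  emb <- t(rhdf5::h5read(path, paste0("obsm/", embedding_key)))
  cell_ids <- as.character(rhdf5::h5read(path, "obs/_index"))
  obs_cols <- slot_names("obs")
  read_col <- function(nm) {
    if (nm %in% obs_cols) as.vector(rhdf5::h5read(path, paste0("obs/", nm))) else NULL
  }
  graph <- NULL
  if (graph_key %in% slot_names("obsp"))
    graph <- h5_read_csr(path, paste0("obsp/", graph_key), nrow(emb))
  features <- NULL; feature_ids <- NULL
  if ("X" %in% ls$name[ls$group == "/"]) {
    features <- t(rhdf5::h5read(path, "X"))
    feature_ids <- as.character(rhdf5::h5read(path, "var/_index"))
  }
  if (is.null(name)) {
    name <- tryCatch(as.character(rhdf5::h5read(path, "uns/modality_name")),
                     error = function(e) NULL)
    if (is.null(name) || !length(name))
      name <- sub("\\.h5(ad)?$", "", basename(path))
  }
  modality_view(name = name, embedding = emb, neighbor_graph = graph,
                cell_ids = cell_ids, features = features,
                feature_ids = feature_ids,
                cell_labels = read_col("cell_label"),
                batch_labels = read_col("batch_label"), knn = knn)
}

# ---- delimited-text directory container ------------------------------------

# 17 significant digits round-trip IEEE doubles exactly
write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  data.table::fwrite(df, path, quote = FALSE)
}

#' Write a ModalityView as a directory of delimited-text matrices
#'
#' @param view A `ModalityView`.
#' @param path Output directory (created).
#' @return `path`, invisibly.
#' @export
write_modality_dir <- function(view, path) {
  stopifnot(inherits(view, "ModalityView"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  emb <- as.data.frame(view$embedding)
  names(emb) <- paste0("V", seq_len(ncol(emb)))
  write_num_csv(cbind(data.frame(cell_id = view$cell_ids), emb),
                file.path(path, "embedding.csv"))
  g <- methods::as(view$neighbor_graph, "TsparseMatrix")
  write_num_csv(data.frame(i = g@i + 1L, j = g@j + 1L, weight = g@x),
                file.path(path, "graph.csv"))
  if (!is.null(view$features)) {
    fe <- as.data.frame(view$features)
    names(fe) <- view$feature_ids
    write_num_csv(cbind(data.frame(cell_id = view$cell_ids), fe),
                  file.path(path, "features.csv"))
  }
  obs <- data.frame(cell_id = view$cell_ids)
  if (!is.null(view$cell_labels)) obs$cell_label <- as.character(view$cell_labels)
  if (!is.null(view$batch_labels)) obs$batch_label <- as.character(view$batch_labels)
  data.table::fwrite(obs, file.path(path, "obs.csv"), quote = FALSE)
  jsonlite::write_json(list(name = view$name), file.path(path, "meta.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

load_modality_dir <- function(path, name = NULL, knn = 15L) {
  embf <- file.path(path, "embedding.csv")
  if (!file.exists(embf))
    stop("directory input requires embedding.csv in ", path)
  emb_df <- data.table::fread(embf, data.table = FALSE)
  cell_ids <- as.character(emb_df[[1]])
  emb <- as.matrix(emb_df[, -1, drop = FALSE])
  graph <- NULL
  gf <- file.path(path, "graph.csv")
  if (file.exists(gf)) {
    g_df <- data.table::fread(gf, data.table = FALSE)
    graph <- Matrix::sparseMatrix(i = g_df$i, j = g_df$j, x = g_df$weight,
                                  dims = c(nrow(emb), nrow(emb)))
  }
  features <- NULL; feature_ids <- NULL
  ff <- file.path(path, "features.csv")
  if (file.exists(ff)) {
    f_df <- data.table::fread(ff, data.table = FALSE)
    features <- as.matrix(f_df[, -1, drop = FALSE])
    feature_ids <- colnames(features)
  }
  cell_labels <- NULL; batch_labels <- NULL
  of <- file.path(path, "obs.csv")
  if (file.exists(of)) {
    o_df <- data.table::fread(of, data.table = FALSE)
    if ("cell_label" %in% names(o_df)) cell_labels <- o_df$cell_label
    if ("batch_label" %in% names(o_df)) batch_labels <- o_df$batch_label
  }
  if (is.null(name)) {
    mf <- file.path(path, "meta.json")
    name <- if (file.exists(mf)) jsonlite::read_json(mf)$name else basename(path)
  }
  modality_view(name = name, embedding = emb, neighbor_graph = graph,
                cell_ids = cell_ids, features = features,
                feature_ids = feature_ids, cell_labels = cell_labels,
                batch_labels = batch_labels, knn = knn)
}

# ---- study / synthetic output I/O ------------------------------------------

#' Write every modality of a study as h5ad files
#'
#' One `<modality>.h5ad` per modality plus a `study.json` sidecar recording
#' pairing, reference modality and (when present) ground-truth label levels.
#'
#' @param study A `MultiomicStudy`.
#' @param dir Output directory.
#' @return Invisible character vector of written files.
#' @export
save_study <- function(study, dir) {
  stopifnot(inherits(study, "MultiomicStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(study$modalities, function(v) {
    f <- file.path(dir, paste0(v$name, ".h5ad"))
    write_modality_h5ad(v, f)
    f
  }, character(1))
  jsonlite::write_json(
    list(modalities = vapply(study$modalities, `[[`, "", "name"),
         paired = study$paired, reference_index = study$reference_index,
         C = study$C),
    file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Load a study written by [save_study()]
#'
#' @param dir Directory containing `study.json` and per-modality h5ad files.
#' @return A `MultiomicStudy`.
#' @export
load_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)
  views <- lapply(meta$modalities, function(nm)
    load_modality(file.path(dir, paste0(nm, ".h5ad"))))
  multiomic_study(views, paired = meta$paired,
                  reference_index = meta$reference_index, C = meta$C)
}

#' Save a SyntheticMultiomicOutput as one h5ad per modality
#'
#' Each modality gets `<name>.h5ad` with the synthetic embedding slice in
#' `obsm/X_gan`, reconstructed features (when present) as `X`, and
#' `model_label` as an `obs` column; provenance goes to `uns`. Embeddings
#' round-trip bit exactly.
#'
#' @param out A `SyntheticMultiomicOutput`.
#' @param dir Output directory.
#' @return Invisible character vector of written files.
#' @export
save_output <- function(out, dir) {
  stopifnot(inherits(out, "SyntheticMultiomicOutput"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(out$embeddings)[1]
  ids <- if (n) sprintf("syn_%06d", seq_len(n)) else character(0)
  files <- character(0)
  for (m in seq_along(out$modality_names)) {
    nm <- out$modality_names[m]
    f <- file.path(dir, paste0(nm, ".h5ad"))
    unlink(f)
    rhdf5::h5createFile(f)
    h5 <- rhdf5::H5Fopen(f)
    local_close <- local({ hh <- h5; function() try(rhdf5::H5Fclose(hh), silent = TRUE) })
    h5_sattr(h5, "encoding-type", "anndata")
    h5_sattr(h5, "encoding-version", "0.1.0")
    h5_write_dataframe(h5, "obs", ids,
                       list(model_label = as.character(out$model_label)))
    feats <- out$reconstructed_features[[nm]]
    if (!is.null(feats)) {
      h5_write_obs_matrix(feats, h5, "X")
      fid <- colnames(feats)
      if (is.null(fid)) fid <- paste0("feature_", seq_len(ncol(feats)))
      h5_write_dataframe(h5, "var", fid)
    } else {
      h5_write_dataframe(h5, "var", character(0))
    }
    h5_write_dict_group(h5, "obsm")
    slice <- modality_slice(out, m)
    h5_write_obs_matrix(slice, h5, "obsm/X_gan")
    h5_write_dict_group(h5, "uns")
    h5_write_string(nm, h5, "uns/modality_name")
    h5_write_string(as.character(jsonlite::toJSON(out$provenance,
                                                  auto_unbox = TRUE)),
                    h5, "uns/provenance")
    h5_write_string(if (is.null(feats)) "absent" else "present",
                    h5, "uns/features")
    local_close()
    files <- c(files, f)
  }
  jsonlite::write_json(list(modalities = out$modality_names),
                       file.path(dir, "output.json"), auto_unbox = TRUE)
  invisible(files)
}

#' Load a SyntheticMultiomicOutput written by [save_output()]
#'
#' @param dir Directory of per-modality h5ad files.
#' @param modality_names Optional explicit ordering; defaults to the sorted
#'   `.h5ad` file names found.
#' @return A `SyntheticMultiomicOutput`.
#' @export
load_output <- function(dir, modality_names = NULL) {
  if (is.null(modality_names)) {
    sidecar <- file.path(dir, "output.json")
    if (file.exists(sidecar)) {
      modality_names <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$modalities
    } else {
      files <- sort(list.files(dir, pattern = "\\.h5ad$", full.names = FALSE))
      modality_names <- sub("\\.h5ad$", "", files)
    }
  }
  if (!length(modality_names)) stop("no h5ad files in ", dir)
  slices <- list(); feats <- list(); model_label <- NULL; prov <- list()
  for (nm in modality_names) {
    f <- file.path(dir, paste0(nm, ".h5ad"))
    sl <- t(rhdf5::h5read(f, "obsm/X_gan"))
    slices[[nm]] <- sl
    ls <- rhdf5::h5ls(f)
    if ("X" %in% ls$name[ls$group == "/"]) {
      x <- t(rhdf5::h5read(f, "X"))
      colnames(x) <- as.character(rhdf5::h5read(f, "var/_index"))
      feats[[nm]] <- x
    }
    if (is.null(model_label))
      model_label <- as.character(rhdf5::h5read(f, "obs/model_label"))
    if (!length(prov))
      prov <- tryCatch(
        jsonlite::fromJSON(as.character(rhdf5::h5read(f, "uns/provenance"))),
        error = function(e) list())
  }
  n <- nrow(slices[[1]]); M <- length(slices); C <- ncol(slices[[1]])
  emb <- array(0, dim = c(n, M, C))
  for (m in seq_len(M)) emb[, m, ] <- slices[[m]]
  synthetic_output(emb, modality_names,
                   reconstructed_features = if (length(feats)) feats,
                   model_label = if (n) factor(model_label) else factor(character(0)),
                   provenance = prov)
}

#' Save trained model parameters as HDF5
#'
#' @param model A `TrainedModel`.
#' @param path Output `.h5` file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "TrainedModel"))
  unlink(path)
  rhdf5::h5createFile(path)
  for (grp in c("generator", "critic")) {
    obj <- model[[grp]]
    rhdf5::h5createGroup(path, grp)
    for (nm in names(obj$params))
      rhdf5::h5write(obj$params[[nm]], path, paste0(grp, "/", nm))
  }
  rhdf5::h5createGroup(path, "generator_run")
  for (nm in names(model$generator$run))
    rhdf5::h5write(model$generator$run[[nm]], path, paste0("generator_run/", nm))
  rhdf5::h5write(model$loss_history$critic, path, "loss_critic")
  rhdf5::h5write(model$loss_history$generator, path, "loss_generator")
  rhdf5::h5write(model$modality_names, path, "modality_names")
  rhdf5::h5write(c(model$generator$M, model$generator$C,
                   model$generator$latent_dim, model$generator$filters[1],
                   model$generator$filters[2], model$critic$filters,
                   model$n_reference), path, "dims")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path `.h5` checkpoint.
#' @return A `TrainedModel` (sufficient for [generate_cells()]).
#' @export
load_model <- function(path) {
  dims <- as.integer(rhdf5::h5read(path, "dims"))
  M <- dims[1]; C <- dims[2]; ld <- dims[3]
  gen <- build_generator(M, C, ld, dims[4:5])
  critic <- build_critic(M, C, dims[6:7])
  for (nm in names(gen$params)) {
    v <- rhdf5::h5read(path, paste0("generator/", nm))
    gen$params[[nm]] <- if (is.null(dim(gen$params[[nm]]))) as.numeric(v) else as.matrix(v)
  }
  for (nm in names(gen$run))
    gen$run[[nm]] <- as.numeric(rhdf5::h5read(path, paste0("generator_run/", nm)))
  for (nm in names(critic$params)) {
    v <- rhdf5::h5read(path, paste0("critic/", nm))
    critic$params[[nm]] <- if (is.null(dim(critic$params[[nm]]))) as.numeric(v) else as.matrix(v)
  }
  structure(list(generator = gen, critic = critic,
                 loss_history = list(
                   critic = as.numeric(rhdf5::h5read(path, "loss_critic")),
                   generator = as.numeric(rhdf5::h5read(path, "loss_generator"))),
                 config = NULL, seed_used = NA_integer_,
                 modality_names = as.character(rhdf5::h5read(path, "modality_names")),
                 n_reference = dims[8],
                 study_fingerprint = list(M = M, C = C)),
            class = "TrainedModel")
}
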