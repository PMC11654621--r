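# Quantitative evaluation suite: clustering agreement (AMI, homogeneity /
# completeness / V-measure), neighbourhood mixing (LISI), and a cell-type
# accuracy built from a preranked-GSEA confusion matrix of normalized
# enrichment scores.

# ---- entropy helpers -------------------------------------------------------

label_counts <- function(x) as.numeric(table(x))

entropy_counts <- function(cnt) {
  n <- sum(cnt)
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

#' Adjusted mutual information between two labelings
#'
#' Chance-corrected agreement: `(MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`,
#' with the expected mutual information computed exactly under the permutation
#' (hypergeometric) model and arithmetic-mean normalization. Returns 1 for
#' identical partitions and approximately 0 for independent ones. By
#' convention two trivial single-cluster labelings give 1 and a single trivial
#' one gives 0.
#'
#' @param a,b Label vectors of equal length (any type coercible to factor).
#' @return AMI value (<= 1).
#' @export
adjusted_mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  a <- as.factor(a); b <- as.factor(b)
  n <- length(a)
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  Ha <- entropy_counts(ai); Hb <- entropy_counts(bj)
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(nij * n / (ai[i] * bj[j]))
  }
  emi <- expected_mutual_information(ai, bj, n)
  denom <- (Ha + Hb) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  as.numeric((mi - emi) / denom)
}

# Exact expected MI under random permutation of one labeling (hypergeometric
# sum over all feasible cell counts), in log space for stability.
expected_mutual_information <- function(ai, bj, n) {
  lg <- lgamma
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - n)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lg(ai[i] + 1) - lg(nij + 1) - lg(ai[i] - nij + 1) +
          lg(n - ai[i] + 1) - lg(bj[j] - nij + 1) - lg(n - ai[i] - bj[j] + nij + 1) -
          (lg(n + 1) - lg(bj[j] + 1) - lg(n - bj[j] + 1))
        emi <- emi + exp(lp) * (nij / n) * log(n * nij / (ai[i] * bj[j]))
      }
    }
  }
  emi
}

#' Homogeneity, completeness and V-measure
#'
#' Entropy-based scores: homogeneity `1 - H(truth | pred) / H(truth)` (every
#' cluster contains a single class), completeness `1 - H(pred | truth) /
#' H(pred)` (every class sits in one cluster), and their harmonic mean
#' (V-measure). A zero-entropy denominator scores 1 by convention.
#'
#' @param truth,pred Label vectors of equal length.
#' @return Named numeric vector `c(homogeneity, completeness, v_measure)`.
#' @export
clustering_scores <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("labelings must have equal length")
  truth <- as.factor(truth); pred <- as.factor(pred)
  n <- length(truth)
  tab <- table(truth, pred)
  Ht <- entropy_counts(rowSums(tab))
  Hp <- entropy_counts(colSums(tab))
  # conditional entropies
  Ht_given_p <- 0; Hp_given_t <- 0
  for (j in seq_len(ncol(tab))) {
    cj <- tab[, j]; nj <- sum(cj)
    if (nj > 0) Ht_given_p <- Ht_given_p + (nj / n) * entropy_counts(cj)
  }
  for (i in seq_len(nrow(tab))) {
    ci <- tab[i, ]; ni <- sum(ci)
    if (ni > 0) Hp_given_t <- Hp_given_t + (ni / n) * entropy_counts(ci)
  }
  h <- if (Ht == 0) 1 else 1 - Ht_given_p / Ht
  c_ <- if (Hp == 0) 1 else 1 - Hp_given_t / Hp
  v <- if (h + c_ == 0) 0 else 2 * h * c_ / (h + c_)
  c(homogeneity = h, completeness = c_, v_measure = v)
}

#' Local inverse Simpson index (LISI)
#'
#' For every cell, its `3 * perplexity` nearest neighbours receive Gaussian
#' kernel weights whose bandwidth is fitted per cell by binary search so that
#' the weight distribution has the target perplexity (tolerance 1e-5, at most
#' 50 bisection steps); the label probabilities `p_b` are the normalized
#' per-label weight sums and the cell's LISI is `1 / sum_b p_b^2` — the
#' effective number of labels in its neighbourhood, from 1 (perfect
#' separation) to the number of distinct labels (perfect mixing).
#'
#' @param embedding Joint `n x C` matrix (e.g. real plus synthetic cells of
#'   one modality).
#' @param labels Dataset labels, length n.
#' @param perplexity Target perplexity (default 30).
#' @return List with `per_cell` (numeric length n) and `mean`.
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  labels <- as.factor(labels)
  n <- nrow(embedding)
  if (length(labels) != n) stop("labels must have one entry per cell")
  if (nlevels(droplevels(labels)) < 2L)
    return(list(per_cell = rep(1, n), mean = 1))
  k <- 3L * as.integer(perplexity)
  if (k > n - 1L) {
    warning("fewer cells than 3 * perplexity + 1; using all ", n - 1L,
            " available neighbours")
    k <- n - 1L
  }
  nn <- knn_query(embedding, embedding, k + 1L)
  # drop self (first neighbour at distance 0; robust to exact duplicates)
  idx <- nn$index[, -1L, drop = FALSE]
  d2 <- nn$dist[, -1L, drop = FALSE]^2
  lab_int <- as.integer(labels)
  L <- nlevels(labels)
  per_cell <- numeric(n)
  log_target <- log(perplexity)
  for (i in seq_len(n)) {
    w <- perplexity_weights(d2[i, ], log_target)
    pb <- vapply(seq_len(L), function(b) sum(w[lab_int[idx[i, ]] == b]), numeric(1))
    per_cell[i] <- 1 / sum(pb^2)
  }
  list(per_cell = per_cell, mean = mean(per_cell))
}

# Gaussian kernel weights over squared distances with bandwidth fitted by
# bisection on the precision beta to match the target entropy log(perplexity).
perplexity_weights <- function(d2, log_target, tol = 1e-5, max_iter = 50L) {
  beta <- 1
  beta_min <- -Inf; beta_max <- Inf
  d2 <- d2 - min(d2)                       # stabilize exponentials
  for (it in seq_len(max_iter)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    H <- log(sw) + beta * sum(d2 * w) / sw
    diff <- H - log_target
    if (abs(diff) < tol) break
    if (diff > 0) {                        # entropy too high -> sharpen
      beta_min <- beta
      beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
    } else {
      beta_max <- beta
      beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
    }
  }
  w <- exp(-d2 * beta)
  w / sum(w)
}

# ---- marker ranking --------------------------------------------------------

#' Rank features per group by Wilcoxon rank-sum versus the rest
#'
#' For every group with at least 2 cells, each feature is tested in-group
#' versus all remaining cells with a two-sided Wilcoxon rank-sum test
#' (normal approximation with tie correction and continuity correction);
#' p-values are Benjamini-Hochberg adjusted across features within the group.
#' The effect size is the log2 fold change of the group mean over the rest
#' mean with a pseudocount of 1e-9.
#'
#' @param view A `ModalityView` with features, or a numeric `cells x F`
#'   matrix.
#' @param labels Group labels (defaults to the view's `cell_labels`).
#' @return A data.frame with columns `group`, `feature`, `statistic` (the
#'   rank-sum U for the group), `lfc`, `p`, `p_adj`, ordered by group then
#'   decreasing `lfc`.
#' @export
rank_features <- function(view, labels = NULL) {
  if (inherits(view, "ModalityView")) {
    if (is.null(view$features)) stop("modality has no features")
    X <- view$features
    if (is.null(labels)) labels <- view$cell_labels
    fid <- view$feature_ids
  } else {
    X <- as.matrix(view)
    fid <- colnames(X)
    if (is.null(fid)) fid <- paste0("feature_", seq_len(ncol(X)))
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.factor(labels)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  ranks <- apply(X, 2, rank)               # ties -> average ranks
  # tie correction term per feature: sum(t^3 - t) over tied groups
  tie_term <- apply(X, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  })
  res <- list()
  for (g in levels(labels)) {
    in_g <- labels == g
    n1 <- sum(in_g); n2 <- n - n1
    if (n1 < 2L) {
      warning("group '", g, "' has fewer than 2 cells; skipped")
      next
    }
    r1 <- colSums(ranks[in_g, , drop = FALSE])
    U <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    sigma <- sqrt(pmax(sigma2, 0))
    z <- ifelse(sigma > 0, (U - mu - sign(U - mu) * 0.5) / sigma, 0)
    p <- ifelse(sigma > 0, 2 * pnorm(-abs(z)), 1)
    p <- pmin(p, 1)
    m1 <- colMeans(X[in_g, , drop = FALSE])
    m2 <- colMeans(X[!in_g, , drop = FALSE])
    # means clamped at zero: fold changes assume expression-like non-negative
    # intensities, but noisy features may dip below zero
    lfc <- log2((pmax(m1, 0) + 1e-9) / (pmax(m2, 0) + 1e-9))
    lfc[m1 == m2] <- 0
    res[[g]] <- data.frame(group = g, feature = fid, statistic = U,
                           lfc = lfc, p = p, p_adj = p.adjust(p, "BH"),
                           row.names = NULL)
  }
  if (!length(res)) stop("no group had at least 2 cells")
  out <- do.call(rbind, res)
  out <- out[order(out$group, -out$lfc), ]
  rownames(out) <- NULL
  out
}

#' Build cell-type marker sets from a ranking table
#'
#' Per group, keeps features with adjusted p below `adjusted_p_max`
#' (default 5e-3), sorts by decreasing log fold change and retains the top
#' `top_k` (100 is the convention for expression-like modalities, 500 for
#' region-like ones). Groups with no surviving feature are recorded as empty
#' and excluded downstream with a warning.
#'
#' @param test_table Output of [rank_features()] on the held-out (test) split.
#' @param adjusted_p_max Significance cutoff on the adjusted p-value.
#' @param top_k Maximum features per set.
#' @return A `MarkerSetCollection`: named list of character vectors, with
#'   attributes recording the thresholds.
#' @export
build_marker_sets <- function(test_table, adjusted_p_max = 5e-3, top_k = 100L) {
  stopifnot(all(c("group", "feature", "lfc", "p_adj") %in% names(test_table)))
  groups <- unique(test_table$group)
  sets <- lapply(groups, function(g) {
    sub <- test_table[test_table$group == g & test_table$p_adj < adjusted_p_max, ]
    sub <- sub[order(-sub$lfc), ]
    head(as.character(sub$feature), top_k)
  })
  names(sets) <- groups
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    warning("no significant markers for: ", paste(groups[empty], collapse = ", "))
  structure(sets, class = "MarkerSetCollection",
            adjusted_p_max = adjusted_p_max, top_k = as.integer(top_k))
}

# ---- preranked GSEA --------------------------------------------------------

#' Preranked gene-set enrichment
#'
#' Classic weighted Kolmogorov-Smirnov running sum with weight
#' `|metric|^1`: walking down the ranking (decreasing metric), hits advance
#' the sum by their normalized absolute metric, misses retreat by
#' `1 / (n - n_set)`; the enrichment score (ES) is the extremum of the running
#' sum. The null distribution comes from `n_perm` random same-size feature
#' sets; NES is `ES / mean(|null ES| of the matching sign)` and the p-value is
#' the same-sign tail fraction.
#'
#' @param ranking Named numeric vector (feature -> ranking metric, e.g. log
#'   fold change). Order need not be sorted.
#' @param gene_set Character vector of features.
#' @param n_perm Number of permutations for the null (default 1000).
#' @return List with `ES`, `NES`, `p`, and `n_hits` (set size after
#'   intersection). An empty intersection yields `ES = NA` and `NES = NA`
#'   (downstream imputes 0).
#' @export
preranked_gsea <- function(ranking, gene_set, n_perm = 1000L) {
  stopifnot(!is.null(names(ranking)))
  ranking <- ranking[is.finite(ranking)]
  ord <- order(ranking, decreasing = TRUE)
  metric <- as.numeric(ranking)[ord]
  feats <- names(ranking)[ord]
  hits <- feats %in% gene_set
  nh <- sum(hits)
  if (nh == 0L || nh == length(feats))
    return(list(ES = NA_real_, NES = NA_real_, p = NA_real_, n_hits = nh))
  es <- gsea_es(metric, hits)
  null_es <- vapply(seq_len(n_perm), function(i) {
    h <- logical(length(feats))
    h[sample.int(length(feats), nh)] <- TRUE
    gsea_es(metric, h)
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- if (length(same)) mean(abs(same) >= abs(es)) else NA_real_
  list(ES = es, NES = nes, p = p, n_hits = nh)
}

# running-sum enrichment score; metric sorted decreasing, hits logical
gsea_es <- function(metric, hits) {
  w <- abs(metric)
  nr <- sum(w[hits])
  n_miss <- sum(!hits)
  step <- numeric(length(metric))
  if (nr > 0) step[hits] <- w[hits] / nr else step[hits] <- 1 / sum(hits)
  step[!hits] <- -1 / n_miss
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' NES confusion matrix of marker sets against cell-type rankings
#'
#' Entry `(s, t)` is the normalized enrichment score of cell type `s`'s marker
#' set against cell type `t`'s feature ranking (log fold changes from the
#' training split). Cell types with empty marker sets are dropped with a
#' warning; NES values that could not be computed are imputed as 0.
#'
#' @param train_table [rank_features()] output on the training split.
#' @param marker_sets A `MarkerSetCollection` from the test split.
#' @param n_perm Permutations per GSEA call.
#' @return A `NESConfusionMatrix`: square numeric matrix, rows = marker sets,
#'   columns = evaluated cell types.
#' @export
nes_confusion_matrix <- function(train_table, marker_sets, n_perm = 1000L) {
  keep <- vapply(marker_sets, length, integer(1)) > 0L
  if (!all(keep))
    warning("excluding cell types with empty marker sets: ",
            paste(names(marker_sets)[!keep], collapse = ", "))
  types <- intersect(names(marker_sets)[keep], unique(train_table$group))
  m <- matrix(NA_real_, length(types), length(types),
              dimnames = list(set = types, ranking = types))
  for (t in types) {
    sub <- train_table[train_table$group == t, ]
    ranking <- setNames(sub$lfc, sub$feature)
    for (s in types) {
      res <- preranked_gsea(ranking, marker_sets[[s]], n_perm = n_perm)
      m[s, t] <- res$NES
    }
  }
  m[!is.finite(m)] <- 0
  structure(m, class = c("NESConfusionMatrix", "matrix"))
}

#' Weighted and unweighted accuracy from a NES confusion matrix
#'
#' Each column is scaled by its absolute maximum (so entries lie in
#' `[-1, 1]`; all-zero columns stay zero). Positive diagonal mass counts as
#' true positives, negative diagonal mass as false negatives, positive
#' off-diagonal mass as false positives and negative off-diagonal mass as
#' true negatives; weighted accuracy is `(TP + TN) / (TP + TN + FP + FN)`.
#' The unweighted variant replaces each scaled entry by its sign before the
#' same sums.
#'
#' @param m A square `NESConfusionMatrix` (or plain matrix).
#' @return Named vector `c(weighted, unweighted)`.
#' @export
accuracy_from_confusion <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) == 0L)
    stop("need a non-empty square NES matrix")
  cmax <- apply(abs(m), 2, max)
  scaled <- sweep(m, 2, ifelse(cmax > 0, cmax, 1), `/`)
  acc_of <- function(x) {
    d <- diag(x)
    off <- x; diag(off) <- 0
    tp <- sum(pmax(d, 0)); fn <- sum(abs(pmin(d, 0)))
    fp <- sum(pmax(off, 0)); tn <- sum(abs(pmin(off, 0)))
    tot <- tp + tn + fp + fn
    if (tot == 0) 0 else (tp + tn) / tot
  }
  c(weighted = acc_of(scaled), unweighted = acc_of(sign(scaled)))
}

# ---- end-to-end GSEA accuracy ----------------------------------------------

#' Stratified train/test split of cells
#'
#' Uniform random partition stratified by label, so that small groups keep
#' representatives on both sides.
#'
#' @param labels Cell labels.
#' @param p_train Training fraction (default 0.7).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, p_train = 0.7) {
  labels <- as.factor(labels)
  train <- integer(0)
  for (g in levels(labels)) {
    idx <- which(labels == g)
    n_tr <- max(1L, round(length(idx) * p_train))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Cell-type accuracy through the GSEA confusion pipeline
#'
#' Convenience wrapper: splits cells 70:30 stratified by label, derives
#' marker sets from the test split ([rank_features()] + [build_marker_sets()]),
#' ranks features on the training split, assembles the NES confusion matrix
#' and reports the accuracies. Pass `split = FALSE` to use all cells for both
#' sides (the reference construction used to judge an upstream method's
#' ceiling).
#'
#' @param features `cells x F` matrix (or a `ModalityView` with features).
#' @param labels Cell-type labels.
#' @param top_k Marker-set size cap (100 expression-like / 500 region-like).
#' @param adjusted_p_max Marker significance cutoff.
#' @param n_perm GSEA permutations.
#' @param split Perform the 70:30 split (default `TRUE`).
#' @return List with `accuracy` (named vector), `confusion`
#'   (`NESConfusionMatrix`) and `marker_sets`.
#' @export
gsea_celltype_accuracy <- function(features, labels, top_k = 100L,
                                   adjusted_p_max = 5e-3, n_perm = 1000L,
                                   split = TRUE) {
  if (inherits(features, "ModalityView")) {
    if (is.null(labels)) labels <- features$cell_labels
    features <- features$features
  }
  labels <- as.factor(labels)
  if (split) {
    parts <- split_train_test(labels, 0.7)
    test_tab <- rank_features(features[parts$test, , drop = FALSE],
                              labels[parts$test])
    train_tab <- rank_features(features[parts$train, , drop = FALSE],
                               labels[parts$train])
  } else {
    test_tab <- train_tab <- rank_features(features, labels)
  }
  sets <- build_marker_sets(test_tab, adjusted_p_max = adjusted_p_max,
                            top_k = top_k)
  conf <- nes_confusion_matrix(train_tab, sets, n_perm = n_perm)
  list(accuracy = accuracy_from_confusion(conf), confusion = conf,
       marker_sets = sets)
}
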