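# --- independent oracles ----------------------------------------------------

# exact AMI by enumerating every permutation of one labeling (n <= 8)
ami_oracle <- function(a, b) {
  a <- as.factor(a); b <- as.factor(b)
  n <- length(a)
  mi_of <- function(bb) {
    tab <- table(a, bb)
    ai <- rowSums(tab); bj <- colSums(tab)
    mi <- 0
    for (i in seq_along(ai)) for (j in seq_along(bj))
      if (tab[i, j] > 0)
        mi <- mi + (tab[i, j] / n) * log(tab[i, j] * n / (ai[i] * bj[j]))
    mi
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  all_p <- perms(seq_len(n))
  emi <- mean(vapply(all_p, function(p) mi_of(b[p]), numeric(1)))
  ent <- function(x) { p <- table(x) / n; -sum(p[p > 0] * log(p[p > 0])) }
  as.numeric((mi_of(b) - emi) / ((ent(a) + ent(b)) / 2 - emi))
}

# dense LISI recomputation, written independently of the package
# implementation (full distance matrix, its own bisection loop) but with the
# same bandwidth-search settings (start 1, tolerance 1e-5, <= 50 steps) so the
# two can be compared at tight tolerance
lisi_oracle <- function(emb, labels, perplexity) {
  emb <- as.matrix(emb)
  labels <- as.factor(labels)
  n <- nrow(emb)
  D2 <- as.matrix(dist(emb))^2
  k <- min(3 * perplexity, n - 1)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    others <- others[order(D2[i, others])][seq_len(k)]
    d2 <- D2[i, others] - min(D2[i, others])
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      u <- exp(-beta * d2)
      H <- log(sum(u)) + beta * sum(d2 * u) / sum(u)
      if (abs(H - log(perplexity)) < 1e-5) break
      if (H > log(perplexity)) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-beta * d2); w <- w / sum(w)
    p <- tapply(w, labels[others], sum, default = 0)
    vals[i] <- 1 / sum(p^2)
  }
  list(per_cell = vals, mean = mean(vals))
}

# --- AMI ---------------------------------------------------------------------

test_that("AMI honours its boundary conventions", {
  expect_equal(adjusted_mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_mutual_information(c("x", "y", "z"), c("a", "b", "c")), 1)
  expect_equal(adjusted_mutual_information(rep(1, 6), c(1, 2, 1, 2, 1, 2)), 0)
  expect_error(adjusted_mutual_information(1:3, 1:4), "equal length")
})

test_that("AMI equals the exact permutation-enumeration oracle", {
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(adjusted_mutual_information(a, b), ami_oracle(a, b),
               tolerance = 1e-10)
  withr::with_seed(61, {
    for (trial in 1:5) {
      a <- sample(1:3, 8, replace = TRUE)
      b <- sample(1:2, 8, replace = TRUE)
      if (length(unique(a)) < 2 || length(unique(b)) < 2) next
      expect_equal(adjusted_mutual_information(a, b), ami_oracle(a, b),
                   tolerance = 1e-8)
    }
  })
})

test_that("independent large labelings score near zero", {
  withr::with_seed(62, {
    a <- sample(1:3, 3000, replace = TRUE)
    b <- sample(1:3, 3000, replace = TRUE)
  })
  expect_lt(abs(adjusted_mutual_information(a, b)), 0.05)
})

# --- V-measure ---------------------------------------------------------------

test_that("homogeneity/completeness/V follow the entropy definitions", {
  ident <- clustering_scores(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(unname(ident), c(1, 1, 1))
  singl <- clustering_scores(c(1, 1, 2, 2), 1:4)
  expect_equal(unname(singl["homogeneity"]), 1)
  expect_lt(singl["completeness"], 1)
  # 4-point example against a direct hand computation:
  # truth (1,1,2,2), pred (1,1,1,2): H(T)=log 2, H(T|P) = (3/4)*H(1/3,2/3)
  truth <- c(1, 1, 2, 2); pred <- c(1, 1, 1, 2)
  Ht <- log(2)
  Htp <- (3 / 4) * (-(1 / 3) * log(1 / 3) - (2 / 3) * log(2 / 3))
  Hp <- -(3 / 4) * log(3 / 4) - (1 / 4) * log(1 / 4)
  Hpt <- (1 / 2) * (-(1 / 2) * log(1 / 2) - (1 / 2) * log(1 / 2))
  h <- 1 - Htp / Ht; cc <- 1 - Hpt / Hp; v <- 2 * h * cc / (h + cc)
  got <- clustering_scores(truth, pred)
  expect_equal(unname(got), c(h, cc, v), tolerance = 1e-12)
})

# --- LISI --------------------------------------------------------------------

test_that("LISI is exactly 1 for one label and for separated clouds", {
  withr::with_seed(63, {
    emb <- matrix(rnorm(100 * 2), 100, 2)
  })
  expect_equal(lisi(emb, rep("only", 100))$mean, 1)
  withr::with_seed(64, {
    a <- matrix(rnorm(200 * 2), 200, 2)
    b <- matrix(rnorm(200 * 2), 200, 2); b[, 1] <- b[, 1] + 1000
  })
  res <- lisi(rbind(a, b), rep(c("A", "B"), each = 200), perplexity = 30)
  expect_equal(res$mean, 1, tolerance = 1e-6)
  expect_true(all(res$per_cell >= 1))
})

test_that("perfectly interleaved labels on a lattice approach LISI 2", {
  emb <- matrix(seq_len(300), ncol = 1)
  labels <- rep(c("A", "B"), 150)
  res <- lisi(emb, labels, perplexity = 30)
  expect_lt(abs(res$mean - 2), 0.05)
  expect_true(all(res$per_cell <= 2 + 1e-9))
})

test_that("LISI matches a dense brute-force recomputation on small instances", {
  withr::with_seed(65, {
    emb <- rbind(matrix(rnorm(10 * 2), 10, 2),
                 matrix(rnorm(10 * 2, mean = 2), 10, 2))
    labels <- rep(c("A", "B"), each = 10)
  })
  expect_warning(got <- lisi(emb, labels, perplexity = 10), "available")
  want <- lisi_oracle(emb, labels, perplexity = 10)
  expect_equal(got$per_cell, want$per_cell, tolerance = 1e-6)
})

test_that("cross-label mixing never decreases mean LISI on the lattice", {
  # blocks -> alternating: progressively more mixed arrangements
  n <- 120
  emb <- matrix(seq_len(n), ncol = 1)
  blocks <- rep(c("A", "B"), each = n / 2)
  pairs <- rep(rep(c("A", "B"), each = 2), n / 4)
  alternating <- rep(c("A", "B"), n / 2)
  v <- vapply(list(blocks, pairs, alternating),
              function(l) lisi(emb, l, perplexity = 8)$mean, numeric(1))
  expect_gt(v[2], v[1])
  expect_gt(v[3], v[1])
})

# --- marker ranking ----------------------------------------------------------

test_that("rank_features agrees with a brute-force U and wilcox.test on a toy", {
  withr::with_seed(66, {
    x <- c(rnorm(5), rnorm(5, mean = 2))
    X <- cbind(f1 = x, f2 = rep(1, 10), f3 = rnorm(10))
    labels <- factor(rep(c("g1", "g2"), each = 5))
  })
  tab <- rank_features(X, labels)
  # brute-force U for group g1, feature f1
  in_g <- 1:5
  U_brute <- sum(outer(x[in_g], x[-in_g], ">")) +
    0.5 * sum(outer(x[in_g], x[-in_g], "=="))
  got <- tab[tab$group == "g1" & tab$feature == "f1", ]
  expect_equal(got$statistic, U_brute)
  # p agrees with stats::wilcox.test (normal approximation, corrected)
  wt <- wilcox.test(x[in_g], x[-in_g], exact = FALSE, correct = TRUE)
  expect_equal(got$p, wt$p.value, tolerance = 1e-10)
  # constant feature: p = 1, lfc = 0
  cst <- tab[tab$feature == "f2", ]
  expect_true(all(cst$p == 1))
  expect_true(all(cst$lfc == 0))
})

test_that("planted markers rank on top with small adjusted p", {
  dat <- planted_marker_data(n_per = 60L, effect = 4, noise_sd = 0.3)
  tab <- rank_features(dat$features, dat$labels)
  for (t in 1:3) {
    g <- paste0("type_", t)
    sub <- tab[tab$group == g, ]
    top20 <- head(sub$feature, 20)
    expect_setequal(top20, dat$marker_cols[[t]])
    expect_true(all(sub$p_adj[sub$feature %in% top20] < 5e-3))
  }
  # a single-cell group is skipped with a warning
  labs2 <- as.character(dat$labels)
  labs2[1] <- "lonely"
  labs2[dat$labels == "type_1"][-1] <- "type_1"
  expect_warning(rank_features(dat$features, factor(labs2)), "fewer than 2")
})

test_that("marker sets respect the significance filter and top-k boundary", {
  tab <- data.frame(group = "g",
                    feature = paste0("f", 1:6),
                    lfc = c(5, 4, 3, 2, 1, 6),
                    p_adj = c(rep(1e-4, 5), 0.5))
  sets <- build_marker_sets(tab, top_k = 4L)
  expect_equal(sets$g, paste0("f", 1:4))       # f6 filtered, f5 over the cap
  sets_all <- build_marker_sets(tab, top_k = 100L)
  expect_equal(length(sets_all$g), 5L)
  tab$p_adj <- 1
  expect_warning(empty <- build_marker_sets(tab), "no significant markers")
  expect_length(empty$g, 0L)
})

# --- preranked GSEA ----------------------------------------------------------

test_that("the enrichment score equals the hand-computed running-sum extremum", {
  metric <- c(a = 5, b = 4, c = 3, d = 2, e = 1,
              f = -1, g = -2, h = -3, i = -4, j = -5)
  set <- c("a", "b", "d")
  # hand computation: hits at ranks 1, 2, 4; NR = 5 + 4 + 2 = 11
  # running sum: 5/11, 9/11, 9/11 - 1/7, 11/11 - 1/7, then only misses
  steps <- c(5 / 11, 4 / 11, -1 / 7, 2 / 11, -1 / 7, -1 / 7, -1 / 7, -1 / 7,
             -1 / 7, -1 / 7)
  rs <- cumsum(steps)
  es_hand <- rs[which.max(abs(rs))]
  withr::with_seed(67, {
    res <- preranked_gsea(metric, set, n_perm = 50L)
  })
  expect_equal(res$ES, es_hand, tolerance = 1e-12)
  expect_gt(res$ES, 0)
  expect_gt(res$NES, 0)
  # bottom-ranked set scores negative
  withr::with_seed(68, {
    res_b <- preranked_gsea(metric, c("h", "i", "j"), n_perm = 50L)
  })
  expect_lt(res_b$ES, 0)
  # empty intersection: NA recorded
  expect_true(is.na(preranked_gsea(metric, c("zz"), n_perm = 10L)$NES))
})

test_that("NES agrees with an exhaustive-null oracle within Monte-Carlo error", {
  metric <- c(a = 5, b = 4, c = 3, d = 2, e = 1,
              f = -1, g = -2, h = -3, i = -4, j = -5)
  set <- c("a", "b", "d")
  # exact null: all choose(10, 3) = 120 same-size sets
  combos <- combn(10, 3)
  es_all <- apply(combos, 2, function(ix) {
    hits <- logical(10); hits[ix] <- TRUE
    scbridge:::gsea_es(metric, hits)
  })
  es <- scbridge:::gsea_es(metric, names(metric) %in% set)
  nes_exact <- es / mean(abs(es_all[sign(es_all) == sign(es)]))
  withr::with_seed(69, {
    res <- preranked_gsea(metric, set, n_perm = 4000L)
  })
  expect_equal(res$NES, nes_exact, tolerance = 0.05)
})

test_that("the enrichment score matches fgsea on random instances", {
  skip_if_not_installed("fgsea")
  withr::with_seed(70, {
    for (trial in 1:3) {
      stats <- sort(rnorm(40), decreasing = TRUE)
      names(stats) <- paste0("f", 1:40)
      set <- sample(names(stats), 8)
      ours <- scbridge:::gsea_es(stats, names(stats) %in% set)
      theirs <- fgsea::calcGseaStat(stats,
                                    selectedStats = which(names(stats) %in% set),
                                    gseaParam = 1)
      expect_equal(ours, theirs, tolerance = 1e-9)
    }
  })
})

test_that("NES confusion matrix lights its diagonal on planted markers", {
  dat <- planted_marker_data(n_per = 50L, n_markers = 100L, n_noise = 100L,
                             effect = 4, noise_sd = 0.3)
  withr::with_seed(71, {
    tab <- rank_features(dat$features, dat$labels)
    sets <- build_marker_sets(tab, top_k = 100L)
    conf <- nes_confusion_matrix(tab, sets, n_perm = 200L)
  })
  expect_equal(dim(conf), c(3L, 3L))
  expect_true(all(diag(unclass(conf)) > 0))
  expect_true(all(is.finite(conf)))
  # a type with an empty marker set is excluded with a warning
  sets2 <- sets; sets2[["type_1"]] <- character(0)
  expect_warning(conf2 <- nes_confusion_matrix(tab, sets2, n_perm = 50L),
                 "empty marker sets")
  expect_equal(dim(conf2), c(2L, 2L))
})

# --- confusion-matrix accuracy ----------------------------------------------

test_that("accuracy follows the stated TP/TN/FP/FN sums", {
  m1 <- matrix(c(1, -0.5, -0.5, 1), 2, 2)      # clean diagonal
  expect_equal(unname(accuracy_from_confusion(m1)["weighted"]), 1)
  m2 <- matrix(c(0, 1, 1, 0), 2, 2)            # positives off the diagonal
  expect_equal(unname(accuracy_from_confusion(m2)["weighted"]), 0)
  m3 <- matrix(1, 2, 2)                        # TP = 2, FP = 2
  expect_equal(unname(accuracy_from_confusion(m3)["weighted"]), 0.5)
  expect_equal(unname(accuracy_from_confusion(m3)["unweighted"]), 0.5)
  expect_error(accuracy_from_confusion(matrix(0, 0, 0)), "square")
})

test_that("accuracy is invariant to positive column rescaling", {
  withr::with_seed(72, {
    m <- matrix(rnorm(16), 4, 4)
  })
  a1 <- accuracy_from_confusion(m)
  a2 <- accuracy_from_confusion(sweep(m, 2, c(2, 0.5, 7, 1.3), `*`))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("end-to-end GSEA accuracy on strong markers is near perfect", {
  dat <- planted_marker_data(n_per = 60L, n_markers = 100L, n_noise = 100L,
                             effect = 4, noise_sd = 0.4)
  withr::with_seed(73, {
    res <- gsea_celltype_accuracy(dat$features, dat$labels, top_k = 100L,
                                  n_perm = 200L, split = FALSE)
  })
  expect_gte(res$accuracy["weighted"], 0.9)
  withr::with_seed(74, {
    res_split <- gsea_celltype_accuracy(dat$features, dat$labels, top_k = 100L,
                                        n_perm = 200L, split = TRUE)
  })
  expect_gte(res_split$accuracy["weighted"], 0.8)
})

test_that("the stratified split keeps every class on both sides at 70:30", {
  labels <- factor(rep(c("a", "b", "c"), times = c(100, 50, 10)))
  withr::with_seed(75, {
    parts <- split_train_test(labels, 0.7)
  })
  expect_equal(sort(c(parts$train, parts$test)), seq_along(labels))
  for (g in levels(labels)) {
    n_tr <- sum(labels[parts$train] == g)
    expect_equal(n_tr, round(sum(labels == g) * 0.7))
  }
})
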