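test_that("AUC handles the canonical cases", {
  expect_equal(auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)), 0.75)
  expect_equal(auc(rep(5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc(1:4, rep(TRUE, 4)), "single_class")
  # label inversion reflects the AUC
  set.seed(60)
  v <- rnorm(20); lab <- rep(c(TRUE, FALSE), 10)
  expect_equal(auc(v, lab), 1 - auc(v, !lab))
})

test_that("AUC equals brute-force pair enumeration, with ties", {
  set.seed(61)
  for (k in 1:20) {
    n <- sample(6:50, 1)
    v <- sample(round(rnorm(n), 1))  # rounded: forces ties
    lab <- sample(c(TRUE, FALSE), n, TRUE)
    if (all(lab) || !any(lab)) next
    expect_equal(auc(v, lab), auc_oracle(v, lab))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(62)
  v <- rnorm(30); lab <- rep(c(TRUE, FALSE), 15)
  a <- auc(v, lab)
  expect_equal(auc(exp(v), lab), a)
  expect_equal(auc(v^3 + 5 * v, lab), a)
  expect_equal(auc(rank(v), lab), a)
})

test_that("ROC metrics maximize Youden's J, ties to higher specificity", {
  # separable data
  m <- roc_metrics(c(1, 2, 3, 10, 11, 12),
                   rep(c(FALSE, TRUE), each = 3))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  # brute-force cutoff oracle
  set.seed(63)
  for (k in 1:10) {
    v <- rnorm(14); lab <- rep(c(TRUE, FALSE), 7)
    got <- roc_metrics(v, lab)
    vs <- sort(unique(v))
    cuts <- c(vs[1] - 1, (vs[-1] + vs[-length(vs)]) / 2,
              vs[length(vs)] + 1)
    best_j <- -Inf; best_spec <- -Inf; best_acc <- NA
    for (cut in cuts) {
      pred <- if (got$direction == ">") v > cut else v < cut
      sens <- sum(pred & lab) / sum(lab)
      spec <- sum(!pred & !lab) / sum(!lab)
      j <- sens + spec - 1
      if (j > best_j + 1e-12 ||
          (abs(j - best_j) <= 1e-12 && spec > best_spec + 1e-12)) {
        best_j <- j; best_spec <- spec
        best_acc <- mean(pred == lab)
      }
    }
    expect_equal(got$sensitivity + got$specificity - 1, best_j)
    expect_equal(got$specificity, best_spec)
    expect_equal(got$accuracy, best_acc)
  }
})

test_that("AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  for (k in 1:5) {
    v <- rnorm(20); lab <- rep(c(TRUE, FALSE), 10)
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, v,
                                                           quiet = TRUE))))
    got <- auc(v, lab)
    expect_equal(max(got, 1 - got), max(ref, 1 - ref), tolerance = 1e-12)
  }
})

test_that("synthetic DE features separate conditions with high AUC", {
  aucs <- vapply(1:20, function(s) {
    d <- simulate_dataset(sim_config(n_mirna = 10, n_mrna = 10,
                                     n_reps_per_condition = 10,
                                     effect_size = 2, noise_sd = 0.5,
                                     bio_sd = 0, n_planted_edges = 0,
                                     seed = s))
    de <- d$truth$de_mirnas
    mean(vapply(de, function(id) {
      a <- auc(d$mirna[id, ], d$condition == "treated")
      max(a, 1 - a)  # down-regulated features discriminate low-side
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(aucs), 0.9)
})

test_that("the per-miRNA ROC fixture summarizes as printed", {
  tab <- load_table2_fixture()
  expect_equal(nrow(tab), 13)
  s <- summarize_fixture(tab)
  expect_equal(s$min[s$metric == "auc"], 0.870)
  expect_equal(s$max[s$metric == "auc"], 0.986)
  row <- tab[tab$mirna == "osa-miR319a-3p", ]
  expect_equal(row$auc, 0.950)
  expect_equal(row$accuracy, 0.900)
})

test_that("hierarchical clustering is correct on hand-checkable cases", {
  # identical rows merge at height zero
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             d = c(1, 2, 3, 4))
  hc <- hierarchical_cluster(m, metric = "pearson")
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
  # scaling a row leaves correlation distances unchanged
  m2 <- m; m2["c", ] <- 3 * m2["c", ]
  hc2 <- hierarchical_cluster(m2, metric = "pearson")
  expect_equal(hc$height, hc2$height, tolerance = 1e-12)
  # merge heights are monotone under average linkage here
  expect_true(all(diff(hc$height) >= -1e-12))
  expect_error(hierarchical_cluster(rbind(a = rep(1, 4), b = 1:4)),
               "zero_variance_feature")
})

test_that("average-linkage tree equals a naive agglomeration oracle", {
  set.seed(65)
  m <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(letters[1:5], NULL))
  hc <- hierarchical_cluster(m, metric = "euclidean", linkage = "average")
  # O(n^3) naive average-linkage on the same distances
  d <- as.matrix(dist(m[sort(rownames(m)), ]))
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(j, i) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(sort(hc$height), sort(heights), tolerance = 1e-10)
})

test_that("dendrograms export to Newick parseable by ape", {
  m <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(letters[1:4], NULL))
  hc <- hierarchical_cluster(m, metric = "euclidean")
  nw <- cluster_newick(hc)
  tree <- ape::read.tree(text = nw)
  expect_setequal(tree$tip.label, letters[1:4])
})
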