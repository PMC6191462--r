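# Classification, ROC/AUC, clustering.

test_that("rank AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.5)), 0.75)

  set.seed(8)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forced ties
    expect_equal(roc_auc(labels, scores), auc_brute(labels, scores))
    # complement property
    expect_equal(roc_auc(labels, scores) + roc_auc(labels, -scores), 1)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  labels <- sample(0:1, 40, replace = TRUE)
  labels[1:2] <- 0:1
  scores <- rnorm(40)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-12)
})

synthetic_table <- function(n_per_class, sep, seed) {
  set.seed(seed)
  n <- 2 * n_per_class
  label <- rep(c("adeno-like", "granuloma-like"), each = n_per_class)
  f <- vapply(1:5, function(j) rnorm(n) + sep * (label == "adeno-like"),
              numeric(n))
  colnames(f) <- paste0("f", 1:5)
  cbind(data.frame(case_id = sprintf("c%02d", 1:n), label = label,
                   stringsAsFactors = FALSE), as.data.frame(f))
}

test_that("cross-validated training separates a strong synthetic effect", {
  tab <- synthetic_table(15, sep = 3, seed = 1)
  for (kind in c("svm", "knn", "naive_bayes")) {
    cv <- train_evaluate(tab, classifier_spec(kind, rng_seed = 2),
                         paste0("f", 1:5))
    expect_gte(cv$cv_auc_mean, 0.9)
  }
})

test_that("permuted labels give chance-level AUC and constant features warn", {
  tab <- synthetic_table(15, sep = 3, seed = 1)
  set.seed(5)
  tab$label <- sample(tab$label)
  cv <- train_evaluate(tab, classifier_spec("svm", rng_seed = 2), paste0("f", 1:5))
  expect_gt(cv$cv_auc_mean, 0.2)
  expect_lt(cv$cv_auc_mean, 0.8)

  tab$cst <- 1
  expect_warning(cvc <- train_evaluate(tab, classifier_spec("naive_bayes", rng_seed = 2),
                                       "cst"), "constant")
  expect_equal(cvc$cv_auc_mean, 0.5, tolerance = 0.05)
})

test_that("training scores behave sensibly and are reproducible", {
  tab <- synthetic_table(12, sep = 2, seed = 3)
  cv <- train_evaluate(tab, classifier_spec("svm", rng_seed = 7), paste0("f", 1:5))
  sc <- predict_scores(cv$model, tab)
  expect_true(all(sc >= 0 & sc <= 1))
  # resubstitution AUC at least as high as CV AUC (overfit direction)
  expect_gte(roc_auc(tab$label, sc) + 1e-9, cv$cv_auc_mean)

  # duplicated row scores identically
  dup <- rbind(tab[1, ], tab[1, ])
  expect_equal(diff(predict_scores(cv$model, dup)), 0)
  # empty table gives empty scores
  expect_length(predict_scores(cv$model, tab[0, ]), 0)
  # missing feature is reported by name
  expect_error(predict_scores(cv$model, tab[setdiff(names(tab), "f3")]), "f3")

  # row order invariance given the same seed (folds built on sorted ids)
  shuf <- tab[sample(nrow(tab)), ]
  cv2 <- train_evaluate(shuf, classifier_spec("svm", rng_seed = 7), paste0("f", 1:5))
  expect_equal(cv$fold_aucs, cv2$fold_aucs)
  expect_error(train_evaluate(tab[c(1, 2, 16, 17), ],
                              classifier_spec("svm", cv_folds = 3, rng_seed = 1),
                              "f1"), "fewer folds")
})

test_that("k-means recovers separated blobs and flags degenerate input", {
  set.seed(11)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
  cl <- kmeans_cluster(X, 2, rng_seed = 1)
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:40])), 1)
  expect_false(cl[1] == cl[21])

  # k = number of cases: every case its own cluster
  small <- matrix(rnorm(12), ncol = 2)
  expect_equal(sort(kmeans_cluster(small, 6, rng_seed = 1)), 1:6)
  expect_error(kmeans_cluster(small, 7, rng_seed = 1), "exceeds")

  ident <- matrix(1, 5, 2)
  dg <- kmeans_cluster(ident, 2, rng_seed = 1)
  expect_true(isTRUE(attr(dg, "degenerate")))
})

test_that("consensus clustering: exact toy matrix, run counts, purity", {
  # 4 cases forming two tight pairs: block-diagonal consensus at k = 2
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10, 10.1))
  res <- consensus_cluster(X, k_list = 2,
                           metric_list = c("euclidean", "cityblock"),
                           n_restarts = 5, rng_seed = 3,
                           labels = c("a", "a", "b", "b"))
  expect_true(isSymmetric(res$cooccurrence))
  expect_equal(diag(res$cooccurrence), rep(1, 4))
  expect_equal(res$cooccurrence[1, 2], 1)
  expect_equal(res$cooccurrence[3, 4], 1)
  expect_equal(res$cooccurrence[1, 3], 0)
  expect_equal(res$overall_purity, 1)

  # a single run configuration gives a binary consensus matrix
  one <- consensus_cluster(X, k_list = 2, metric_list = "cityblock",
                           n_restarts = 1, rng_seed = 3)
  expect_true(all(one$cooccurrence %in% c(0, 1)))
  expect_equal(one$n_runs, 1)

  # planted clusters at realistic size: purity >= 0.9
  set.seed(13)
  Y <- rbind(matrix(rnorm(60, 0), ncol = 3), matrix(rnorm(60, 4), ncol = 3))
  resy <- consensus_cluster(Y, rng_seed = 5,
                            labels = rep(c("a", "b"), each = 20))
  expect_gte(resy$overall_purity, 0.9)
  expect_true(all(resy$cooccurrence >= 0 & resy$cooccurrence <= 1))
})

test_that("slice-thickness errors below native spacing and at empty input", {
  coh <- make_cohort(2, seed = 5)
  expect_error(sensitivity_to_slice_thickness(coh, numeric(0)), "empty")
  expect_error(sensitivity_to_slice_thickness(coh, 0.1), "below native")
})
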