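# Supervised classification with cross-validated AUC, and unsupervised
# k-means / co-occurrence consensus clustering.

#' Classifier specification
#'
#' @param kind `"svm"` (RBF kernel), `"knn"` or `"naive_bayes"`.
#' @param cv_folds number of stratified CV folds (>= 2; default 3).
#' @param rng_seed seed for fold assignment and classifier fitting.
#' @param cost_grid,gamma_scale_grid SVM hyperparameter grid; gamma values
#'   are `gamma_scale / n_features`.
#' @param k_neighbors neighbourhood size for KNN.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "knn", "naive_bayes"),
                            cv_folds = 3L, rng_seed = 1L,
                            cost_grid = c(0.1, 1, 10),
                            gamma_scale_grid = c(0.5, 1, 2),
                            k_neighbors = 5L) {
  kind <- match.arg(kind)
  stopifnot(cv_folds >= 2)
  structure(list(kind = kind, cv_folds = as.integer(cv_folds),
                 rng_seed = as.integer(rng_seed), cost_grid = cost_grid,
                 gamma_scale_grid = gamma_scale_grid,
                 k_neighbors = as.integer(k_neighbors)),
            class = "classifier_spec")
}

positive_class <- function(labels) {
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2) stopf("need exactly 2 classes, got %d", length(u))
  u[1]
}

#' Area under the ROC curve (rank formulation)
#'
#' Probability that a random positive case outscores a random negative one,
#' with ties counted 1/2 (Mann-Whitney).
#'
#' @param labels binary labels. For logical/numeric labels the positive class
#'   is the larger value; for character/factor labels it is the first class
#'   in sort order.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- if (is.logical(labels) || is.numeric(labels)) {
    labels == max(labels)
  } else {
    as.character(labels) == positive_class(labels)
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("roc_auc: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

feature_matrix <- function(table, feature_subset) {
  missing <- setdiff(feature_subset, names(table))
  if (length(missing) > 0) stopf("missing feature column(s): %s",
                                 paste(missing, collapse = ", "))
  as.matrix(table[feature_subset])
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2, std$center), 2, std$scale, `/`)
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    if (length(unique(labels[fold != f])) < 2 ||
        length(labels[fold == f]) == 0) {
      stopf("fold %d lacks both classes; use fewer folds", f)
    }
  }
  fold
}

fit_classifier <- function(kind, X, y, positive, hyper, seed) {
  set.seed(seed)
  y <- factor(y)
  switch(kind,
    svm = e1071::svm(X, y, kernel = "radial", cost = hyper$cost,
                     gamma = hyper$gamma, probability = TRUE, scale = FALSE),
    naive_bayes = e1071::naiveBayes(X, y),
    knn = list(train = X, cl = y, k = hyper$k)  # lazy learner
  )
}

score_classifier <- function(kind, fit, X, positive) {
  if (nrow(X) == 0) return(numeric(0))
  switch(kind,
    svm = {
      pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, positive])
    },
    naive_bayes = {
      pr <- predict(fit, X, type = "raw")
      as.numeric(pr[, positive])
    },
    knn = {
      pred <- class::knn(fit$train, X, fit$cl, k = fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(as.character(pred) == positive, p, 1 - p)
    })
}

hyper_grid <- function(spec, n_features) {
  switch(spec$kind,
    svm = {
      g <- expand.grid(cost = spec$cost_grid,
                       gamma = spec$gamma_scale_grid / n_features)
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    knn = list(list(k = spec$k_neighbors)),
    naive_bayes = list(list()))
}

#' Train and cross-validate a classifier on a cohort table
#'
#' Stratified k-fold cross-validation with fold-internal z-scoring (the
#' standardizer is fit on the training folds only). For the SVM, a small
#' fixed hyperparameter grid is evaluated by the same CV and the best grid
#' point is kept. The returned model is refit on all rows ("locked down")
#' with the winning hyperparameters and carries its feature list and scaler.
#'
#' @param table data.frame with `case_id`, `label` and feature columns.
#' @param spec a [classifier_spec()].
#' @param feature_subset character vector of feature names to use (when
#'   `select_k` is given, the candidate pool for fold-internal selection).
#' @param select_k optional: run mRMR selection of `select_k` features
#'   inside every training fold, so the reported CV AUC is free of
#'   feature-selection leakage. The locked-down model uses the selection on
#'   all rows.
#' @return A list: `model` (class `qvt_model`), `cv_auc_mean`, `cv_auc_sd`,
#'   `fold_aucs`, `hyper` (winning hyperparameters), `positive`.
#' @export
train_evaluate <- function(table, spec, feature_subset, select_k = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), length(feature_subset) >= 1)
  if ("case_id" %in% names(table)) table <- table[order(table$case_id), ]
  y <- as.character(table$label)
  positive <- positive_class(y)
  X <- feature_matrix(table, feature_subset)
  if (all(apply(X, 2, sd) == 0)) {
    warning("train_evaluate: all selected features are constant; AUC is chance level")
  }
  folds <- stratified_folds(y, spec$cv_folds, derive_seed(spec$rng_seed, "cv-folds"))
  grid <- hyper_grid(spec, ncol(X))

  fold_features <- function(tr) {
    if (is.null(select_k)) return(feature_subset)
    sub <- cbind(data.frame(label = y[tr], stringsAsFactors = FALSE),
                 as.data.frame(X[tr, , drop = FALSE]))
    mrmr_select(sub, min(select_k, ncol(X)))$selected
  }

  # hyperparameter choice happens inside each training fold (2-fold inner CV)
  # so the reported fold AUCs carry no selection optimism
  pick_hyper <- function(Xtr, ytr, seed, grid) {
    if (length(grid) == 1) return(grid[[1]])
    inner <- tryCatch(stratified_folds(ytr, 2L, seed),
                      error = function(e) NULL)
    if (is.null(inner)) return(grid[[1]])
    means <- vapply(grid, function(hy) {
      mean(vapply(1:2, function(g) {
        itr <- inner != g
        std <- standardizer(Xtr[itr, , drop = FALSE])
        fit <- fit_classifier(spec$kind,
                              apply_standardizer(Xtr[itr, , drop = FALSE], std),
                              ytr[itr], positive, hy, seed)
        sc <- score_classifier(spec$kind, fit,
                               apply_standardizer(Xtr[!itr, , drop = FALSE], std),
                               positive)
        tryCatch(roc_auc(ytr[!itr], sc), error = function(e) 0.5)
      }, numeric(1)))
    }, numeric(1))
    grid[[which.max(means)]]
  }

  fold_hyper <- vector("list", spec$cv_folds)
  fold_aucs <- vapply(seq_len(spec$cv_folds), function(f) {
    tr <- folds != f
    feats <- fold_features(tr)
    Xf <- X[, feats, drop = FALSE]
    grid_f <- hyper_grid(spec, ncol(Xf))
    hy <- pick_hyper(Xf[tr, , drop = FALSE], y[tr],
                     derive_seed(spec$rng_seed, paste0("inner-", f)), grid_f)
    fold_hyper[[f]] <<- hy
    std <- standardizer(Xf[tr, , drop = FALSE])
    fit <- fit_classifier(spec$kind, apply_standardizer(Xf[tr, , drop = FALSE], std),
                          y[tr], positive, hy,
                          derive_seed(spec$rng_seed, paste0("fit-", f)))
    sc <- score_classifier(spec$kind, fit,
                           apply_standardizer(Xf[!tr, , drop = FALSE], std), positive)
    roc_auc(y[!tr], sc)
  }, numeric(1))

  # lock-down: select on all rows (when requested), take the hyperparameters
  # picked most often across folds (ties to canonical grid order), refit
  final_features <- if (is.null(select_k)) feature_subset else fold_features(rep(TRUE, nrow(X)))
  keys <- vapply(fold_hyper, function(h) paste(unlist(h), collapse = "/"),
                 character(1))
  best_key <- names(sort(table(factor(keys, levels = unique(keys))),
                         decreasing = TRUE))[1]
  best_hyper <- fold_hyper[[match(best_key, keys)]]
  Xfin <- X[, final_features, drop = FALSE]
  std <- standardizer(Xfin)
  fit <- fit_classifier(spec$kind, apply_standardizer(Xfin, std), y, positive,
                        best_hyper, derive_seed(spec$rng_seed, "fit-final"))
  model <- structure(list(kind = spec$kind, fit = fit, features = final_features,
                          std = std, positive = positive, hyper = best_hyper),
                     class = "qvt_model")
  list(model = model, cv_auc_mean = mean(fold_aucs), cv_auc_sd = sd(fold_aucs),
       fold_aucs = fold_aucs, hyper = best_hyper, positive = positive)
}

#' Score cases with a locked-down model
#'
#' @param model a `qvt_model` from [train_evaluate()].
#' @param table data.frame containing the model's feature columns.
#' @return Numeric malignancy-like scores in \[0, 1\] (probability of the
#'   model's positive class); empty input gives an empty vector.
#' @export
predict_scores <- function(model, table) {
  stopifnot(inherits(model, "qvt_model"))
  if (nrow(table) == 0) return(numeric(0))
  X <- feature_matrix(table, model$features)
  score_classifier(model$kind, model$fit, apply_standardizer(X, model$std),
                   model$positive)
}

#' Seeded k-means clustering of a cohort table
#'
#' Columns are z-scored; Lloyd iterations with `n_restarts` seeded restarts,
#' keeping the best inertia.
#'
#' @param table data.frame (feature columns are all numeric columns except
#'   `case_id`/`label`) or a numeric matrix.
#' @param k number of clusters (2 <= k <= cases).
#' @param rng_seed seed.
#' @param n_restarts random restarts.
#' @return Integer cluster assignment with attribute `degenerate = TRUE` when
#'   the data had fewer distinct rows than clusters.
#' @export
kmeans_cluster <- function(table, k, rng_seed = 1L, n_restarts = 10L) {
  X <- cluster_matrix(table)
  if (k > nrow(X)) stopf("kmeans_cluster: k = %d exceeds %d cases", k, nrow(X))
  stopifnot(k >= 2)
  if (k == nrow(X)) return(seq_len(nrow(X)))   # every case its own cluster
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    assign <- rep(1L, nrow(X))
    attr(assign, "degenerate") <- TRUE
    return(assign)
  }
  set.seed(rng_seed)
  km <- kmeans(X, centers = k, nstart = n_restarts, iter.max = 100)
  km$cluster
}

cluster_matrix <- function(table) {
  X <- if (is.data.frame(table)) {
    as.matrix(table[setdiff(names(table), c("case_id", "label"))])
  } else as.matrix(table)
  std <- standardizer(X)
  apply_standardizer(X, std)
}

#' Co-occurrence consensus clustering
#'
#' The cohort is clustered many times (every k in `k_list` crossed with every
#' distance metric; the euclidean/k-means runs additionally restart
#' `n_restarts` times from random initialisations). The consensus matrix
#' holds, per case pair, the fraction of runs assigning both to the same
#' cluster; average-linkage hierarchical clustering of (1 - consensus) then
#' yields the two dominant clusters.
#'
#' @param table cohort table or numeric matrix.
#' @param k_list cluster counts to sweep.
#' @param metric_list subset of `"euclidean"` (k-means), `"cityblock"` and
#'   `"correlation"` (partitioning around medoids on the distance matrix).
#' @param n_restarts k-means restarts per k.
#' @param rng_seed seed.
#' @param labels optional true labels for purity evaluation.
#' @return A list of class `consensus_result`: `cooccurrence` (symmetric,
#'   unit diagonal), `assignment` (2 clusters), `purity` (per cluster, when
#'   labels given), `overall_purity`, `n_runs`.
#' @export
consensus_cluster <- function(table, k_list = c(2, 3, 4),
                              metric_list = c("euclidean", "cityblock", "correlation"),
                              n_restarts = 20L, rng_seed = 1L, labels = NULL) {
  stopifnot(length(k_list) >= 1, length(metric_list) >= 1)
  X <- cluster_matrix(table)
  n <- nrow(X)
  co <- matrix(0, n, n)
  runs <- 0L
  for (k in k_list) {
    if (k > n) stopf("consensus_cluster: k = %d exceeds %d cases", k, n)
    for (metric in metric_list) {
      assigns <- if (metric == "euclidean") {
        lapply(seq_len(n_restarts), function(r) {
          if (nrow(unique(X)) < k) return(rep(1L, n))
          set.seed(derive_seed(rng_seed, sprintf("km-%d-%d", k, r)))
          kmeans(X, centers = k, nstart = 1, iter.max = 100)$cluster
        })
      } else {
        d <- switch(metric,
                    cityblock = dist(X, method = "manhattan"),
                    correlation = {
                      cm <- suppressWarnings(cor(t(X)))
                      cm[!is.finite(cm)] <- 0   # zero-variance rows
                      as.dist(1 - cm)
                    },
                    stopf("unknown metric '%s'", metric))
        list(cluster::pam(d, k, cluster.only = TRUE))
      }
      for (a in assigns) {
        co <- co + outer(a, a, `==`)
        runs <- runs + 1L
      }
    }
  }
  co <- co / runs
  diag(co) <- 1
  hc <- hclust(as.dist(1 - co), method = "average")
  assignment <- cutree(hc, k = 2)
  purity <- overall <- NULL
  if (!is.null(labels)) {
    labels <- as.character(labels)
    purity <- vapply(1:2, function(cl) {
      in_cl <- labels[assignment == cl]
      if (length(in_cl) == 0) return(NA_real_)
      max(table(in_cl)) / length(in_cl)
    }, numeric(1))
    overall <- sum(vapply(1:2, function(cl) {
      in_cl <- labels[assignment == cl]
      if (length(in_cl) == 0) 0 else max(table(in_cl))
    }, numeric(1))) / length(labels)
  }
  structure(list(cooccurrence = co, assignment = assignment, purity = purity,
                 overall_purity = overall, n_runs = runs),
            class = "consensus_result")
}

#' Classification performance as a function of slice thickness
#'
#' Each case volume is resampled along z to the requested slice thickness
#' (linear interpolation of HU; nearest-neighbour for the nodule mask), the
#' full pipeline (lung isolation, region growing, centerline extraction,
#' feature computation, mRMR selection, cross-validated training) is rerun,
#' and the CV AUC is reported per thickness.
#'
#' @param cohort a [make_cohort()] result.
#' @param thickness_list slice thicknesses in mm (each >= native z spacing).
#' @param spec a [classifier_spec()].
#' @param config pipeline configuration (see [default_config()]).
#' @return data.frame: `thickness_mm`, `auc_mean`, `auc_sd`.
#' @export
sensitivity_to_slice_thickness <- function(cohort, thickness_list,
                                           spec = classifier_spec(),
                                           config = default_config()) {
  if (length(thickness_list) == 0) stopf("sensitivity_to_slice_thickness: empty thickness list")
  native <- cohort$cases[[1]]$volume$spacing[3]
  if (any(thickness_list < native - 1e-9)) {
    stopf("slice thickness below native spacing (%.3g mm)", native)
  }
  out <- data.frame(thickness_mm = thickness_list, auc_mean = NA_real_,
                    auc_sd = NA_real_)
  for (ti in seq_along(thickness_list)) {
    t <- thickness_list[ti]
    tab <- cohort_feature_table(lapply(cohort$cases, resample_case_z, t),
                                cohort$manifest, config)
    pool <- setdiff(names(tab), c("case_id", "label"))
    cv <- train_evaluate(tab, spec, pool,
                         select_k = min(config$select_k, length(pool)))
    out$auc_mean[ti] <- cv$cv_auc_mean
    out$auc_sd[ti] <- cv$cv_auc_sd
  }
  out
}

# Resample a phantom case along z to slice thickness t (mm). Each output
# slice averages the native slices inside its slab (the slice sensitivity
# profile of a thick acquisition), which reproduces the partial-volume
# dilution of thin vessels that thick-slice CT suffers from. The nodule mask
# is propagated as the slab union so seeds stay inside the nodule.
resample_case_z <- function(case, t) {
  v <- case$volume
  dz <- v$spacing[3]
  if (abs(t - dz) < 1e-9) return(case)
  d <- dim(v$values)
  zmax <- (d[3] - 1) * dz
  znew <- seq(0, zmax, by = t)
  zk <- (seq_len(d[3]) - 1) * dz
  newvals <- array(0, dim = c(d[1], d[2], length(znew)))
  newnod <- array(FALSE, dim = c(d[1], d[2], length(znew)))
  for (s in seq_along(znew)) {
    sel <- which(abs(zk - znew[s]) <= t / 2 + 1e-9)
    slab <- v$values[, , sel, drop = FALSE]
    newvals[, , s] <- apply(slab, c(1, 2), mean)
    nod <- case$nodule_mask$values[, , sel, drop = FALSE]
    newnod[, , s] <- apply(nod, c(1, 2), any)
  }
  sp <- c(v$spacing[1:2], t)
  out <- case
  out$volume <- image_volume(newvals, sp, v$origin)
  out$nodule_mask <- binary_mask(newnod, sp, v$origin)
  out$truth_vessel_mask <- NULL
  out
}
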