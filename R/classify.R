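# Classifiers and leave-one-out evaluation.
#
# Gaussian naive Bayes and KNN (which carry the headline result) are
# implemented natively with fully specified tie-breaking so leave-one-out
# results are bit-reproducible; SVM and tree-bagger plug in through the same
# fit/predict contract via e1071 and randomForest.

#' Classifier specification
#'
#' @param kind One of `"naive_bayes"`, `"knn"`, `"svm"`, `"tree_bagger"`.
#' @param k Neighbourhood size for KNN (odd, >= 1).
#' @param use_pca Apply PCA (fitted on the training fold only) before the
#'   classifier.
#' @param feature_subset Character vector of feature names, default all six.
#' @param var_retained PCA variance retention.
#' @param cost SVM cost parameter (linear kernel).
#' @param n_trees Tree count for the bagged-tree ensemble.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("naive_bayes", "knn", "svm", "tree_bagger"),
                            k = 5, use_pca = FALSE, feature_subset = NULL,
                            var_retained = 0.99, cost = 1, n_trees = 200) {
  kind <- match.arg(kind)
  if (kind == "knn") {
    if (k < 1 || k != round(k)) usage_error("k must be a positive integer")
    if (k %% 2 == 0) usage_error("k must be odd for reproducible voting")
  }
  structure(list(kind = kind, k = k, use_pca = use_pca,
                 feature_subset = feature_subset,
                 var_retained = var_retained, cost = cost, n_trees = n_trees),
            class = "classifier_spec")
}

# --- Gaussian naive Bayes -------------------------------------------------

nb_fit <- function(x, y) {
  x <- as.matrix(x)
  classes <- levels(droplevels(y))
  overall_var <- apply(x, 2L, stats::var)
  floor_var <- pmax(1e-9 * overall_var, 1e-12)
  stats_by_class <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    v <- if (nrow(xi) < 2L) rep(0, ncol(xi)) else apply(xi, 2L, stats::var)
    if (any(v < floor_var)) {
      if (nrow(xi) < 2L) {
        warning(sprintf(
          "class %s has a single training row; variance floored", cl))
      }
      v <- pmax(v, floor_var)
    }
    list(mu = mu, var = v, n = nrow(xi))
  })
  names(stats_by_class) <- classes
  priors <- vapply(stats_by_class, function(s) s$n, numeric(1)) / nrow(x)
  list(classes = classes, stats = stats_by_class, priors = priors)
}

nb_predict <- function(model, x) {
  x <- as.matrix(x)
  scores <- vapply(model$classes, function(cl) {
    s <- model$stats[[cl]]
    ll <- rep(log(model$priors[[cl]]), nrow(x))
    for (j in seq_len(ncol(x))) {
      ll <- ll + stats::dnorm(x[, j], s$mu[j], sqrt(s$var[j]), log = TRUE)
    }
    ll
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  # tie-break: larger posterior, then larger class frequency, then
  # lexicographic label order
  freq_rank <- rank(-vapply(model$stats, function(s) s$n, numeric(1)),
                    ties.method = "first")
  apply(scores, 1L, function(sc) {
    best <- which(sc >= max(sc) - 1e-12)
    model$classes[best[order(freq_rank[best], model$classes[best])][1L]]
  })
}

#' Fit-and-predict Gaussian naive Bayes
#'
#' Gaussian class-conditional densities with independent features, priors
#' equal to class frequencies, per-class per-feature variances floored at
#' 1e-9 times the overall feature variance. Posterior ties break toward the
#' more frequent class, then lexicographic label order.
#'
#' @param train_x,train_y Training feature matrix and labels (factor).
#' @param test_x Feature matrix to classify.
#' @return Character vector of predicted labels.
#' @export
fit_predict_naive_bayes <- function(train_x, train_y, test_x) {
  if (length(unique(train_y)) < 1L) usage_error("empty training set")
  nb_predict(nb_fit(train_x, train_y), test_x)
}

# --- k-nearest neighbours -------------------------------------------------

#' Fit-and-predict k-nearest neighbours
#'
#' Euclidean distances; majority vote over the k nearest training rows.
#' Vote ties break by the larger summed inverse distance, then class
#' frequency, then lexicographic order. Features should be standardized with
#' training statistics before calling (done automatically inside [loo_cv()]).
#'
#' @param train_x,train_y Training matrix and labels.
#' @param test_x Rows to classify.
#' @param k Neighbourhood size (<= number of training rows).
#' @return Character vector of predicted labels.
#' @export
fit_predict_knn <- function(train_x, train_y, test_x, k = 5) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (k > nrow(train_x)) {
    usage_error(sprintf("k (%d) exceeds the number of training rows (%d)",
                        k, nrow(train_x)))
  }
  y <- as.character(train_y)
  freq <- table(y)
  apply(test_x, 1L, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      w <- vapply(top, function(cl) {
        sum(1 / (d[nn][y[nn] == cl] + 1e-12))
      }, numeric(1))
      top <- top[w >= max(w) - 1e-12]
      if (length(top) > 1L) {
        top <- top[order(-as.numeric(freq[top]), top)]
      }
    }
    top[1L]
  })
}

# --- pluggable backends ---------------------------------------------------

clf_fit_predict <- function(spec, train_x, train_y, test_x, fold_seed = NULL) {
  train_y <- droplevels(factor(train_y))
  switch(
    spec$kind,
    naive_bayes = fit_predict_naive_bayes(train_x, train_y, test_x),
    knn = fit_predict_knn(train_x, train_y, test_x, k = spec$k),
    svm = {
      if (nlevels(train_y) < 2L) {
        rep(levels(train_y), nrow(as.matrix(test_x)))
      } else {
        fit <- e1071::svm(x = as.matrix(train_x), y = train_y,
                          kernel = "linear", cost = spec$cost, scale = TRUE)
        as.character(stats::predict(fit, as.matrix(test_x)))
      }
    },
    tree_bagger = {
      if (!is.null(fold_seed)) set.seed(fold_seed)
      fit <- randomForest::randomForest(x = as.matrix(train_x), y = train_y,
                                        ntree = spec$n_trees)
      as.character(stats::predict(fit, as.matrix(test_x)))
    },
    usage_error(sprintf("unknown classifier kind: %s", spec$kind)))
}

# --- leave-one-out evaluation --------------------------------------------

feature_matrix <- function(table, subset = NULL) {
  if (is.null(subset)) subset <- FEATURE_COLS
  unknown <- setdiff(subset, FEATURE_COLS)
  if (length(unknown) > 0L) {
    usage_error(sprintf("unknown feature name(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  as.matrix(as.data.frame(table)[, subset, drop = FALSE])
}

#' Leave-one-out cross validation
#'
#' For each row, the classifier (and any standardization or PCA) is fitted on
#' all remaining rows and the held-out row is predicted; no statistic ever
#' sees the test row. KNN and SVM inputs are standardized with training-fold
#' statistics; PCA, when requested, is likewise fitted per fold.
#'
#' @param table A `labeled_feature_table`.
#' @param spec A [classifier_spec()].
#' @param seed Base seed for stochastic classifiers (per-fold seeds derive
#'   from it); deterministic classifiers ignore it.
#' @param diagnostics Record per-fold preprocessing statistics (used to audit
#'   the absence of train/test leakage).
#' @return List of class `cv_report`: `accuracy`, `confusion` (4x4 over the
#'   NINDS grades), `misclassified_ids`, `predicted`, and optionally
#'   `fold_stats`.
#' @export
loo_cv <- function(table, spec, seed = 1, diagnostics = FALSE) {
  table <- validate_feature_table(as.data.frame(table))
  if (nrow(table) < 2L) usage_error("LOO CV needs at least 2 rows")
  x <- feature_matrix(table, spec$feature_subset)
  y <- table$label
  n <- nrow(x)
  pred <- character(n)
  fold_stats <- if (diagnostics) vector("list", n) else NULL

  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    te_x <- x[i, , drop = FALSE]
    if (spec$kind %in% c("knn", "svm") || spec$use_pca) {
      ctr <- colMeans(tr_x)
      scl <- apply(tr_x, 2L, stats::sd)
      scl[scl == 0] <- 1
      tr_x <- sweep(sweep(tr_x, 2L, ctr), 2L, scl, "/")
      te_x <- sweep(sweep(te_x, 2L, ctr), 2L, scl, "/")
      if (diagnostics) fold_stats[[i]] <- list(center = ctr, scale = scl)
    }
    if (spec$use_pca) {
      fit <- pca_fit_transform(tr_x, var_retained = spec$var_retained,
                               standardize = FALSE)
      tr_x <- fit$scores
      te_x <- pca_apply(fit, te_x)
      if (diagnostics) fold_stats[[i]]$pca_center <- fit$center
    }
    pred[i] <- clf_fit_predict(spec, tr_x, y[-i], te_x,
                               fold_seed = seed + i)
  }

  truth <- factor(as.character(y), levels = ninds_levels())
  predicted <- factor(pred, levels = ninds_levels())
  confusion <- table(truth = truth, predicted = predicted)
  accuracy <- sum(diag(confusion)) / n
  structure(list(accuracy = accuracy, confusion = confusion,
                 misclassified_ids = table$subject_id[pred != as.character(y)],
                 predicted = predicted, fold_stats = fold_stats),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> LOO accuracy %.2f%% (%d/%d misclassified)\n",
              100 * x$accuracy, length(x$misclassified_ids),
              sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Default feature-combination grid
#'
#' The six feature-set x PCA combinations evaluated in the published accuracy
#' grid: (delta_a, vmax) with and without PCA, (delta_a, vmax, ratio_13),
#' (delta_a, ts_s), and (ratio_13, delta_t1_ms, delta_t2_s) with and without
#' PCA.
#'
#' @return List of `list(features, pca)` entries.
#' @export
default_feature_combos <- function() {
  list(
    list(features = c("delta_a", "vmax"), pca = FALSE),
    list(features = c("delta_a", "vmax"), pca = TRUE),
    list(features = c("delta_a", "vmax", "ratio_13"), pca = FALSE),
    list(features = c("delta_a", "ts_s"), pca = FALSE),
    list(features = c("ratio_13", "delta_t1_ms", "delta_t2_s"), pca = FALSE),
    list(features = c("ratio_13", "delta_t1_ms", "delta_t2_s"), pca = TRUE))
}

#' Leave-one-out accuracy grid over feature combinations and classifiers
#'
#' @param table A `labeled_feature_table`.
#' @param combos List of `list(features, pca)` entries
#'   (default [default_feature_combos()]).
#' @param classifiers Character vector of classifier kinds.
#' @param config A [pipeline_config()] supplying `knn_k` and `var_retained`.
#' @param seed Base seed for stochastic classifiers.
#' @return Data frame: one row per combination, one accuracy column per
#'   classifier.
#' @export
accuracy_grid <- function(table, combos = default_feature_combos(),
                          classifiers = c("naive_bayes", "tree_bagger",
                                          "knn", "svm"),
                          config = pipeline_config(), seed = 1) {
  if (length(combos) == 0L) usage_error("combos must be non-empty")
  rows <- lapply(seq_along(combos), function(ci) {
    combo <- combos[[ci]]
    accs <- vapply(classifiers, function(kind) {
      spec <- classifier_spec(kind, k = config$knn_k, use_pca = combo$pca,
                              feature_subset = combo$features,
                              var_retained = config$var_retained)
      loo_cv(table, spec, seed = seed + 1000 * ci)$accuracy
    }, numeric(1))
    cbind(data.frame(features = paste(combo$features, collapse = "+"),
                     pca = combo$pca, stringsAsFactors = FALSE),
          as.data.frame(as.list(accs)))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
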