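# Native classifiers, leave-one-out machinery, accuracy grid.

test_that("naive Bayes with a single training class predicts that class", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  y <- factor(rep("2+", 3), levels = ninds_levels())
  expect_identical(fit_predict_naive_bayes(x, y, matrix(c(-5, 10), ncol = 1)),
                   c("2+", "2+"))
})

test_that("naive Bayes decision boundary sits at the closed-form midpoint", {
  # equal priors, equal sample variances, means 0 and 10 -> boundary at 5
  train <- matrix(c(-1, 1, 9, 11), ncol = 1)
  y <- factor(c("0+", "0+", "3+", "3+"))
  expect_identical(fit_predict_naive_bayes(train, y, matrix(4.9)), "0+")
  expect_identical(fit_predict_naive_bayes(train, y, matrix(5.1)), "3+")
})

test_that("unequal priors shift the boundary by s2*log(p1/p2)/(mu2-mu1)", {
  # class A: 10 rows, sample variance 10/9; class B: 2 rows, same variance
  xa <- rep(c(-1, 1), 5)
  xb <- 10 + c(-1, 1) * sqrt(5) / 3
  train <- matrix(c(xa, xb), ncol = 1)
  y <- factor(c(rep("1+", 10), rep("2+", 2)))
  s2 <- 10 / 9
  boundary <- 5 + s2 * log(10 / 2) / 10
  expect_identical(
    fit_predict_naive_bayes(train, y, matrix(boundary - 0.02)), "1+")
  expect_identical(
    fit_predict_naive_bayes(train, y, matrix(boundary + 0.02)), "2+")
})

test_that("native naive Bayes agrees with an independent implementation", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2),
             matrix(rnorm(30, 4), ncol = 2),
             matrix(rnorm(30, 9), ncol = 2))
  y <- factor(rep(c("1+", "2+", "3+"), c(20, 15, 15)))
  xa <- data.frame(f1 = x[, 1], f2 = x[, 2])
  test_x <- data.frame(f1 = seq(-2, 11, length.out = 25),
                       f2 = seq(-2, 11, length.out = 25))
  ours <- fit_predict_naive_bayes(as.matrix(xa), y, as.matrix(test_x))
  ref <- as.character(predict(e1071::naiveBayes(xa, y), test_x))
  expect_identical(ours, ref)
})

test_that("KNN votes match brute-force distance enumeration", {
  train <- matrix(c(0, 0, 0, 1, 5, 5, 5, 6), ncol = 2, byrow = TRUE)
  y <- factor(c("0+", "0+", "3+", "3+"))

  expect_identical(fit_predict_knn(train, y, train[3, , drop = FALSE], k = 1),
                   "3+")
  # query at (1,1): distances 1.41, 1, 5.66, 6.4 -> 3-NN majority is 0+
  expect_identical(
    fit_predict_knn(train, y, matrix(c(1, 1), ncol = 2), k = 3), "0+")

  dup <- rbind(train, train)
  ydup <- factor(rep(as.character(y), 2))
  expect_identical(
    fit_predict_knn(dup, ydup, matrix(c(5, 5.5), ncol = 2), k = 5), "3+")

  expect_error(fit_predict_knn(train, y, train, k = 9),
               class = "reflexquant_usage_error")
  expect_error(classifier_spec("knn", k = 4),
               class = "reflexquant_usage_error")
})

test_that("LOO is perfect on separated pairs and zero on the diagonal square", {
  tbl <- make_two_group_table(list("0+" = c(1, 1.1), "3+" = c(50, 50.1)))
  spec <- classifier_spec("knn", k = 1, feature_subset = c("delta_a", "vmax"))
  expect_equal(loo_cv(tbl, spec)$accuracy, 1.0)

  # unit-square corners, diagonal classes: every left-out corner's nearest
  # neighbours both belong to the other class
  rows <- data.frame(
    subject_id = sprintf("c%d", 1:4), label = c("0+", "3+", "3+", "0+"),
    delta_a = c(0, 1, 0, 1), ratio_13 = 0.2, delta_t1_ms = 400,
    delta_t2_s = 1.6, ts_s = 2, vmax = c(0, 0, 1, 1))
  sq <- labeled_feature_table(rows$subject_id, rows$label, rows[, 3:8])
  spec1 <- classifier_spec("knn", k = 1, feature_subset = c("delta_a", "vmax"))
  rep1 <- loo_cv(sq, spec1)
  expect_equal(rep1$accuracy, 0.0)
  expect_length(rep1$misclassified_ids, 4)
})

test_that("fold-wise preprocessing statistics exclude the held-out row", {
  tbl <- toy_feature_table(n_per_group = 3)
  spec <- classifier_spec("knn", k = 3, use_pca = TRUE,
                          feature_subset = c("delta_a", "vmax", "ts_s"))
  rep <- loo_cv(tbl, spec, diagnostics = TRUE)
  centers <- do.call(rbind, lapply(rep$fold_stats, `[[`, "center"))
  # removing a different row must change the training mean
  expect_gt(nrow(unique(round(centers, 12))), 1)
  # and every fold's center differs from the all-data mean
  full <- colMeans(as.matrix(tbl[, c("delta_a", "vmax", "ts_s")]))
  expect_true(all(apply(centers, 1, function(ctr) any(abs(ctr - full) > 1e-9))))
})

test_that("confusion matrix is consistent with accuracy and row order", {
  tbl <- toy_feature_table(n_per_group = 4)
  spec <- classifier_spec("naive_bayes", feature_subset = c("delta_a", "vmax"))
  rep <- loo_cv(tbl, spec)
  expect_equal(sum(rep$confusion), nrow(tbl))
  expect_equal(sum(diag(rep$confusion)) / nrow(tbl), rep$accuracy)

  set.seed(4)
  shuffled <- as.data.frame(tbl)[sample(nrow(tbl)), ]
  shuffled <- labeled_feature_table(shuffled$subject_id, shuffled$label,
                                    shuffled[, 3:8])
  expect_equal(loo_cv(shuffled, spec)$accuracy, rep$accuracy)
})

test_that("accuracy grid has the published structure and is reproducible", {
  tbl <- toy_feature_table(n_per_group = 4)
  cfg <- pipeline_config()

  single <- accuracy_grid(tbl, combos = list(list(features = c("delta_a", "vmax"),
                                                  pca = FALSE)),
                          classifiers = "naive_bayes", config = cfg, seed = 1)
  direct <- loo_cv(tbl, classifier_spec("naive_bayes",
                                        feature_subset = c("delta_a", "vmax")),
                   seed = 1001)
  expect_equal(single$naive_bayes, direct$accuracy)

  grid1 <- accuracy_grid(tbl, config = cfg, seed = 9)
  grid2 <- accuracy_grid(tbl, config = cfg, seed = 9)
  expect_identical(grid1, grid2)
  expect_equal(nrow(grid1), 6)
  expect_true(all(c("naive_bayes", "tree_bagger", "knn", "svm") %in%
                    names(grid1)))
  expect_true(all(vapply(grid1[, 3:6], function(col)
    all(col >= 0 & col <= 1), logical(1))))

  expect_error(accuracy_grid(tbl, combos = list()),
               class = "reflexquant_usage_error")
  expect_error(
    loo_cv(tbl, classifier_spec("knn", feature_subset = "no_such_feature")),
    class = "reflexquant_usage_error")
})
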