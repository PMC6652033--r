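# Group summaries, Kruskal-Wallis and PCA.

test_that("group summary computes arithmetic means and n-1 SDs", {
  tbl <- make_two_group_table(list("2+" = c(1, 3)))
  gs <- suppressWarnings(group_summary(tbl))
  row <- gs[gs$feature == "delta_a" & gs$label == "2+", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, sqrt(2))
  expect_equal(row$n, 2)
})

test_that("single-row groups report sd 0 with a warning", {
  tbl <- make_two_group_table(list("1+" = 5, "2+" = c(1, 3)))
  w <- capture_warnings(gs <- group_summary(tbl))
  expect_true(any(grepl("single row", w)))
  expect_true(any(grepl("omitted", w)))   # the absent grades are flagged too
  expect_equal(gs$sd[gs$label == "1+" & gs$feature == "delta_a"], 0)
})

test_that("Kruskal-Wallis handles symmetry, a hand-computed H, and ties", {
  sym <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_equal(sym$H, 0)
  expect_equal(sym$p, 1)

  # groups {1,2}, {3,4}, {5,6}: mean ranks 1.5/3.5/5.5 ->
  # H = 12/(6*7) * 2*((1.5-3.5)^2 + 0 + (5.5-3.5)^2) = 32/7
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$H, 32 / 7, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_false(res$tie_corrected)

  expect_warning(deg <- kruskal_wallis(list(c(2, 2), c(2, 2, 2))),
                 "identical")
  expect_equal(deg$H, 0)
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)

  expect_error(kruskal_wallis(list(1:3)), class = "reflexquant_usage_error")
})

test_that("chi-square p approximates the exhaustive permutation p (n=3,3,3)", {
  # configurations with group-level separation, where the chi-square tail is
  # informative; near the null (interleaved groups) the approximation error
  # at n = 9 reaches ~0.05, which is what the exact mode is for
  separated <- list(
    list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
    list(c(1, 2, 4), c(3, 5, 7), c(6, 8, 9)))
  for (groups in separated) {
    p_perm <- perm_kw_oracle(groups)
    expect_lt(abs(kruskal_wallis(groups)$p - p_perm), 0.05)
    expect_equal(kruskal_wallis(groups, exact = TRUE)$p, p_perm,
                 tolerance = 1e-9)
  }
  # exact mode matches the oracle even interleaved and under heavy ties
  for (groups in list(list(c(1, 4, 7), c(2, 5, 8), c(3, 6, 9)),
                      list(c(1, 1, 2), c(2, 3, 3), c(4, 4, 5)))) {
    expect_equal(kruskal_wallis(groups, exact = TRUE)$p,
                 perm_kw_oracle(groups), tolerance = 1e-9)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(1)
  groups <- list(rnorm(6), rnorm(5, 1), rnorm(7, 2))
  h1 <- kruskal_wallis(groups)$H
  h2 <- kruskal_wallis(lapply(groups, function(g) exp(3 * g)))$H
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("PCA retention, isometry and explained fractions", {
  # collinear points: one component carries everything
  x <- cbind(a = c(-2, -1, 0, 1, 2), b = 2 * c(-2, -1, 0, 1, 2))
  fit <- pca_fit_transform(x, standardize = FALSE)
  expect_equal(fit$k, 1)
  expect_equal(fit$explained[1], 1, tolerance = 1e-12)

  # full retention is a rotation: pairwise distances preserved
  set.seed(2)
  y <- matrix(rnorm(60), ncol = 3)
  fit <- pca_fit_transform(y, var_retained = 1, standardize = FALSE)
  expect_equal(as.matrix(dist(fit$scores)), as.matrix(dist(scale(y, scale = FALSE))),
               tolerance = 1e-9)

  # sample covariance diag(8/3, 2/3): explained fractions 0.8 / 0.2
  z <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1))
  fit <- pca_fit_transform(z, standardize = FALSE)
  expect_equal(fit$explained, c(0.8, 0.2), tolerance = 1e-12)

  const <- cbind(c(1, 1, 1), c(1, 2, 3))
  expect_error(pca_fit_transform(const, standardize = TRUE),
               class = "reflexquant_zero_variance_error")
})

test_that("projection of new rows matches training scores", {
  set.seed(3)
  y <- matrix(rnorm(40), ncol = 2)
  fit <- pca_fit_transform(y, var_retained = 1, standardize = TRUE)
  back <- reflexquant:::pca_apply(fit, y)
  expect_equal(unname(back), unname(fit$scores[, seq_len(fit$k), drop = FALSE]),
               tolerance = 1e-9)
})
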