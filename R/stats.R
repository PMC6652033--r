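# Group statistics, Kruskal-Wallis separation tests and PCA.

#' Per-grade feature summary (n, mean, sd)
#'
#' Means are arithmetic; SDs use the n-1 denominator. A group with a single
#' row reports sd = 0 with a warning (the unbiased estimate is undefined);
#' empty groups are omitted with a warning.
#'
#' @param table A `labeled_feature_table`.
#' @return Data frame with columns `label`, `feature`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(table) {
  table <- validate_feature_table(as.data.frame(table))
  present <- levels(table$label)[levels(table$label) %in% table$label]
  empty <- setdiff(levels(table$label), present)
  if (length(empty) > 0L) {
    warning(sprintf("empty group(s) omitted from summary: %s",
                    paste(empty, collapse = ", ")))
  }
  out <- list()
  for (g in present) {
    sub <- table[table$label == g, FEATURE_COLS, drop = FALSE]
    n <- nrow(sub)
    sds <- if (n == 1L) {
      warning(sprintf("group %s has a single row; sd reported as 0", g))
      rep(0, length(FEATURE_COLS))
    } else {
      vapply(sub, stats::sd, numeric(1))
    }
    out[[g]] <- data.frame(label = g, feature = FEATURE_COLS, n = n,
                           mean = vapply(sub, mean, numeric(1)),
                           sd = sds, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with mid-ranks and a chi-square upper-tail
#' p-value on g-1 degrees of freedom (via [stats::kruskal.test()]). For small
#' pooled samples an exhaustive-permutation p-value is available with
#' `exact = TRUE` (all distinct assignments of the pooled values to the group
#' sizes are enumerated when feasible, otherwise Monte Carlo resampling is
#' used).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, total
#'   n >= 3).
#' @param exact Compute a permutation p-value instead of the chi-square
#'   approximation.
#' @param n_resample Resample count when the exact enumeration is infeasible.
#' @return List of class `kw_result` with `H`, `df`, `p`, `tie_corrected`,
#'   `degenerate`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE, n_resample = 10000) {
  if (!is.list(groups) || length(groups) < 2L) {
    usage_error("kruskal_wallis needs a list of at least two groups")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) usage_error("total sample size must be at least 3")
  g <- factor(rep(seq_along(groups), lengths(groups)))

  if (length(unique(values)) == 1L) {
    warning("all values identical across groups; H = 0, p = 1 (degenerate)")
    return(structure(list(H = 0, df = length(groups) - 1L, p = 1,
                          tie_corrected = TRUE, degenerate = TRUE),
                     class = "kw_result"))
  }

  kt <- stats::kruskal.test(values, g)
  H <- unname(kt$statistic)
  p <- unname(kt$p.value)

  if (exact) {
    p <- kw_permutation_p(values, lengths(groups), H, n_resample)
  }
  structure(list(H = H, df = unname(kt$parameter), p = p,
                 tie_corrected = anyDuplicated(values) > 0L,
                 degenerate = FALSE),
            class = "kw_result")
}

# Permutation p-value: exhaustive over all assignments of pooled indices to
# group sizes when the count is small, Monte Carlo otherwise.
kw_permutation_p <- function(values, sizes, H_obs, n_resample) {
  n <- length(values)
  n_assign <- round(exp(lgamma(n + 1) - sum(lgamma(sizes + 1))))
  stat <- function(idx_groups) {
    g <- factor(rep(seq_along(sizes), sizes))
    unname(stats::kruskal.test(values[idx_groups], g)$statistic)
  }
  tol <- 1e-9
  if (n_assign <= 20000) {
    perms <- enumerate_assignments(n, sizes)
    stats_all <- vapply(perms, stat, numeric(1))
    mean(stats_all >= H_obs - tol)
  } else {
    hits <- 0L
    for (i in seq_len(n_resample)) {
      if (stat(sample.int(n)) >= H_obs - tol) hits <- hits + 1L
    }
    (hits + 1) / (n_resample + 1)
  }
}

# All ordered partitions of 1..n into consecutive groups of the given sizes
# (as index vectors concatenating the groups).
enumerate_assignments <- function(n, sizes) {
  rec <- function(avail, sizes) {
    if (length(sizes) == 0L) return(list(integer(0)))
    if (length(sizes) == 1L) return(list(avail))
    picks <- utils::combn(avail, sizes[1L], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- rec(setdiff(avail, p), sizes[-1L])
      out <- c(out, lapply(rest, function(r) c(p, r)))
    }
    out
  }
  rec(seq_len(n), sizes)
}

#' PCA with variance-based component retention
#'
#' Columns are centred (and scaled to unit variance when `standardize`).
#' Components are covariance eigenvectors sorted by decreasing eigenvalue;
#' the smallest number of components reaching `var_retained` of the total
#' variance is retained. Sign convention: the largest-magnitude loading of
#' each component is positive.
#'
#' @param x Numeric matrix (rows = observations, >= 2; all finite).
#' @param var_retained Fraction of variance to retain (default 0.99).
#' @param standardize Scale columns to unit variance before rotation.
#' @return List of class `reflex_pca` with `scores` (retained components),
#'   `loadings`, `explained`, `k`, `center`, `scale`.
#' @export
pca_fit_transform <- function(x, var_retained = 0.99, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) usage_error("PCA needs at least 2 rows")
  if (!all(is.finite(x))) usage_error("PCA input must be finite")
  sds <- apply(x, 2L, stats::sd)
  if (standardize && any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    zero_variance_error(sprintf(
      "zero-variance column(s) cannot be standardized: %s",
      paste(bad, collapse = ", ")))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  k <- which(cumsum(explained) >= var_retained - 1e-12)[1L]
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(
    list(scores = pc$x[, seq_len(k), drop = FALSE], loadings = rot,
         explained = explained, k = k, center = pc$center,
         scale = if (standardize) pc$scale else NULL),
    class = "reflex_pca")
}

# Project new rows into an existing PCA fit (used fold-wise in LOO CV so test
# rows never influence the rotation).
pca_apply <- function(fit, newx) {
  newx <- as.matrix(newx)
  z <- sweep(newx, 2L, fit$center)
  if (!is.null(fit$scale)) z <- sweep(z, 2L, fit$scale, "/")
  (z %*% fit$loadings)[, seq_len(fit$k), drop = FALSE]
}
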