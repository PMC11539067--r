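#' Fisher permutation test for a two-group difference
#'
#' Permutes group labels \code{n_resamples} times (or resamples with
#' replacement when \code{replace = TRUE}) and compares the absolute
#' observed statistic with the permutation distribution. The two-sided
#' p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{|T^*| \ge |T_{obs}|\})/(1 + B)}, which never returns 0
#' and is bounded below by \eqn{1/(B+1)}. The default statistic is the
#' difference of group medians; difference of means is available and much
#' faster for large resample counts.
#'
#' @param x,y Numeric samples (non-empty).
#' @param statistic \code{"median_diff"} or \code{"mean_diff"}.
#' @param n_resamples Number of label permutations (default 200000).
#' @param seed Integer seed; \code{NULL} leaves the RNG state alone.
#' @param replace Resample labels with replacement (bootstrap variant)
#'   instead of permuting without replacement.
#' @return A \code{permutation_result}: \code{statistic_observed},
#'   \code{p_value}, \code{n_resamples}, \code{statistic}, \code{seed}.
#' @export
permutation_test <- function(x, y, statistic = c("median_diff", "mean_diff"),
                             n_resamples = 200000, seed = NULL,
                             replace = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(length(x) > 0, length(y) > 0)
  if (n_resamples < 1000)
    warning("fewer than 1000 resamples: p-value resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  nx <- length(x); ny <- length(y)
  comb <- c(x, y)
  n <- nx + ny
  obs <- if (statistic == "median_diff") {
    stats::median(x) - stats::median(y)
  } else {
    mean(x) - mean(y)
  }
  if (statistic == "mean_diff" && !replace) {
    tot <- sum(comb)
    stat_star <- vapply(seq_len(n_resamples), function(b) {
      sx <- sum(comb[sample.int(n, nx)])
      sx / nx - (tot - sx) / ny
    }, numeric(1))
  } else if (statistic == "mean_diff") {
    stat_star <- vapply(seq_len(n_resamples), function(b) {
      mean(comb[sample.int(n, nx, replace = TRUE)]) -
        mean(comb[sample.int(n, ny, replace = TRUE)])
    }, numeric(1))
  } else {
    stat_star <- vapply(seq_len(n_resamples), function(b) {
      if (replace) {
        stats::median(comb[sample.int(n, nx, replace = TRUE)]) -
          stats::median(comb[sample.int(n, ny, replace = TRUE)])
      } else {
        idx <- sample.int(n, nx)
        stats::median(comb[idx]) - stats::median(comb[-idx])
      }
    }, numeric(1))
  }
  # tolerance guards ties at |obs| against summation-order round-off
  eps <- 1e-9 * max(abs(obs), max(abs(stat_star)), 1e-300)
  p <- (1 + sum(abs(stat_star) >= abs(obs) - eps)) / (1 + n_resamples)
  structure(list(statistic_observed = obs, p_value = p,
                 n_resamples = n_resamples, statistic = statistic,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %d resamples): T = %.4g, p = %.4g\n",
              x$statistic, x$n_resamples, x$statistic_observed, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values, monotone in sorted order and capped at 1.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test; exact null distribution for small samples
#' without ties, normal approximation with tie correction otherwise.
#' Completely tied data (all values equal) returns p = 1 with a flag rather
#' than an error.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List: \code{p_value}, \code{statistic} (rank-sum W),
#'   \code{all_tied} flag.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1)
    return(list(p_value = 1, statistic = NA_real_, all_tied = TRUE))
  exact <- min(length(x), length(y)) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       all_tied = FALSE)
}

#' Percentile-bootstrap confidence band for a cross-individual median series
#'
#' Per time point, the median across individuals plus a percentile bootstrap
#' interval obtained by resampling individuals (rows) with replacement.
#'
#' @param series Matrix [individual, time].
#' @param level Confidence level in percent.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return List: \code{median}, \code{lower}, \code{upper} (vectors over
#'   time).
#' @export
bootstrap_median_band <- function(series, level = 95, n_boot = 1000,
                                  seed = 1) {
  series <- as.matrix(series)
  n <- nrow(series)
  stopifnot(n >= 1, level > 0, level < 100)
  set.seed(seed)
  med <- apply(series, 2, stats::median, na.rm = TRUE)
  alpha <- (100 - level) / 200
  boot_meds <- matrix(NA_real_, n_boot, ncol(series))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_meds[b, ] <- apply(series[idx, , drop = FALSE], 2, stats::median,
                            na.rm = TRUE)
  }
  list(median = med,
       lower = apply(boot_meds, 2, stats::quantile, probs = alpha,
                     na.rm = TRUE, names = FALSE),
       upper = apply(boot_meds, 2, stats::quantile, probs = 1 - alpha,
                     na.rm = TRUE, names = FALSE))
}

#' Group-wise permutation tests on a tidy feature table
#'
#' Runs [permutation_test()] for every feature against a two-level group
#' column and applies [bh_fdr()] across features.
#'
#' @param table data.frame with group, value and feature columns.
#' @param group_col,value_col,feature_col Column names.
#' @param ... Passed to [permutation_test()].
#' @return data.frame: feature, statistic_observed, p_value, p_adjusted.
#' @export
feature_permutation_table <- function(table, group_col = "genotype",
                                      value_col = "value",
                                      feature_col = "feature", ...) {
  groups <- unique(table[[group_col]])
  stopifnot(length(groups) == 2)
  feats <- unique(table[[feature_col]])
  res <- lapply(feats, function(f) {
    sub <- table[table[[feature_col]] == f, ]
    pt <- permutation_test(sub[[value_col]][sub[[group_col]] == groups[1]],
                           sub[[value_col]][sub[[group_col]] == groups[2]],
                           ...)
    data.frame(feature = f, statistic_observed = pt$statistic_observed,
               p_value = pt$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_fdr(out$p_value)
  out
}
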