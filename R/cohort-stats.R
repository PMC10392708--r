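group_test <- function(statistic, p, method, pairwise = NULL) {
  structure(list(statistic = statistic, p = p, method = method,
                 pairwise = pairwise), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g\n", x$method,
              x$statistic, x$p))
  if (!is.null(x$pairwise)) {
    cat("pairwise comparisons (adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

# log multivariate hypergeometric probability constant and per-table part
table_logprob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# Enumerate sum(lgamma(cell+1)) over every RxC table in the fiber with
# the given margins (recursion over rows; within a row over cells).
fiber_cellsums <- function(rs, cs) {
  R <- length(rs); C <- length(cs)
  acc <- new.env(parent = emptyenv())
  acc$v <- numeric(0)
  row_rec <- function(i, cols_left, run) {
    if (i == R) {
      acc$v <- c(acc$v, run + sum(lgamma(cols_left + 1)))
      return(invisible())
    }
    cell_rec <- function(j, t, cl, run2) {
      if (j == C) {
        if (t <= cl[C])
          row_rec(i + 1, {cl[C] <- cl[C] - t; cl},
                  run2 + lgamma(t + 1))
        return(invisible())
      }
      rest_cap <- sum(cl[(j + 1):C])
      lo <- max(0L, t - rest_cap)
      hi <- min(t, cl[j])
      if (lo > hi) return(invisible())
      for (x in lo:hi) {
        cl2 <- cl; cl2[j] <- cl2[j] - x
        cell_rec(j + 1, t - x, cl2, run2 + lgamma(x + 1))
      }
    }
    cell_rec(1L, rs[i], cols_left, run)
  }
  row_rec(1L, cs, 0)
  acc$v
}

#' Exact Fisher test for an RxC contingency table
#'
#' Exact two-sided p-value under the fixed-margins multivariate
#' hypergeometric null, using the probability-mass rule: the p-value is
#' the total null probability of all tables in the margin fiber whose
#' probability does not exceed the observed table's (within a relative
#' tolerance of 1e-7). For 2x2 tables this is the usual two-sided Fisher
#' exact test. The fiber is enumerated in full; for large tables a
#' Monte-Carlo estimate over `mc` sampled tables ([stats::r2dtable()])
#' can be requested instead.
#'
#' @param counts matrix of nonnegative integer counts, at least 2x2.
#' @param budget maximum table total for full enumeration (default
#'   10000); exceeding it without `mc` is an error.
#' @param mc if non-NULL, number of Monte-Carlo tables for the sampled
#'   estimate `(1 + #extreme) / (mc + 1)`.
#' @return A `group_test` with `method = "fisher"`; `statistic` is the
#'   observed table probability.
#' @examples
#' fisher_exact(matrix(c(26, 0, 17, 8), 2, byrow = TRUE))$p  # ~0.002
#' @export
fisher_exact <- function(counts, budget = 10000, mc = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stopf("table must be at least 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  N <- sum(counts)
  if (N == 0) stopf("table total must be positive")
  rs <- rowSums(counts); cs <- colSums(counts)
  logp_obs <- table_logprob(counts)
  if (!is.null(mc)) {
    tabs <- stats::r2dtable(mc, rs, cs)
    lp <- vapply(tabs, table_logprob, numeric(1))
    extreme <- sum(lp <= logp_obs + log1p(1e-7))
    p <- (1 + extreme) / (mc + 1)
  } else {
    if (N > budget)
      stopf(paste("table total %d exceeds the enumeration budget %d;",
                  "use `mc` for a Monte-Carlo estimate"), N, budget)
    const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
    lp <- const - fiber_cellsums(rs, cs)
    p <- min(1, sum(exp(lp[lp <= logp_obs + log1p(1e-7)])))
  }
  group_test(statistic = exp(logp_obs), p = p, method = "fisher")
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test with midranks for ties, tie-corrected
#' variance, and (by default) a 0.5 continuity correction — the form
#' used for continuous cohort variables.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param correct apply the continuity correction.
#' @return A `group_test` with `method = "wilcoxon"`.
#' @export
wilcoxon_rank_sum <- function(x, y, correct = TRUE) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    warnf("all values tied across both samples; p = 1")
    return(group_test(statistic = length(x) * length(y) / 2, p = 1,
                      method = "wilcoxon"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = correct))
  group_test(statistic = unname(wt$statistic), p = wt$p.value,
             method = "wilcoxon")
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups list of non-empty numeric vectors.
#' @return A `group_test` with `method = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(!lengths(groups))) stopf("groups must be non-empty")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1)
    return(group_test(statistic = 0, p = 1, method = "kruskal_wallis"))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(vals, g)
  group_test(statistic = unname(kt$statistic), p = kt$p.value,
             method = "kruskal_wallis")
}

#' Dunn post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics from mean-rank differences with the
#' tie-corrected pooled variance
#' `sigma^2 = N(N+1)/12 - T/(12(N-1))`, `T = sum(t^3 - t)` over tie
#' groups; two-sided p-values Bonferroni-adjusted over all
#' `k(k-1)/2` pairs.
#'
#' @param groups list of non-empty numeric vectors (named, optionally).
#' @return A `group_test` with `method = "dunn"`, `statistic` the
#'   omnibus Kruskal-Wallis H, and a `pairwise` data.frame with columns
#'   `pair`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups) {
  if (length(groups) < 3) stopf("Dunn post-hoc needs at least 3 groups")
  if (any(!lengths(groups))) stopf("groups must be non-empty")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  omni <- kruskal_wallis(groups)
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  g <- rep(names(groups), lengths(groups))
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- lengths(groups)
  ties <- table(vals)
  Tcorr <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  combs <- utils::combn(names(groups), 2)
  npairs <- ncol(combs)
  pw <- data.frame(pair = paste(combs[1, ], combs[2, ], sep = " vs "),
                   z = NA_real_, p = NA_real_, p_adjusted = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(npairs)) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt(sigma2 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    pw$z[i] <- z
    pw$p[i] <- 2 * stats::pnorm(-abs(z))
  }
  pw$p_adjusted <- pmin(1, pw$p * npairs)
  group_test(statistic = omni$statistic, p = omni$p, method = "dunn",
             pairwise = pw)
}

#' Median and interquartile range
#'
#' Median and quartiles by linear interpolation of order statistics
#' (quantile type 7).
#'
#' @param x non-empty numeric vector.
#' @return Named vector `median`, `q1`, `q3`.
#' @export
summarize_median_iqr <- function(x) {
  if (!length(x)) stopf("input must be non-empty")
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Group comparisons of scores against clinical variables
#'
#' For one score vector and one clinical grouping: a Wilcoxon rank-sum
#' test for two-level groupings, or Kruskal-Wallis with Dunn post-hoc
#' comparisons for three or more levels.
#'
#' @param score named numeric per-sample score.
#' @param grouping factor/character grouping aligned with `score`.
#' @return A `group_test`.
#' @export
score_by_group <- function(score, grouping) {
  grouping <- as.factor(as.character(grouping))
  gl <- split(score, grouping)
  gl <- gl[lengths(gl) > 0]
  if (length(gl) < 2) stopf("grouping must have at least 2 levels")
  if (length(gl) == 2) wilcoxon_rank_sum(gl[[1]], gl[[2]])
  else dunn_posthoc(gl)
}
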