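# Independent oracles used across tests. These re-derive expected values
# from first principles and must stay independent of the package code
# paths they check.

# Efron-approximation Cox log partial likelihood for a single covariate.
efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    ed <- exp(beta * x[D])
    er <- exp(beta * x[R])
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum(er) - (l / d) * sum(ed))
  }
  ll
}

# Two-stage grid maximizer of the Efron partial likelihood.
efron_grid_beta <- function(time, status, x) {
  coarse <- seq(-4, 4, by = 0.01)
  ll <- vapply(coarse, efron_loglik, numeric(1), time, status, x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, efron_loglik, numeric(1), time, status, x)
  fine[which.max(llf)]
}

# Direct Benjamini-Yekutieli formula: step-up with harmonic inflation.
by_direct <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Hand product-limit table: S(t) multiplied by (1 - d/n) at event times.
km_oracle <- function(time, status) {
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & status == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Brute-force hypergeometric upper tail P(X >= k) by pmf enumeration.
hyper_tail_oracle <- function(k, N, K, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Small helper: a normalized expr_matrix built directly from a matrix.
norm_mat <- function(values, probe_class = "endogenous", panel = "p") {
  expr_matrix(values, probe_class, panel_id = panel, scale = "normalized")
}

# A small cohort config used throughout the synth tests.
tiny_config <- function(seed = 1, ...) {
  args <- list(n_samples = 30, n_endog_a = 60, n_hk_a = 6, n_endog_b = 60,
               n_hk_b = 6, n_common = 45, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

# Run normalize -> merge -> log2 on a synthetic cohort.
merged_log2_of <- function(cohort, min_refs = 3) {
  na <- suppressWarnings(tilscore:::normalize_panel(cohort$panel_a,
                                                    min_refs = min_refs))
  nb <- suppressWarnings(tilscore:::normalize_panel(cohort$panel_b,
                                                    min_refs = min_refs))
  log2_transform(suppressWarnings(merge_panels(na, nb)))
}
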