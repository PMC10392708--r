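#' Kaplan-Meier (product-limit) survival estimate
#'
#' Wraps [survival::survfit()] on an intercept-only model: at each
#' distinct event time, survival is multiplied by `1 - d / n_at_risk`,
#' with individuals censored at t still counted at risk at t.
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return A data.frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   covering every distinct observed time.
#' @export
km_estimate <- function(times, events) {
  if (!length(times) || any(times <= 0)) stopf("times must be positive")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with the hypergeometric variance at
#' each distinct event time, referred to chi-square with 1 df
#' ([survival::survdiff()]).
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param group two-level group labels.
#' @return A `group_test` with `method = "logrank"` and the chi-square
#'   statistic.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stopf("log-rank test needs exactly 2 groups")
  if (min(table(group)) == 0) stopf("both groups must be non-empty")
  if (sum(events) == 0) {
    warnf("no events observed; log-rank p = 1")
    return(group_test(statistic = 0, p = 1, method = "logrank"))
  }
  sd <- survival::survdiff(
    survival::Surv(times, events) ~ group,
    data = data.frame(times = times, events = events, group = group))
  group_test(statistic = unname(sd$chisq),
             p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
             method = "logrank")
}

#' Optimal dichotomization cutoff by the Youden index
#'
#' Scans every midpoint between consecutive sorted distinct marker
#' values as a candidate cutoff, evaluates the Youden index
#' `J = sensitivity + specificity - 1` for both orientations (events
#' enriched above or below the cutoff), and returns the cutoff
#' maximizing J; ties are broken toward the lowest cutoff. Censored
#' observations enter as non-events via the 0/1 `event` indicator.
#'
#' @param marker per-sample numeric marker (>= 2 distinct values).
#' @param event 0/1 class indicator (event observed during follow-up);
#'   both classes must be present.
#' @return A list of class `cutpoint_result`: `cutoff`, `direction`
#'   (`"high"` or `"low"`: which side is event-enriched), `j_statistic`,
#'   and `groups` (per-sample `"high"`/`"low"`, value > cutoff = high).
#' @export
youden_cutpoint <- function(marker, event) {
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  if (length(marker) != length(event)) stopf("length mismatch")
  if (!any(event == 1) || !any(event == 0))
    stopf("both classes must be present")
  v <- sort(unique(marker))
  if (length(v) < 2) stopf("marker has a single distinct value")
  cand <- (v[-length(v)] + v[-1]) / 2
  pos <- event == 1
  # J for orientation "high side predicts event"; the other orientation
  # is its negation
  j_high <- vapply(cand, function(cc) {
    sens <- mean(marker[pos] > cc)
    spec <- mean(marker[!pos] <= cc)
    sens + spec - 1
  }, numeric(1))
  j_best <- pmax(j_high, -j_high)
  best <- which(j_best >= max(j_best) - 1e-12)[1]  # lowest cutoff wins
  direction <- if (j_high[best] >= -j_high[best]) "high" else "low"
  structure(list(cutoff = cand[best], direction = direction,
                 j_statistic = j_best[best],
                 groups = ifelse(marker > cand[best], "high", "low")),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Youden cutpoint %.4g (J = %.3f), event-enriched side: %s\n",
              x$cutoff, x$j_statistic, x$direction))
  invisible(x)
}

#' Dichotomize a marker by Youden or median cutoff
#'
#' `method = "youden"` uses [youden_cutpoint()] against the event
#' indicator; `method = "median"` labels values at or below the sample
#' median `"low"` and the rest `"high"`. A split leaving either group
#' empty is an error.
#'
#' @param marker per-sample numeric marker.
#' @param method `"youden"` or `"median"`.
#' @param event 0/1 indicator (required for `"youden"`).
#' @return Character vector of `"high"`/`"low"` labels with attribute
#'   `cutoff`.
#' @export
dichotomize <- function(marker, method = c("youden", "median"),
                        event = NULL) {
  method <- match.arg(method)
  if (method == "youden") {
    if (is.null(event)) stopf("youden dichotomization needs `event`")
    cp <- youden_cutpoint(marker, event)
    g <- cp$groups
    cut <- cp$cutoff
  } else {
    if (length(marker) < 2) stopf("median split needs at least 2 values")
    cut <- stats::median(marker)
    g <- ifelse(marker > cut, "high", "low")
  }
  if (length(unique(g)) < 2)
    stopf("degenerate split: one group is empty")
  attr(g, "cutoff") <- cut
  g
}

#' Univariate Cox proportional hazards fit
#'
#' Maximum partial likelihood with the Efron tie approximation
#' ([survival::coxph()]); the p-value is the two-sided Wald test.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (at least one event).
#' @param covariate non-constant numeric covariate.
#' @return A list `beta`, `hr` (`exp(beta)`), `se`, `p`.
#' @export
cox_univariate <- function(times, events, covariate) {
  if (length(unique(covariate)) == 1) stopf("covariate is constant")
  if (sum(events) < 1) stopf("at least one event is required")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        stopf("Cox partial likelihood is monotone (divergent fit): %s",
              conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)$coefficients
  list(beta = unname(s[1, "coef"]), hr = unname(s[1, "exp(coef)"]),
       se = unname(s[1, "se(coef)"]), p = unname(s[1, "Pr(>|z|)"]))
}

#' Three-way survival evaluation of one marker
#'
#' Mirrors the per-marker survival report: the marker is analyzed (i) as
#' a continuous covariate in a univariate Cox model, (ii) dichotomized
#' at the sample median, and (iii) dichotomized at the Youden-index
#' cutoff, with a log-rank test for each split.
#'
#' @param marker named per-sample numeric marker (e.g. a relative cell
#'   score or a gene's log2 expression).
#' @param times,events follow-up times and 0/1 indicators aligned with
#'   `marker`.
#' @param name marker name for the report row.
#' @return One-row data.frame: `marker`, `cox_beta`, `cox_hr`, `cox_p`,
#'   `median_cutoff`, `median_logrank_chi2`, `median_logrank_p`,
#'   `youden_cutoff`, `youden_j`, `youden_logrank_chi2`,
#'   `youden_logrank_p`, `n_high_youden`, `n_low_youden`.
#' @export
survival_report_row <- function(marker, times, events, name = "marker") {
  cx <- tryCatch(cox_univariate(times, events, marker),
                 error = function(e) list(beta = NA, hr = NA, se = NA,
                                          p = NA))
  med <- tryCatch({
    g <- dichotomize(marker, "median")
    lr <- logrank_test(times, events, g)
    list(cut = attr(g, "cutoff"), chi2 = lr$statistic, p = lr$p)
  }, error = function(e) list(cut = NA, chi2 = NA, p = NA))
  ycp <- tryCatch({
    g <- dichotomize(marker, "youden", event = events)
    lr <- logrank_test(times, events, g)
    list(cut = attr(g, "cutoff"),
         j = youden_cutpoint(marker, events)$j_statistic,
         chi2 = lr$statistic, p = lr$p,
         n_high = sum(g == "high"), n_low = sum(g == "low"))
  }, error = function(e) list(cut = NA, j = NA, chi2 = NA, p = NA,
                              n_high = NA, n_low = NA))
  data.frame(marker = name, cox_beta = cx$beta, cox_hr = cx$hr,
             cox_p = cx$p, median_cutoff = med$cut,
             median_logrank_chi2 = med$chi2, median_logrank_p = med$p,
             youden_cutoff = ycp$cut, youden_j = ycp$j,
             youden_logrank_chi2 = ycp$chi2, youden_logrank_p = ycp$p,
             n_high_youden = ycp$n_high, n_low_youden = ycp$n_low,
             stringsAsFactors = FALSE)
}
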