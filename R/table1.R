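#' Published cohort contingency counts
#'
#' Loads the contingency counts of the study cohort's summary table
#' (26 AA vs 25 CA radical-prostatectomy patients: age group, PSA group,
#' Gleason score, grade group, BCR and metastasis status), shipped as
#' plain-text package data.
#'
#' @return Named list of integer matrices (levels x race).
#' @export
cohort_table1 <- function() {
  path <- system.file("extdata", "cohort_table1.csv", package = "tilscore")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "integer", "integer"))
  lapply(split(df, factor(df$variable, unique(df$variable))), function(d) {
    m <- as.matrix(d[, c("AA", "CA")])
    rownames(m) <- d$level
    m
  })
}

#' Fisher exact p-values for the cohort summary table
#'
#' Recomputes the two-sided Fisher exact p-value of every categorical
#' row block of [cohort_table1()] with [fisher_exact()].
#'
#' @return Named numeric vector of p-values.
#' @export
table1_fisher <- function() {
  vapply(cohort_table1(), function(tab) fisher_exact(tab)$p, numeric(1))
}
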