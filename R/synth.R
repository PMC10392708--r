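#' TIL component cell types
#'
#' The five cell types whose raw scores are averaged into the total
#' tumor-infiltrating lymphocyte (TIL) composite score.
#' @export
TIL_COMPONENTS <- c("B cells", "T cells", "CD45", "macrophages",
                    "cytotoxic cells")

default_cell_types <- function() {
  c(TIL_COMPONENTS, "DC", "mast cells", "NK cells", "CD8 T cells",
    "exhausted CD8", "Treg", "Th1", "neutrophils")
}

#' Configuration for the synthetic two-panel cohort generator
#'
#' Describes a cohort emulating a two-panel targeted immune expression
#' study: two overlapping probe panels with housekeeping genes,
#' marker-gene blocks driven by latent per-sample cell-type abundances,
#' per-sample library size factors, overdispersed count noise, simple
#' clinicopathologic covariates, and exponential survival endpoints whose
#' hazards depend on chosen relative cell scores.
#'
#' The defaults mirror a cohort of 51 radical-prostatectomy specimens run
#' on a 770-gene and a 730-gene immune panel (10 and 40 reference genes
#' respectively) with 13 profiled cell types, and plant a single survival
#' effect: a log-hazard coefficient of -1 linking the mast-cell-vs-TIL
#' relative score to the metastasis endpoint, the association the scoring
#' pipeline is designed to detect.
#'
#' @param n_samples number of samples.
#' @param n_endog_a,n_endog_b endogenous gene counts of panels A and B.
#' @param n_hk_a,n_hk_b housekeeping gene counts per panel.
#' @param n_common number of endogenous probes shared by both panels;
#'   must not exceed `min(n_endog_a, n_endog_b)`.
#' @param cell_types character vector of profiled cell types; must
#'   contain the five [TIL_COMPONENTS].
#' @param markers_per_type markers assigned per cell type (>= 2).
#' @param abundance_sd SD (log2 scale) of the latent per-sample cell-type
#'   abundances around 0.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param bio_sd SD (log2 scale) of per-gene, per-sample biological
#'   variability of background endogenous genes (marker genes vary
#'   through their cell type's abundance instead; housekeeping genes are
#'   stable by construction).
#' @param hk_dispersion overdispersion of housekeeping-gene counts;
#'   kept at technical-noise level since reference genes are selected
#'   for stability.
#' @param size_factor_sd SD (log2 scale) of per-sample library factors.
#' @param effect_map list of planted survival effects, each a list with
#'   `score` ("numerator|denominator", denominator `"TIL"` or a cell
#'   type), `coef` (log-hazard per unit of centered latent score), and
#'   `endpoint` ("bcr" or "metastasis").
#' @param censor_rate target fraction of censored observations in [0, 1).
#' @param baseline_hazard baseline event rate per month (> 0).
#' @param covariate_probs named list of category probabilities for race,
#'   age_group, psa_group, gleason, grade_group (defaults emulate a
#'   51-patient prostate cohort).
#' @param seed master seed; each generation step uses an independent
#'   substream derived from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 51,
                         n_endog_a = 770, n_hk_a = 10,
                         n_endog_b = 730, n_hk_b = 40,
                         n_common = 300,
                         cell_types = default_cell_types(),
                         markers_per_type = 3,
                         abundance_sd = 1,
                         dispersion = 0.1,
                         bio_sd = 0.8,
                         hk_dispersion = 0.01,
                         size_factor_sd = 0.25,
                         effect_map = list(list(score = "mast cells|TIL",
                                                coef = -1,
                                                endpoint = "metastasis")),
                         censor_rate = 0.3,
                         baseline_hazard = 0.01,
                         covariate_probs = NULL,
                         seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_endog_a = as.integer(n_endog_a),
              n_hk_a = as.integer(n_hk_a),
              n_endog_b = as.integer(n_endog_b),
              n_hk_b = as.integer(n_hk_b),
              n_common = as.integer(n_common),
              cell_types = cell_types,
              markers_per_type = as.integer(markers_per_type),
              abundance_sd = abundance_sd,
              dispersion = dispersion,
              bio_sd = bio_sd,
              hk_dispersion = hk_dispersion,
              size_factor_sd = size_factor_sd,
              effect_map = effect_map,
              censor_rate = censor_rate,
              baseline_hazard = baseline_hazard,
              covariate_probs = covariate_probs %||% list(
                race = c(AA = 26 / 51, CA = 25 / 51),
                age_group = c("40s" = 6, "50s" = 17, "60s" = 23,
                              "70s" = 5) / 51,
                psa_group = c("1" = 8, "2" = 26, "3" = 17) / 51,
                gleason = c("6" = 14, "7" = 19, "8" = 5, "9-10" = 13) / 51,
                grade_group = c(low = 33, high = 18) / 51),
              seed = as.integer(seed))
  if (cfg$n_samples < 1) stopf("n_samples must be positive")
  if (cfg$n_common > min(cfg$n_endog_a, cfg$n_endog_b))
    stopf("n_common exceeds the smaller panel's endogenous gene count")
  if (cfg$n_common < 1) stopf("panels must share at least one probe")
  if (cfg$markers_per_type < 2)
    stopf("markers_per_type must be at least 2")
  if (anyDuplicated(cfg$cell_types)) stopf("cell_types must be unique")
  if (!all(TIL_COMPONENTS %in% cfg$cell_types))
    stopf("cell_types must include all five TIL components")
  if (cfg$abundance_sd < 0 || cfg$dispersion < 0 ||
      cfg$size_factor_sd < 0 || cfg$bio_sd < 0 || cfg$hk_dispersion < 0)
    stopf("rates and SDs must be nonnegative")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stopf("censor_rate must be in [0, 1)")
  if (cfg$baseline_hazard <= 0)
    stopf("baseline_hazard must be positive")
  for (ef in cfg$effect_map) {
    if (!all(c("score", "coef", "endpoint") %in% names(ef)))
      stopf("each effect needs score, coef, endpoint")
    if (!ef$endpoint %in% c("bcr", "metastasis"))
      stopf("effect endpoint must be 'bcr' or 'metastasis'")
    parse_score_name(ef$score, cfg$cell_types)  # validates
  }
  structure(cfg, class = "synth_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_score_name <- function(score, cell_types) {
  parts <- strsplit(score, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stopf("effect score '%s' must be 'numerator|denominator'", score)
  if (!parts[1] %in% cell_types)
    stopf("unknown cell type '%s' in effect score", parts[1])
  if (!(parts[2] == "TIL" || parts[2] %in% cell_types))
    stopf("denominator '%s' must be 'TIL' or a cell type", parts[2])
  parts
}

# Deterministic gene-name universe: shared probes first, then each
# panel's unique endogenous genes, then panel-specific housekeeping.
synth_gene_names <- function(cfg) {
  common <- sprintf("CMN%04d", seq_len(cfg$n_common))
  ua <- if (cfg$n_endog_a > cfg$n_common)
    sprintf("UA%04d", seq_len(cfg$n_endog_a - cfg$n_common)) else character()
  ub <- if (cfg$n_endog_b > cfg$n_common)
    sprintf("UB%04d", seq_len(cfg$n_endog_b - cfg$n_common)) else character()
  list(common = common, unique_a = ua, unique_b = ub,
       hk_a = sprintf("HKA%02d", seq_len(cfg$n_hk_a)),
       hk_b = sprintf("HKB%02d", seq_len(cfg$n_hk_b)),
       endog_a = c(common, ua), endog_b = c(common, ub),
       endog_all = c(common, ua, ub))
}

#' Generate a marker map for a synthetic cohort
#'
#' Assigns `markers_per_type` endogenous genes to each configured cell
#' type, deterministically and disjointly, drawing first from probes
#' shared by both panels (so scores survive the merge) and then from
#' panel-unique genes. Remaining endogenous genes are unassigned
#' background.
#'
#' @param config a [synth_config()].
#' @return A data.frame with columns `cell_type` and `gene`.
#' @export
generate_marker_map <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nm <- synth_gene_names(config)
  need <- config$markers_per_type * length(config$cell_types)
  if (need > length(nm$endog_all))
    stopf("marker capacity exceeded: need %d genes, have %d endogenous",
          need, length(nm$endog_all))
  genes <- nm$endog_all[seq_len(need)]
  data.frame(
    cell_type = rep(config$cell_types, each = config$markers_per_type),
    gene = genes, stringsAsFactors = FALSE)
}

marker_list <- function(map) split(map$gene, map$cell_type)

# Latent relative score used to plant survival effects: the cell type's
# latent log2 abundance minus the TIL (or denominator type) latent mean,
# centered across samples.
latent_score <- function(abundance, score, cell_types) {
  parts <- parse_score_name(score, cell_types)
  den <- if (parts[2] == "TIL") {
    colMeans(abundance[TIL_COMPONENTS, , drop = FALSE])
  } else abundance[parts[2], ]
  s <- abundance[parts[1], ] - den
  s - mean(s)
}

#' Generate two-panel synthetic counts with known ground truth
#'
#' Draws latent per-sample cell-type abundances (log2 scale), per-sample
#' library size factors, and per-gene baseline expression levels, then
#' simulates overdispersed counts for both panels around
#' `mean = baseline * 2^abundance * size_factor` (abundance enters only
#' for marker genes of the corresponding cell type). Background
#' endogenous genes carry per-gene, per-sample biological variability
#' (`bio_sd`, log2 scale) instead; housekeeping genes are
#' abundance-independent and drawn with technical-level overdispersion
#' (`hk_dispersion`). Shared probes have the same generative mean in
#' both panels but independent count noise.
#'
#' @param config a [synth_config()].
#' @param map marker map from [generate_marker_map()].
#' @return A list with `panel_a` and `panel_b` ([expr_matrix()] raw
#'   counts) and `truth`, a list holding the latent `abundance`
#'   (cell type x sample), `size_factors`, per-gene `baseline` means,
#'   planted `true_coefficients` and `true_cutpoints` (the median of each
#'   planted latent score).
#' @export
generate_counts <- function(config, map = generate_marker_map(config)) {
  stopifnot(inherits(config, "synth_config"))
  nm <- synth_gene_names(config)
  S <- config$n_samples
  samples <- sprintf("S%03d", seq_len(S))
  with_substream(config$seed, "counts", {
    abundance <- matrix(
      stats::rnorm(length(config$cell_types) * S, 0, config$abundance_sd),
      nrow = length(config$cell_types),
      dimnames = list(config$cell_types, samples))
    size_factors <- 2^stats::rnorm(S, 0, config$size_factor_sd)
    names(size_factors) <- samples
    all_genes <- c(nm$endog_all, nm$hk_a, nm$hk_b)
    baseline <- stats::rlnorm(length(all_genes), log(150), 1)
    names(baseline) <- all_genes
    baseline[c(nm$hk_a, nm$hk_b)] <-
      stats::rlnorm(config$n_hk_a + config$n_hk_b, log(400), 0.5)

    gene2type <- structure(map$cell_type, names = map$gene)
    # biological variability of background endogenous genes, drawn once
    # so shared probes have the same generative mean in both panels
    background <- setdiff(nm$endog_all, names(gene2type))
    bio <- matrix(2^stats::rnorm(length(background) * S, 0, config$bio_sd),
                  nrow = length(background),
                  dimnames = list(background, samples))
    mean_for <- function(genes) {
      mu <- outer(baseline[genes], size_factors)
      mk <- genes %in% names(gene2type)
      if (any(mk)) {
        amp <- 2^abundance[gene2type[genes[mk]], , drop = FALSE]
        mu[mk, ] <- mu[mk, , drop = FALSE] * amp
      }
      bg <- genes %in% background
      if (any(bg))
        mu[bg, ] <- mu[bg, , drop = FALSE] * bio[genes[bg], , drop = FALSE]
      mu
    }
    draw <- function(mu, disp) {
      n <- length(mu)
      cnt <- if (disp <= 1e-12) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / disp)
      matrix(cnt, nrow = nrow(mu), dimnames = dimnames(mu))
    }
    draw_panel <- function(endog, hk) {
      rbind(draw(mean_for(endog), config$dispersion),
            draw(mean_for(hk), config$hk_dispersion))
    }
    panel_a <- expr_matrix(
      draw_panel(nm$endog_a, nm$hk_a),
      probe_class = rep(c("endogenous", "housekeeping"),
                        c(length(nm$endog_a), config$n_hk_a)),
      panel_id = "panel_a", scale = "raw_counts")
    panel_b <- expr_matrix(
      draw_panel(nm$endog_b, nm$hk_b),
      probe_class = rep(c("endogenous", "housekeeping"),
                        c(length(nm$endog_b), config$n_hk_b)),
      panel_id = "panel_b", scale = "raw_counts")

    cuts <- vapply(config$effect_map, function(ef)
      stats::median(latent_score(abundance, ef$score, config$cell_types)),
      numeric(1))
    names(cuts) <- vapply(config$effect_map, `[[`, "", "score")
    coefs <- vapply(config$effect_map, `[[`, numeric(1), "coef")
    names(coefs) <- names(cuts)
    list(panel_a = panel_a, panel_b = panel_b,
         truth = list(abundance = abundance, size_factors = size_factors,
                      baseline = baseline, true_cutpoints = cuts,
                      true_coefficients = coefs))
  })
}

#' Generate clinical covariates and survival endpoints
#'
#' Samples clinicopathologic covariates from the configured categorical
#' distributions (independently of expression), then draws event times
#' for the BCR and metastasis endpoints from an exponential model with
#' `log hazard = log(baseline_hazard) + sum(coef * latent score)` over
#' the planted effects of that endpoint. Censoring is independent
#' exponential, with its rate calibrated by root finding so the expected
#' censored fraction equals `censor_rate`.
#'
#' @param truth ground-truth list from [generate_counts()].
#' @param config the matching [synth_config()].
#' @return A data.frame with sample id, covariates, and
#'   `time_bcr`/`event_bcr`, `time_metastasis`/`event_metastasis`
#'   (times in months).
#' @export
generate_clinical <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  A <- truth$abundance
  S <- ncol(A)
  if (S != config$n_samples) stopf("truth dimensions do not match config")
  samples <- colnames(A)
  with_substream(config$seed, "clinical", {
    cp <- config$covariate_probs
    draw_cat <- function(p) factor(
      sample(names(p), S, replace = TRUE, prob = p), levels = names(p))
    cl <- data.frame(sample = samples,
                     race = draw_cat(cp$race),
                     age_group = draw_cat(cp$age_group),
                     psa_group = draw_cat(cp$psa_group),
                     gleason = draw_cat(cp$gleason),
                     grade_group = draw_cat(cp$grade_group),
                     stringsAsFactors = FALSE)
    for (ep in c("bcr", "metastasis")) {
      lp <- rep(0, S)
      for (ef in config$effect_map) {
        if (ef$endpoint != ep) next
        lp <- lp + ef$coef * latent_score(A, ef$score, config$cell_types)
      }
      hz <- config$baseline_hazard * exp(lp)
      t_event <- stats::rexp(S, hz)
      if (config$censor_rate > 0) {
        # exponential censoring rate r with mean_s r/(r+h_s) = target
        f <- function(r) mean(r / (r + hz)) - config$censor_rate
        r <- stats::uniroot(f, c(1e-12, 1e6 * max(hz)))$root
        t_cens <- stats::rexp(S, r)
      } else t_cens <- rep(Inf, S)
      cl[[paste0("time_", ep)]] <- pmin(t_event, t_cens)
      cl[[paste0("event_", ep)]] <- as.integer(t_event <= t_cens)
    }
    cl
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_marker_map()],
#' [generate_counts()] and [generate_clinical()] under one config.
#'
#' @param config a [synth_config()].
#' @return A list with `marker_map`, `panel_a`, `panel_b`, `clinical`,
#'   `truth`, and the `config`.
#' @export
synth_cohort <- function(config = synth_config()) {
  map <- generate_marker_map(config)
  cnt <- generate_counts(config, map)
  clinical <- generate_clinical(cnt$truth, config)
  list(marker_map = map, panel_a = cnt$panel_a, panel_b = cnt$panel_b,
       clinical = clinical, truth = cnt$truth, config = config)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes panel counts as the CSV dialect of [write_expr_csv()], the
#' marker map as two-column TSV, the clinical table as CSV, and the
#' latent truth (abundance, size factors) as CSV.
#'
#' @param cohort result of [synth_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synth_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expr_csv(cohort$panel_a, file.path(dir, "panel_a_counts.csv"))
  write_expr_csv(cohort$panel_b, file.path(dir, "panel_b_counts.csv"))
  utils::write.table(cohort$marker_map, file.path(dir, "marker_map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  ab <- data.frame(cell_type = rownames(cohort$truth$abundance),
                   cohort$truth$abundance, check.names = FALSE)
  utils::write.csv(ab, file.path(dir, "truth_abundance.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(sample = names(cohort$truth$size_factors),
               size_factor = cohort$truth$size_factors),
    file.path(dir, "truth_size_factors.csv"), row.names = FALSE)
  invisible(dir)
}
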