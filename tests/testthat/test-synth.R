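test_that("config validation rejects impossible cohorts", {
  expect_error(synth_config(n_common = 800), "n_common")
  expect_error(synth_config(markers_per_type = 0), "markers_per_type")
  expect_error(synth_config(censor_rate = 1), "censor_rate")
  expect_error(synth_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(synth_config(cell_types = c("B cells", "B cells")),
               "unique|TIL")
  expect_error(synth_config(effect_map = list(
    list(score = "gremlins|TIL", coef = 1, endpoint = "bcr"))),
    "unknown cell type")
})

test_that("marker map assigns disjoint markers and leaves background", {
  cfg <- synth_config(n_endog_a = 770, n_endog_b = 730, n_common = 300)
  map <- generate_marker_map(cfg)
  expect_equal(nrow(map), 13 * 3)
  expect_false(anyDuplicated(map$gene) > 0)
  nm <- tilscore:::synth_gene_names(cfg)
  expect_true(all(map$gene %in% nm$endog_all))
  # 770 + 730 - 300 endogenous genes total, 39 assigned
  expect_equal(length(nm$endog_all) - nrow(map), 1200 - 39)
  # capacity error
  small <- tiny_config(n_endog_a = 20, n_endog_b = 20, n_common = 20)
  expect_error(generate_marker_map(small), "capacity")
})

test_that("same seed gives byte-identical cohorts, dims match config", {
  cfg <- tiny_config(seed = 7)
  a <- synth_cohort(cfg)
  b <- synth_cohort(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$panel_a$values), c(60 + 6, 30))
  expect_equal(dim(a$panel_b$values), c(60 + 6, 30))
  expect_equal(nrow(a$clinical), 30)
  expect_equal(dim(a$truth$abundance), c(13, 30))
  expect_true(all(a$truth$size_factors > 0))
  # different seed differs
  expect_false(identical(a$panel_a$values,
                         synth_cohort(tiny_config(seed = 8))$panel_a$values))
})

test_that("marker counts flatten in the noise-free limit", {
  cfg <- tiny_config(dispersion = 0, hk_dispersion = 0, size_factor_sd = 0,
                     abundance_sd = 0, bio_sd = 0)
  cnt <- generate_counts(cfg)
  map <- generate_marker_map(cfg)
  # equal abundances + no size factors: each marker gene's counts across
  # samples are iid Poisson around a common mean
  for (g in map$gene[c(1, 10, 20)]) {
    x <- cnt$panel_a$values[g, ]
    mu <- median(x)
    expect_true(all(abs(x - mu) <= 5 * sqrt(mu + 1)))
  }
})

test_that("counts track the stated generative mean", {
  cfg <- tiny_config(seed = 3, n_samples = 60)
  map <- generate_marker_map(cfg)
  cnt <- generate_counts(cfg, map)
  tr <- cnt$truth
  # marker genes: E[count] = baseline * 2^abundance * size_factor
  g2t <- structure(map$cell_type, names = map$gene)
  obs <- cnt$panel_a$values[map$gene, ]
  expected <- tr$baseline[map$gene] *
    2^tr$abundance[g2t[map$gene], ] *
    rep(tr$size_factors, each = nrow(map))
  ratio <- obs / expected
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se + 1e-3)
  # housekeeping genes: abundance-independent mean
  hk <- rownames(cnt$panel_a$values)[cnt$panel_a$probe_class ==
                                       "housekeeping"]
  obs_hk <- cnt$panel_a$values[hk, ]
  exp_hk <- tr$baseline[hk] %o% tr$size_factors
  r2 <- obs_hk / exp_hk
  expect_lt(abs(mean(r2) - 1), 3 * sd(r2) / sqrt(length(r2)) + 1e-3)
})

test_that("doubling a cell type's abundance doubles its marker means", {
  cfg <- tiny_config(dispersion = 0, hk_dispersion = 0, seed = 11,
                     n_samples = 200)
  map <- generate_marker_map(cfg)
  cnt <- generate_counts(cfg, map)
  mast_markers <- map$gene[map$cell_type == "mast cells"]
  a <- cnt$truth$abundance["mast cells", ]
  sf <- cnt$truth$size_factors
  # counts corrected for size factor and baseline should scale as 2^a
  for (g in mast_markers) {
    norm <- cnt$panel_a$values[g, ] / (sf * cnt$truth$baseline[g])
    fit <- lm(log2(norm + 1e-9) ~ a)
    expect_lt(abs(unname(coef(fit)[2]) - 1), 0.05)
  }
})

test_that("planted negative coefficient shortens low-score survival", {
  cfg <- tiny_config(n_samples = 300, seed = 5,
                     effect_map = list(list(score = "mast cells|TIL",
                                            coef = -1,
                                            endpoint = "metastasis")))
  cnt <- generate_counts(cfg)
  cl <- generate_clinical(cnt$truth, cfg)
  sc <- tilscore:::latent_score(cnt$truth$abundance, "mast cells|TIL",
                                cfg$cell_types)
  low <- sc < median(sc)
  expect_lt(mean(cl$time_metastasis[low]), mean(cl$time_metastasis[!low]))
  # bcr endpoint has no planted effect: times unrelated to the score
  expect_gt(cor.test(sc, cl$time_bcr, method = "spearman")$p.value, 0.001)
})

test_that("univariate Cox on the latent score recovers the coefficient", {
  cfg0 <- tiny_config(n_samples = 200, censor_rate = 0.3,
                      n_endog_a = 40, n_endog_b = 40, n_common = 40,
                      n_hk_a = 3, n_hk_b = 3)
  betas <- vapply(1:50, function(s) {
    cfg <- tiny_config(n_samples = 200, censor_rate = 0.3, seed = s,
                       n_endog_a = 40, n_endog_b = 40, n_common = 40,
                       n_hk_a = 3, n_hk_b = 3)
    cnt <- generate_counts(cfg)
    cl <- generate_clinical(cnt$truth, cfg)
    sc <- tilscore:::latent_score(cnt$truth$abundance, "mast cells|TIL",
                                  cfg$cell_types)
    cox_univariate(cl$time_metastasis, cl$event_metastasis, sc)$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - (-1)), 0.25)
  # censoring calibration: observed censor fraction near the target
  expect_lt(abs(mean(vapply(1:20, function(s) {
    cfg <- tiny_config(n_samples = 200, censor_rate = 0.3, seed = s,
                       n_endog_a = 40, n_endog_b = 40, n_common = 40,
                       n_hk_a = 3, n_hk_b = 3)
    cnt <- generate_counts(cfg)
    cl <- generate_clinical(cnt$truth, cfg)
    1 - mean(cl$event_metastasis)
  }, numeric(1))) - 0.3), 0.05)
})

test_that("null cohorts give uniform log-rank p-values", {
  ps <- vapply(1:200, function(s) {
    cfg <- tiny_config(n_samples = 80, effect_map = list(), seed = s,
                       n_endog_a = 40, n_endog_b = 40, n_common = 40,
                       n_hk_a = 3, n_hk_b = 3)
    cnt <- generate_counts(cfg)
    cl <- generate_clinical(cnt$truth, cfg)
    sc <- tilscore:::latent_score(cnt$truth$abundance, "mast cells|TIL",
                                  cfg$cell_types)
    g <- ifelse(sc > median(sc), "high", "low")
    logrank_test(cl$time_metastasis, cl$event_metastasis, g)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cohort files round-trip through the plain-text writers", {
  dir <- withr::local_tempdir()
  co <- synth_cohort(tiny_config(seed = 2))
  write_synth_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("panel_a_counts.csv", "panel_b_counts.csv",
                    "marker_map.tsv", "clinical.csv",
                    "truth_abundance.csv", "truth_size_factors.csv"))
  back <- read_expr_csv(file.path(dir, "panel_a_counts.csv"))
  expect_equal(back$values, co$panel_a$values)
  expect_equal(back$probe_class, co$panel_a$probe_class)
  expect_equal(back$panel_id, "panel_a")
})
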