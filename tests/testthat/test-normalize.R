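test_that("geNorm stability matches the pairwise-SD definition", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 3, 4, 5), g3 = c(1, 1, 1, 1))
  colnames(x) <- paste0("s", 1:4)
  gn <- genorm_stability(x)
  expect_equal(unname(gn$m_values[c("g1", "g2")]),
               rep(sd(c(0, 1, 2, 3)) / 2, 2), tolerance = 1e-12)
  expect_equal(unname(gn$m_values["g3"]), sd(c(0, 1, 2, 3)),
               tolerance = 1e-12)
  # g3 is least stable: eliminated first, so ranked last
  expect_equal(gn$ranking[3], "g3")
})

test_that("geNorm handles degenerate inputs per contract", {
  two <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_error(genorm_stability(two), "3 candidate")
  const <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), NULL))
  gn <- genorm_stability(const)
  expect_equal(unname(gn$m_values), rep(0, 4))
  expect_equal(gn$ranking, paste0("g", 1:4))  # input order on ties
})

test_that("geNorm M values match a brute-force all-pairs SD oracle", {
  set.seed(41)
  for (rep in 1:5) {
    K <- sample(3:10, 1); S <- sample(4:10, 1)
    x <- matrix(rnorm(K * S), K, S,
                dimnames = list(paste0("g", 1:K), paste0("s", 1:S)))
    m_oracle <- sapply(1:K, function(j)
      mean(sapply(setdiff(1:K, j), function(k) sd(x[j, ] - x[k, ]))))
    expect_equal(unname(genorm_stability(x)$m_values), m_oracle,
                 tolerance = 1e-12)
  }
})

test_that("geNorm selects a small stable set when one exists", {
  set.seed(42)
  s <- rnorm(12)                      # shared sample effect
  stable <- t(sapply(1:4, function(i) s + rnorm(12, sd = 0.02)))
  noisy <- t(sapply(1:4, function(i) s + rnorm(12, sd = 1.5)))
  x <- rbind(stable, noisy)
  rownames(x) <- c(paste0("hk", 1:4), paste0("bad", 1:4))
  colnames(x) <- paste0("s", 1:12)
  gn <- genorm_stability(x, min_refs = 3, v_threshold = 0.15)
  expect_true(all(gn$selected %in% paste0("hk", 1:4)))
  expect_gte(length(gn$selected), 3)
  expect_true(all(gn$m_values[paste0("hk", 1:4)] <
                    gn$m_values[paste0("bad", 1:4)]))
})

test_that("housekeeping normalization equalizes reference geomeans", {
  set.seed(9)
  vals <- matrix(rpois(20 * 6, 100), 20, 6,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  refs <- paste0("g", 1:4)
  em <- expr_matrix(vals, rep(c("housekeeping", "endogenous"), c(4, 16)))
  nn <- housekeeping_normalize(em, refs)
  f <- attr(nn, "size_factors")
  # brute-force recomputation of the factor formula
  gm <- apply(vals[refs, ] + 0.5, 2, function(x) exp(mean(log(x))))
  expect_equal(unname(f), unname(mean(gm) / gm), tolerance = 1e-12)
  expect_equal(nn$values, sweep(vals, 2, mean(gm) / gm, `*`),
               tolerance = 1e-12)
  expect_equal(nn$scale, "normalized")

  # equal reference geomeans: identity transform
  eq <- vals; eq[1:4, ] <- 50
  em_eq <- expr_matrix(eq, rep(c("housekeeping", "endogenous"), c(4, 16)))
  nn_eq <- housekeeping_normalize(em_eq, refs)
  expect_equal(nn_eq$values, eq, tolerance = 1e-12)

  # doubling one sample's references halves its factor
  dbl <- vals; dbl[1:4, 3] <- vals[1:4, 3] * 2
  em2 <- expr_matrix(dbl, rep(c("housekeeping", "endogenous"), c(4, 16)))
  f2 <- attr(housekeeping_normalize(em2, refs), "size_factors")
  gm2 <- apply(dbl[refs, ] + 0.5, 2, function(x) exp(mean(log(x))))
  expect_equal(unname(f2[3]), mean(gm2) / gm2[[3]], tolerance = 1e-12)
  expect_lt(f2[[3]], f[[3]])
})

test_that("normalization preserves within-sample ordering and flags QC", {
  set.seed(10)
  vals <- matrix(rpois(30 * 5, 80), 30, 5,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:5)))
  vals[1:3, 5] <- 0  # sample 5 loses its references
  em <- expr_matrix(vals, rep(c("housekeeping", "endogenous"), c(3, 27)))
  expect_warning(nn <- housekeeping_normalize(em, paste0("g", 1:3),
                                              qc_min = 20), "QC")
  expect_equal(attr(nn, "qc_excluded"), "s5")
  expect_equal(ncol(nn$values), 4)
  for (s in colnames(nn$values))
    expect_equal(order(nn$values[, s]), order(vals[, s]))
})

test_that("merging scales the second panel by the common-probe ratio", {
  vals1 <- matrix(c(100, 40, 80, 120, 60, 90), 3, 2,
                  dimnames = list(c("c1", "c2", "u1"), c("s1", "s2")))
  # second panel: common probes exactly double, one unique probe
  vals2 <- rbind(c1 = vals1["c1", ] * 2, c2 = vals1["c2", ] * 2,
                 u2 = c(50, 50))
  m <- merge_panels(norm_mat(vals1), norm_mat(vals2))
  expect_equal(attr(m, "merge_ratio"), 0.5, tolerance = 1e-12)
  # unique second-panel probes rescaled by r
  expect_equal(unname(m$values["u2", ]), c(25, 25), tolerance = 1e-12)
  # common probes averaged after rescaling: (x + 2x * 0.5)/2 = x
  expect_equal(m$values[c("c1", "c2"), ], vals1[c("c1", "c2"), ],
               tolerance = 1e-12)
  # merged gene set is the union
  expect_setequal(rownames(m$values), c("c1", "c2", "u1", "u2"))

  # explicit hand case: common probe (100, 200) -> merged 100
  a <- norm_mat(matrix(c(100, 10), 2, 1,
                       dimnames = list(c("c", "ua"), "s1")))
  b <- norm_mat(matrix(c(200, 50), 2, 1,
                       dimnames = list(c("c", "ub"), "s1")))
  mm <- merge_panels(a, b)
  expect_equal(unname(mm$values["c", 1]), 100, tolerance = 1e-12)
})

test_that("merging a panel with itself is the identity", {
  set.seed(12)
  vals <- matrix(rlnorm(40 * 8, 4, 1), 40, 8,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  em <- norm_mat(vals)
  m <- merge_panels(em, em)
  expect_equal(m$values[rownames(vals), colnames(vals)], vals,
               tolerance = 1e-9)
})

test_that("merge rejects invalid panel pairs", {
  a <- norm_mat(matrix(1:4, 2, 2, dimnames = list(c("a1", "a2"),
                                                  c("s1", "s2"))))
  b <- norm_mat(matrix(1:4, 2, 2, dimnames = list(c("b1", "b2"),
                                                  c("s1", "s2"))))
  expect_error(merge_panels(a, b), "common")
  d <- norm_mat(matrix(1:4, 2, 2, dimnames = list(c("a1", "a2"),
                                                  c("s3", "s4"))))
  expect_error(merge_panels(a, d), "sample")
  raw <- expr_matrix(matrix(1:4, 2, 2,
                            dimnames = list(c("a1", "a2"), c("s1", "s2"))),
                     "endogenous")
  expect_error(merge_panels(raw, a), "normalized")
})
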