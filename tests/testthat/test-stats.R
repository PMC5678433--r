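# Statistical layer: matching, ANCOVA, regression, exact tests.

test_that("perfect duplicates match at zero distance", {
  cases <- data.frame(subject_id = c("a1", "a2", "a3"),
                      ga_wk = c(38, 39, 40), pma_wk = c(39, 40, 41))
  pool <- data.frame(subject_id = c("b3", "b1", "b2", "b4"),
                     ga_wk = c(40, 38, 39, 35), pma_wk = c(41, 39, 40, 36))
  m <- match_controls(cases, pool)
  expect_equal(attr(m, "total_distance"), 0)
  expect_identical(m$control_id, c("b1", "b2", "b3"))
})

test_that("assignment equals the exhaustive optimum (5 cases, 7 candidates)", {
  set.seed(11)
  cases <- data.frame(subject_id = sprintf("c%d", 1:5),
                      ga_wk = runif(5, 36, 41), pma_wk = runif(5, 37, 42))
  pool <- data.frame(subject_id = sprintf("p%d", 1:7),
                     ga_wk = runif(7, 36, 41), pma_wk = runif(7, 37, 42))
  m <- match_controls(cases, pool)
  cost <- outer(1:5, 1:7, function(i, j) {
    sqrt((cases$ga_wk[i] - pool$ga_wk[j])^2 +
         (cases$pma_wk[i] - pool$pma_wk[j])^2)
  })
  bf <- brute_force_match(cost)
  expect_equal(attr(m, "total_distance"), bf$total, tolerance = 1e-12)
})

test_that("matching is invariant to a common scaling of both axes", {
  set.seed(3)
  cases <- data.frame(subject_id = sprintf("c%d", 1:4),
                      ga_wk = rnorm(4, 38), pma_wk = rnorm(4, 39))
  pool <- data.frame(subject_id = sprintf("p%d", 1:6),
                     ga_wk = rnorm(6, 38), pma_wk = rnorm(6, 39))
  m1 <- match_controls(cases, pool)
  cases2 <- transform(cases, ga_wk = 10 * ga_wk, pma_wk = 10 * pma_wk)
  pool2 <- transform(pool, ga_wk = 10 * ga_wk, pma_wk = 10 * pma_wk)
  m2 <- match_controls(cases2, pool2)
  expect_identical(m1$control_id, m2$control_id)
  expect_error(match_controls(pool, cases), "smaller")
})

test_that("matching equals brute force across random small pools", {
  set.seed(99)
  for (trial in 1:30) {
    m <- sample(3:8, 1)
    n <- sample(2:m, 1)
    cost <- matrix(runif(n * m), n, m)
    got <- sum(cost[cbind(seq_len(n), gyriflow:::solve_lap(cost))])
    expect_equal(got, brute_force_match(cost)$total, tolerance = 1e-12)
  }
})

test_that("ANCOVA recovers an injected group offset within its CI", {
  spec <- cohort_spec(n_per_group = 30, group_gmv_offset_ml = -27,
                      gmv_noise_sd_ml = 2, gmv_slope_per_cdo2 = 0, seed = 5)
  tab <- make_cohort(spec)
  res <- ancova_group_effect(tab, "gmv_ml")
  expect_lt(res$ci95[1], -27)
  expect_gt(res$ci95[2], -27)
  expect_equal(res$group_effect, -27, tolerance = 0.1)
  expect_lt(res$group_p, 0.001)  # direction: CHD minus control, negative
})

test_that("extra covariates without real effects leave the estimate alone", {
  spec <- cohort_spec(n_per_group = 30, group_gmv_offset_ml = -10, seed = 8)
  tab <- make_cohort(spec)
  tab$vent_days <- rep(c(0, 1, 2), length.out = nrow(tab))
  base <- ancova_group_effect(tab, "gmv_ml")
  extra <- ancova_group_effect(tab, "gmv_ml", extra_covariates = "vent_days")
  expect_equal(extra$group_effect, base$group_effect, tolerance = 0.2)
  expect_identical(extra$covariates, c("pma_wk", "vent_days"))
})

test_that("ANCOVA rejects singular designs and logs listwise deletion", {
  tab <- make_cohort(cohort_spec(n_per_group = 10, seed = 2))
  tab$pma_copy <- tab$pma_wk
  expect_error(ancova_group_effect(tab, "gmv_ml",
                                   covariates = c("pma_wk", "pma_copy")),
               "collinear")
  tab$gmv_ml[1:3] <- NA
  res <- ancova_group_effect(tab, "gmv_ml")
  expect_equal(res$n_dropped, 3)
  expect_error(ancova_group_effect(tab[1:12, ], "cdo2"), "at least 3")
})

test_that("linreg: exact line, permutation invariance, degenerate input", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  r <- suppressWarnings(linreg(d, "x", "y"))  # perfect fit by design
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  set.seed(4)
  d2 <- data.frame(x = rnorm(20), y = rnorm(20))
  r1 <- linreg(d2, "x", "y")
  r2 <- linreg(d2[sample(20), ], "x", "y")
  expect_equal(r1[c("slope", "intercept", "r_squared", "p")],
               r2[c("slope", "intercept", "r_squared", "p")])
  # internal cross-check: R^2 equals the squared Pearson correlation
  expect_equal(r1$r_squared, cor(d2$x, d2$y)^2)
  expect_error(linreg(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "zero variance")
})

test_that("Bonferroni threshold arithmetic and validation", {
  expect_identical(bonferroni_threshold(0.05, 4), 0.0125)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("Mann-Whitney exact p on separated samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)  # 2 * 1 / choose(6, 3)
  expect_identical(r$method, "exact")
  expect_equal(r$u, 0)
  # identical samples: symmetric distribution, p capped at 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_warning(r0 <- mann_whitney(rep(2, 4), rep(2, 5)), "tied")
  expect_equal(r0$p, 1)
})

test_that("exact branch agrees with wilcox.test on tie-free data", {
  set.seed(21)
  for (i in 1:10) {
    xs <- rnorm(sample(3:9, 1))
    ys <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    expect_equal(mann_whitney(xs, ys)$p,
                 wilcox.test(xs, ys, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("exact branch with ties agrees with direct enumeration", {
  set.seed(31)
  for (i in 1:6) {
    xs <- sample(1:4, 4, replace = TRUE)
    ys <- sample(1:4, 4, replace = TRUE)
    if (length(unique(c(xs, ys))) == 1) next
    r <- rank(c(xs, ys))
    n <- length(xs)
    subsets <- combn(length(r), n)
    sums <- colSums(matrix(r[subsets], nrow = n))
    w <- sum(r[seq_len(n)])
    p_enum <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
    expect_equal(mann_whitney(xs, ys)$p, p_enum, tolerance = 1e-12)
  }
})

test_that("exact and normal branches agree closely at n = 15 per group", {
  set.seed(41)
  for (i in 1:5) {
    xs <- rnorm(15)
    ys <- rnorm(15, 0.3)
    pe <- mann_whitney(xs, ys)$p                       # 225 <= 400: exact
    pn <- mann_whitney(xs, ys, exact_limit = 1)$p      # force approximation
    expect_identical(mann_whitney(xs, ys, exact_limit = 1)$method, "normal")
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("Fisher exact: printed sex table, null table, symmetry", {
  expect_equal(round(fisher_exact(16, 14, 8, 22), 2), 0.06)
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(16, 14, 8, 22), fisher_exact(22, 8, 14, 16))
  # independent check: sum of hypergeometric probabilities no larger than
  # the observed table's
  probs <- dhyper(0:24, 24, 36, 30)
  p_manual <- sum(probs[probs <= dhyper(16, 24, 36, 30) * (1 + 1e-7)])
  expect_equal(fisher_exact(16, 14, 8, 22), p_manual, tolerance = 1e-6)
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
})

test_that("repeatability reports the squared Pearson correlation", {
  x <- c(61, 64, 70, 72, 75, 68)
  expect_equal(suppressWarnings(repeatability(x, x))$r_squared, 1)
  set.seed(6)
  a <- rnorm(24)
  b <- a + rnorm(24)
  r <- repeatability(a, b)
  expect_equal(r$r_squared, cor(a, b)^2)
  # affine rescaling of either series leaves R^2 unchanged
  expect_equal(repeatability(2 * a + 3, b)$r_squared, r$r_squared)
  expect_error(repeatability(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("equal-variance noise gives repeatability near one half", {
  set.seed(7)
  r2 <- replicate(200, {
    a <- rnorm(24)
    repeatability(a, a + rnorm(24))$r_squared
  })
  expect_equal(mean(r2), 0.5, tolerance = 0.05)
})

test_that("all reported p-values live in [0, 1]", {
  set.seed(13)
  for (i in 1:20) {
    xs <- rnorm(sample(3:12, 1))
    ys <- rnorm(sample(3:12, 1))
    p <- mann_whitney(xs, ys)$p
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("exclusion accounting retains and reports correctly", {
  tab <- data.frame(subject_id = sprintf("s%02d", 1:33),
                    exclude_reason = c(rep("", 30), "stroke", "stroke",
                                       "undatable"))
  kept <- apply_exclusions(tab)
  acc <- attr(kept, "accounting")
  expect_equal(acc$recruited, 33)
  expect_equal(acc$retained, 30)
  expect_equal(unname(acc$excluded[c("stroke", "undatable")]), c(2L, 1L))
  expect_error(apply_exclusions(tab, "nope"), "no column")
})
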