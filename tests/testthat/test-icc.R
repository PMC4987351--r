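test_that("ICC(1,1) forced cases follow the mean-square decomposition", {
  r1 <- icc_one_way(rbind(c(1, 1), c(5, 5)))
  expect_equal(r1$icc, 1)
  expect_equal(r1$s_w, 0)

  r2 <- icc_one_way(rbind(c(0, 1), c(1, 0)))
  expect_equal(r2$icc, -1)
  expect_equal(r2$s_b, 0)
  expect_equal(r2$s_w, 0.5)
  expect_false(r2$reliable)

  expect_warning(r3 <- icc_one_way(matrix(2, 3, 2)), "identical")
  expect_equal(r3$icc, 1)
})

test_that("ICC matches the one-way ANOVA oracle on random matrices", {
  withr::with_seed(71, {
    for (i in 1:20) {
      m <- matrix(rnorm(40), 20, 2)
      expect_equal(icc_one_way(m)$icc, oracle_icc(m), tolerance = 1e-12)
    }
    m3 <- matrix(rnorm(30), 10, 3)
    expect_equal(icc_one_way(m3)$icc, oracle_icc(m3), tolerance = 1e-12)
  })
})

test_that("ICC is invariant to location/scale and monotone in noise", {
  m <- make_icc_matrix(15, 2, between_sd = 2, within_sd = 1, seed = 72)
  base <- icc_one_way(m)$icc
  expect_equal(icc_one_way(m + 10)$icc, base, tolerance = 1e-12)
  expect_equal(icc_one_way(m * 3.5)$icc, base, tolerance = 1e-12)

  iccs <- vapply(c(0.01, 0.5, 1.5, 4), function(noise) {
    icc_one_way(make_icc_matrix(30, 2, between_sd = 2, within_sd = noise,
                                seed = 73))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
  expect_gt(iccs[1], 0.99)
})

test_that("strong subject effects give small permutation p-values", {
  hits <- vapply(1:100, function(i) {
    m <- make_icc_matrix(20, 2, between_sd = 10, within_sd = 1,
                         seed = 9000 + i)
    res <- icc_permutation_p(m, seed = 100 + i)
    res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permutation p is calibrated under exchangeability", {
  ps <- vapply(1:200, function(i) {
    m <- make_icc_matrix(12, 2, between_sd = 0, within_sd = 1,
                         seed = 10000 + i)
    icc_permutation_p(m, seed = 200 + i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
})

test_that("sequential and fixed-budget estimates agree", {
  m <- make_icc_matrix(20, 2, between_sd = 10, within_sd = 1, seed = 74)
  seq_res <- icc_permutation_p(m, seed = 75)
  fix_res <- icc_permutation_p(m, mode = "fixed", n_fixed = 9999, seed = 76)
  expect_lt(abs(seq_res$p_value - fix_res$p_value), 0.02)
  expect_equal(seq_res$decision, "significant")
  expect_identical(fix_res$n_permutations_used, 9999L)

  # decisions agree across seeds on clearly null data too
  m0 <- make_icc_matrix(12, 2, between_sd = 0, within_sd = 1, seed = 77)
  decisions <- vapply(1:20, function(i) {
    icc_permutation_p(m0, seed = 300 + i)$decision
  }, character(1))
  expect_true(all(decisions == "not significant"))
})

test_that("the session-shuffling permutation unit is also supported", {
  m <- make_icc_matrix(15, 2, between_sd = 5, within_sd = 1, seed = 78)
  res <- icc_permutation_p(m, unit = "sessions", seed = 79)
  expect_lt(res$p_value, 0.05)
})

test_that("subgroup reliability collapses to the plain ICC at full size", {
  profs2 <- dplyr::bind_rows(
    make_cohort_profiles(12, n_nodes = 10, slopes = seq(-0.3, 0.3, length = 12),
                         noise_sd = 0.4, sessions = "ses1", seed = 81),
    make_cohort_profiles(12, n_nodes = 10, slopes = seq(-0.3, 0.3, length = 12),
                         noise_sd = 0.4, sessions = "ses2", seed = 82)
  )
  tab <- bootstrap_subgroup_reliability(profs2, "D", sizes = 12, seed = 83)
  expect_equal(nrow(tab), 1)
  # oracle: recompute by hand
  kap <- sapply(c("ses1", "ses2"), function(ses) {
    p <- profs2[profs2$session_id == ses, ]
    kt <- cohort_kappa(p, reference_profile(p, "D"), "D")
    kt$kappa[order(kt$subject_id)]
  })
  expect_equal(tab$icc, icc_one_way(kap)$icc, tolerance = 1e-12)
})

test_that("ICC spread narrows with subgroup size and runs are seeded", {
  profs2 <- dplyr::bind_rows(
    make_cohort_profiles(30, n_nodes = 10, slopes = rnorm(30, sd = 0.3),
                         noise_sd = 0.6, sessions = "ses1", seed = 84),
    make_cohort_profiles(30, n_nodes = 10, slopes = rnorm(30, sd = 0.3),
                         noise_sd = 0.6, sessions = "ses2", seed = 85)
  )
  tab <- bootstrap_subgroup_reliability(profs2, "D", sizes = c(8, 20),
                                        n_boot = 40, seed = 86)
  iqrs <- tapply(tab$icc, tab$size, IQR)
  expect_lt(iqrs[["20"]], iqrs[["8"]])
  tab2 <- bootstrap_subgroup_reliability(profs2, "D", sizes = c(8, 20),
                                         n_boot = 40, seed = 86)
  expect_identical(tab, tab2)
})

test_that("hemispheric symmetry tests behave at both extremes", {
  x <- c(0.1, -0.2, 0.05, 0.3, -0.1)
  res_same <- hemispheric_symmetry_test(x, x)
  expect_equal(res_same$p_value, 1)

  withr::with_seed(87, {
    calib <- vapply(1:50, function(i) {
      l <- rnorm(15); r <- rnorm(15)
      hemispheric_symmetry_test(l, r)$p_value > 0.05
    }, logical(1))
  })
  expect_gte(mean(calib), 0.9)

  withr::with_seed(88, {
    l <- rnorm(15) - 2; r <- rnorm(15)
  })
  expect_lt(hemispheric_symmetry_test(l, r)$p_value, 0.05)
  expect_equal(hemispheric_symmetry_test(x, x, paired = TRUE)$p_value, 1)
})
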