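test_that("exact rank-sum enumeration matches hand counting", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3)
  expect_true(res$exact)
  expect_lt(res$z, 0)

  # swapping groups flips z, keeps p
  res_sw <- wilcoxon_rank_sum(c(3, 4), c(1, 2))
  expect_equal(res_sw$z, -res$z)
  expect_equal(res_sw$p_value, res$p_value)

  # all tied: no evidence
  res_tied <- wilcoxon_rank_sum(rep(1, 4), rep(1, 5))
  expect_equal(res_tied$p_value, 1)
  expect_equal(res_tied$z, 0)
})

test_that("exact p-values agree with wilcox.test on tie-free samples", {
  withr::with_seed(91, {
    for (i in 1:10) {
      x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
      ours <- wilcoxon_rank_sum(x, y)
      theirs <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-12)
    }
  })
})

test_that("the normal approximation matches wilcox.test for larger samples", {
  withr::with_seed(92, {
    x <- rnorm(25); y <- rnorm(30) + 0.5
  })
  ours <- wilcoxon_rank_sum(x, y)
  theirs <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-10)
  expect_false(ours$exact)

  # large shifts are detected decisively
  withr::with_seed(93, {
    a <- rnorm(20); b <- rnorm(20) + 2
  })
  expect_lt(wilcoxon_rank_sum(a, b)$p_value, 0.001)
})

test_that("cross-cost comparison tables reduce to single rank-sum calls", {
  withr::with_seed(94, {
    kc <- tibble::tibble(metric = "D", cost = 0.2, kappa = rnorm(12))
    kp <- tibble::tibble(metric = "D", cost = 0.2, kappa = rnorm(12) - 0.3)
  })
  tab <- compare_kappa_across_costs(kc, kp)
  direct <- wilcoxon_rank_sum(kp$kappa, kc$kappa)
  expect_equal(tab$z, direct$z)
  expect_equal(tab$p_value, direct$p_value)
  expect_equal(tab$stars, signif_stars(direct$p_value))

  kp_bad <- tibble::tibble(metric = "D", cost = 0.3, kappa = rnorm(5))
  expect_error(compare_kappa_across_costs(kc, kp_bad, metrics = "D",
                                          costs = 0.2),
               "No kappa values")
})

test_that("significance stars follow the figure-legend thresholds", {
  expect_equal(signif_stars(c(0.2, 0.04, 0.009, 0.0005)),
               c("", "*", "**", "***"))
})

test_that("nodal difference maps apply the 1/N correction", {
  n_nodes <- 44
  expect_equal(round(1 / n_nodes, 3), 0.023)
  withr::with_seed(95, {
    ctl <- purrr::map_dfr(1:20, function(s) {
      tibble::tibble(subject_id = sprintf("c%d", s), node_id = 1:n_nodes,
                     metric = "D", value = rnorm(n_nodes))
    })
    pat_same <- purrr::map_dfr(1:20, function(s) {
      tibble::tibble(subject_id = sprintf("p%d", s), node_id = 1:n_nodes,
                     metric = "D", value = rnorm(n_nodes))
    })
  })
  res <- nodal_group_difference(ctl, ctl, "D")
  expect_equal(attr(res, "p_threshold"), 1 / 44)
  expect_equal(sum(res$significant), 0)

  # a single node shifted by 5 SD is always caught, with the smallest p
  hits <- vapply(1:20, function(i) {
    pat <- withr::with_seed(9600 + i, {
      purrr::map_dfr(1:20, function(s) {
        v <- rnorm(n_nodes)
        v[7] <- v[7] + 5
        tibble::tibble(subject_id = sprintf("p%d", s), node_id = 1:n_nodes,
                       metric = "D", value = v)
      })
    })
    r <- nodal_group_difference(ctl, pat, "D")
    r$significant[7] && which.min(r$p_value) == 7
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("bootstrap robustness nulls center on zero and count correctly", {
  profs <- purrr::map_dfr(1:30, function(s) {
    withr::with_seed(9700 + s, {
      tidyr::expand_grid(hemisphere = c("left", "right"),
                         node_id = 1:10) |>
        dplyr::mutate(subject_id = sprintf("s%02d", s), metric = "D",
                      value = rep(seq(2, 11), 2) + rnorm(20, sd = 1))
    })
  })
  regions <- make_parcellation(10, n_midline = 0)
  # remap node ids onto the two-hemisphere template
  profs <- profs |>
    dplyr::mutate(node_id = ifelse(.data$hemisphere == "right",
                                   .data$node_id + 10L, .data$node_id))
  res <- bootstrap_robustness(profs, "D", observed_z = NULL,
                              design = "pooled", n_iter = 200,
                              n_ref = 12, n_test_right = 6, n_test_left = 4,
                              regions = regions, seed = 97)
  expect_equal(nrow(res$null_z), 200)
  expect_lt(abs(mean(res$null_z$z)), 0.15)

  # counting conventions
  res2 <- bootstrap_robustness(profs, "D", observed_z = median(res$null_z$z),
                               design = "pooled", n_iter = 200,
                               n_ref = 12, n_test_right = 6, n_test_left = 4,
                               regions = regions, seed = 97)
  expect_lt(abs(res2$p_raw[["pooled"]] - 0.5), 0.06)
  res3 <- bootstrap_robustness(profs, "D",
                               observed_z = min(res$null_z$z) - 1,
                               design = "pooled", n_iter = 100,
                               n_ref = 12, n_test_right = 6, n_test_left = 4,
                               regions = regions, seed = 97)
  expect_equal(res3$p_raw[["pooled"]], 0)
  expect_lte(res3$p_plus1[["pooled"]], 1 / 100 + 1e-12)

  # determinism and the per-side design
  res4 <- bootstrap_robustness(profs, "D", design = "per-side", n_iter = 50,
                               n_ref = 12, n_test_right = 6, n_test_left = 4,
                               regions = regions, seed = 98)
  res5 <- bootstrap_robustness(profs, "D", design = "per-side", n_iter = 50,
                               n_ref = 12, n_test_right = 6, n_test_left = 4,
                               regions = regions, seed = 98)
  expect_identical(res4$null_z, res5$null_z)
  expect_setequal(unique(res4$null_z$contrast), c("left", "right"))
})
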