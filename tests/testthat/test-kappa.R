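ref_from <- function(values, node_id = seq_along(values)) {
  profs <- dplyr::bind_rows(
    tibble::tibble(subject_id = "a", node_id = node_id, metric = "D",
                   value = values),
    tibble::tibble(subject_id = "b", node_id = node_id, metric = "D",
                   value = values)
  )
  reference_profile(profs, "D")
}

test_that("reference profiles are nodewise means", {
  profs <- dplyr::bind_rows(
    tibble::tibble(subject_id = "a", node_id = 1:3, metric = "D",
                   value = c(1, 2, 3)),
    tibble::tibble(subject_id = "b", node_id = 1:3, metric = "D",
                   value = c(3, 2, 1))
  )
  ref <- reference_profile(profs, "D")
  expect_equal(ref$value, c(2, 2, 2))
  # a repeated identical profile averages to itself
  ref2 <- ref_from(c(5, 1, 4))
  expect_equal(ref2$value, c(5, 1, 4))
})

test_that("left-right pooling of a symmetric cohort equals one hemisphere", {
  regions <- make_parcellation(4, n_midline = 0)
  base <- c(3, 7, 1, 5)
  profs <- tidyr::expand_grid(subject_id = c("a", "b"),
                              hemisphere = c("left", "right")) |>
    dplyr::mutate(data = purrr::map2(subject_id, hemisphere, function(s, h) {
      ids <- regions$region_id[regions$hemisphere == h]
      tibble::tibble(node_id = ids, metric = "D",
                     value = base + (s == "b"))
    })) |>
    tidyr::unnest("data")
  pooled <- reference_profile(profs, "D", pooling = "left-right-mean",
                              regions = regions)
  left_only <- reference_profile(profs[profs$hemisphere == "left", ], "D")
  expect_equal(pooled$value, left_only$value)
})

test_that("kappa identities hold exactly", {
  ref <- ref_from(c(2, 4, 6, 8, 10, 3, 7))
  # subject identical to the reference: horizontal scatter
  expect_equal(kappa_index(ref$value, ref)$kappa, 0)
  # uniformly inflated subject: slope recovers the inflation exactly
  for (a in c(-0.5, 0.2, 1.5)) {
    k <- kappa_index((1 + a) * ref$value, ref)
    expect_equal(k$kappa, a, tolerance = 1e-12)
    expect_equal(k$intercept, 0, tolerance = 1e-12)
  }
  # constant subject: difference is c - ref, slope -1
  k_const <- kappa_index(rep(4.2, nrow(ref)), ref)
  expect_equal(k_const$kappa, -1, tolerance = 1e-12)
  # adding a constant to the subject leaves the slope unchanged
  withr::with_seed(61, subj <- ref$value + rnorm(nrow(ref)))
  expect_equal(kappa_index(subj + 100, ref)$kappa,
               kappa_index(subj, ref)$kappa, tolerance = 1e-12)
})

test_that("scaling a proportional subject maps kappa as s(1 + k) - 1", {
  ref <- ref_from(c(1, 3, 5, 9, 2))
  k0 <- 0.4
  for (s in c(0.5, 2, 3)) {
    k <- kappa_index(s * (1 + k0) * ref$value, ref)$kappa
    expect_equal(k, s * (1 + k0) - 1, tolerance = 1e-12)
  }
})

test_that("reference members' kappas average to zero", {
  withr::with_seed(62, {
    profs <- make_cohort_profiles(10, n_nodes = 12,
                                  slopes = rnorm(10, sd = 0.2),
                                  noise_sd = 0.5)
  })
  ref <- reference_profile(profs, "D")
  kt <- cohort_kappa(profs, ref, "D")
  expect_equal(mean(kt$kappa), 0, tolerance = 1e-12)
})

test_that("cohort kappa recovers per-subject scaling factors", {
  slopes <- c(-0.4, -0.1, 0, 0.25, 0.5)
  profs <- make_cohort_profiles(5, n_nodes = 20, slopes = slopes)
  base_ref <- ref_from(seq_len(20) + 2, node_id = 1:20)
  kt <- cohort_kappa(profs, base_ref, "D")
  expect_equal(sort(kt$kappa), sort(slopes), tolerance = 1e-10)
})

test_that("constant references are rejected", {
  expect_error(kappa_index(c(1, 2, 3), ref_from(c(4, 4, 4))),
               "constant")
})

test_that("leave-one-out references exclude the subject", {
  profs <- make_cohort_profiles(4, n_nodes = 8,
                                slopes = c(0, 0.1, 0.2, 0.3))
  kt_loo <- cohort_kappa(profs, metric = "D", leave_one_out = TRUE)
  kt_all <- cohort_kappa(profs, metric = "D")
  # excluding yourself moves kappa away from the all-subject value
  expect_true(all(abs(kt_loo$kappa) >= abs(kt_all$kappa) - 1e-12))
  expect_gt(max(abs(kt_loo$kappa - kt_all$kappa)), 1e-6)
})

test_that("tidy, glance and autoplot expose the fit", {
  ref <- ref_from(c(2, 4, 6, 8))
  k <- kappa_index(c(3, 5, 8, 9), ref)
  td <- tidy(k)
  expect_equal(td$term, c("intercept", "kappa"))
  gl <- glance(k)
  expect_equal(gl$kappa, k$kappa)
  expect_s3_class(autoplot(k), "ggplot")
})

test_that("profiles with a planted slope are recovered", {
  ref <- ref_from(c(4, 1, 7, 3, 9, 6))
  p0 <- make_profile_with_slope(ref, a = 0.3)
  expect_equal(kappa_index(p0, ref)$kappa, 0.3, tolerance = 1e-12)

  # noisy profiles: OLS slope is unbiased
  kappas <- vapply(1:500, function(i) {
    p <- make_profile_with_slope(ref, a = 0.3, noise_sd = 0.5,
                                 seed = 7000 + i)
    kappa_index(p, ref)$kappa
  }, numeric(1))
  se <- sd(kappas) / sqrt(length(kappas))
  expect_lt(abs(mean(kappas) - 0.3), 2 * se + 1e-3)

  # null slope centers at zero
  kappas0 <- vapply(1:200, function(i) {
    p <- make_profile_with_slope(ref, a = 0, noise_sd = 0.5, seed = 8000 + i)
    kappa_index(p, ref)$kappa
  }, numeric(1))
  expect_lt(abs(mean(kappas0)), 3 * sd(kappas0) / sqrt(200) + 1e-3)
})
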