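test_that("hub covariances place hubs at elevated correlation and stay PSD", {
  spec0 <- cohort_spec(hub_fraction = 0, n_nodes = 12)
  cov0 <- make_hub_covariance(spec0)
  off <- cov0[upper.tri(cov0)]
  expect_true(all(off == spec0$base_corr))

  spec <- cohort_spec(n_nodes = 30)
  cov <- make_hub_covariance(spec)
  hubs <- attr(cov, "hubs")
  expect_equal(length(hubs), round(0.2 * 30))
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)

  # noiseless graph at 20% cost ranks hubs in the top degree quantile
  g <- threshold_to_cost(corr_matrix(cov), 0.2)
  deg <- node_degree(g)
  expect_gte(min(deg[hubs]), quantile(deg, 0.75))
})

test_that("hub disruption attenuates hub degree monotonically", {
  spec <- cohort_spec(n_nodes = 30)
  cov <- make_hub_covariance(spec)
  hubs <- attr(cov, "hubs")
  expect_equal(apply_hub_disruption(cov, 0), cov, ignore_attr = TRUE)

  cov_flat <- apply_hub_disruption(cov, 1)
  hub_offdiag <- cov_flat[hubs, -hubs]
  expect_equal(max(abs(hub_offdiag - spec$base_corr)), 0, tolerance = 1e-8)

  # heterogeneous correlations (pure two-level targets tie whole degree
  # blocks at a fixed cost, hiding the gradient)
  withr::with_seed(31, {
    w <- stats::cov2cor(crossprod(matrix(rnorm(30 * 36), 36, 30)))
  })
  blend <- 0.8 * cov + 0.2 * (w + t(w)) / 2
  diag(blend) <- 1
  blend <- structure((blend + t(blend)) / 2, hubs = hubs,
                     base_corr = spec$base_corr)
  mean_hub_deg <- vapply(c(0, 0.5, 1), function(g) {
    bg <- threshold_to_cost(corr_matrix(apply_hub_disruption(blend, g)), 0.2)
    mean(node_degree(bg)[hubs])
  }, numeric(1))
  expect_true(all(diff(mean_hub_deg) < 0))
})

test_that("periphery boost raises non-hub correlations", {
  spec <- cohort_spec(n_nodes = 20)
  cov <- make_hub_covariance(spec)
  boosted <- apply_hub_disruption(cov, 0.5, periphery_boost = 0.1)
  periph <- setdiff(seq_len(20), attr(cov, "hubs"))
  expect_gt(mean(boosted[periph, periph][upper.tri(diag(length(periph)))]),
            mean(cov[periph, periph][upper.tri(diag(length(periph)))]))
})

test_that("simulated subjects match the target covariance at large T", {
  spec <- cohort_spec(n_nodes = 15)
  cov <- make_hub_covariance(spec)
  ts <- simulate_subject(cov, n_timepoints = 10000, tr = 2, ar1 = 0,
                         noise_sd = 0, seed = 101)
  emp <- stats::cor(t(ts$data))
  off <- upper.tri(cov)
  expect_lt(mean(abs(emp[off] - cov[off])), 0.03)
  expect_lt(abs(mean(emp[off]) - mean(cov[off])), 0.03)

  # determinism and the short-series guard
  ts2 <- simulate_subject(cov, n_timepoints = 10000, tr = 2, ar1 = 0,
                          noise_sd = 0, seed = 101)
  expect_identical(ts$data, ts2$data)
  expect_error(simulate_subject(cov, n_timepoints = 32, tr = 2), ">= 64")
})

test_that("AR(1) series keep unit variance and the requested memory", {
  spec <- cohort_spec(n_nodes = 2, base_corr = 0, hub_fraction = 0)
  cov <- make_hub_covariance(spec)
  ts <- simulate_subject(cov, n_timepoints = 20000, tr = 2, ar1 = 0.6,
                         noise_sd = 0, seed = 102)
  x <- ts$data[1, ]
  expect_lt(abs(var(x) - 1), 0.1)
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.6), 0.05)
})

test_that("cohorts are reproducible and carry a truthful manifest", {
  spec <- cohort_spec(n_controls = 3, n_patients = 3, n_nodes = 10,
                      n_timepoints = 64, n_sessions = 2, seed = 103)
  co <- simulate_cohort(spec)
  expect_equal(length(co$series), 3 * 2 * 2 * 2)
  expect_equal(sum(co$manifest$disrupted), 3 * 2)  # one hemisphere per patient-session
  # disrupted hemispheres are exactly the patients' contralesional ones
  dis <- co$manifest[co$manifest$disrupted, ]
  expect_true(all(dis$group == "patient"))
  expect_true(all(dis$hemisphere == dis$contralesional_side))
  expect_true(all(dis$hemisphere != dis$lesion_side))

  co2 <- simulate_cohort(spec)
  expect_identical(co$series[[1]]$data, co2$series[[1]]$data)
  expect_identical(co$manifest, co2$manifest)

  # manifest survives a TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(co$manifest, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(co$manifest))
})

test_that("same-subject sessions give near-zero kappa on average", {
  spec <- cohort_spec(n_controls = 8, n_patients = 0, n_nodes = 16,
                      n_timepoints = 256, n_sessions = 2, seed = 104)
  co <- simulate_cohort(spec)
  prof <- cohort_profiles(co, costs = 0.2)
  left <- prof[prof$hemisphere == "left", ]
  s2 <- left[left$session_id == "ses2", ]
  ref2 <- reference_profile(s2, "D")
  k1 <- cohort_kappa(left[left$session_id == "ses1", ], ref2, "D")
  expect_lt(abs(mean(k1$kappa)), 0.1)
})
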