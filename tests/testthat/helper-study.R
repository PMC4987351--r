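# Full-pipeline replicates at the default study conditions: simulate a
# cohort (one session, as in the clinical arm), run time series -> wavelet
# correlation -> fixed-cost graphs -> nodal metrics, then compare patient
# and control kappa distributions.

simulate_study_profiles <- function(seed, gamma, costs) {
  spec <- cohort_spec(n_sessions = 1, disruption_gamma = gamma, seed = seed)
  co <- simulate_cohort(spec)
  prof <- cohort_profiles(co, costs = costs)
  list(regions = co$regions,
       controls = prof[prof$group == "control", ],
       patients = prof[prof$group == "patient" & prof$disrupted, ])
}

# The clinical pooled design: patient contralesional hemisphere vs controls'
# left/right-mean profiles, both against the pooled control reference.
run_kappa_study <- function(seed, gamma, costs = 0.2, metrics = "D") {
  st <- simulate_study_profiles(seed, gamma, costs)
  ctl <- st$controls; pat <- st$patients
  kc_all <- list(); kp_all <- list()
  for (m in metrics) {
    for (cst in costs) {
      ref <- reference_profile(ctl[ctl$cost == cst, ], m,
                               pooling = "left-right-mean",
                               regions = st$regions)
      pooled_ctl <- ctl[ctl$cost == cst, ] |>
        dplyr::filter(.data$metric == m) |>
        dplyr::mutate(node_id = pair_key(.data$node_id, st$regions)) |>
        dplyr::group_by(.data$subject_id, .data$node_id) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
        dplyr::mutate(metric = m, session_id = "ses1",
                      hemisphere = "pooled", cost = cst)
      kc_all[[paste(m, cst)]] <- cohort_kappa(pooled_ctl, ref, m)
      kp_all[[paste(m, cst)]] <- cohort_kappa(pat[pat$cost == cst, ], ref, m)
    }
  }
  kc <- dplyr::bind_rows(kc_all)
  kp <- dplyr::bind_rows(kp_all)
  list(controls = kc, patients = kp,
       comparison = compare_kappa_across_costs(kc, kp, metrics = metrics,
                                               costs = costs))
}

# Null-calibration unit: simulate one gamma = 0 cohort (all 40 subjects
# healthy), score every subject's requested hemisphere against the joint
# leave-one-out reference, and compare the (arbitrary) patient/control
# labels. With each subject excluded from its own reference the subjects are
# exchangeable, so the comparison is exactly level; scoring an external
# group against a *fixed* reference group instead absorbs the reference
# group's sampling fluctuation, which is what bootstrap_robustness nulls.
run_null_calibration_cell <- function(seed, metric, cost, side) {
  spec <- cohort_spec(n_sessions = 1, disruption_gamma = 0, seed = seed)
  co <- simulate_cohort(spec)
  prof <- cohort_profiles(co, costs = cost)
  sub <- prof[prof$hemisphere == side, ]
  kt <- cohort_kappa(sub, metric = metric, leave_one_out = TRUE)
  grp <- co$manifest$group[match(kt$subject_id, co$manifest$subject_id)]
  wilcoxon_rank_sum(kt$kappa[grp == "patient"],
                    kt$kappa[grp == "control"])$p_value
}
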