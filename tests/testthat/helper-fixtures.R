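# Shared fixture builders (all generated in code; no data files).

# long-format nodal profiles: base pattern + per-subject slope + noise
make_cohort_profiles <- function(n_subjects, n_nodes = 15, metric = "D",
                                 slopes = rep(0, n_subjects),
                                 noise_sd = 0, sessions = "ses1",
                                 hemisphere = "left", seed = 1) {
  base <- seq_len(n_nodes) + 2
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      for (ses in sessions) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = sprintf("s%02d", s),
          session_id = ses,
          hemisphere = hemisphere,
          cost = 0.2,
          node_id = seq_len(n_nodes),
          metric = metric,
          value = (1 + slopes[s]) * base + rnorm(n_nodes, sd = noise_sd)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# subject x session matrix with controllable between/within SD
make_icc_matrix <- function(n = 20, k = 2, between_sd = 1, within_sd = 1,
                            seed = 1) {
  withr::with_seed(seed, {
    subj <- rnorm(n, sd = between_sd)
    matrix(rep(subj, k), n, k) + matrix(rnorm(n * k, sd = within_sd), n, k)
  })
}

# symmetric two-hemisphere correlation fixture: identical blocks for
# homologous nodes
symmetric_corr_fixture <- function(n_per_side = 5, seed = 3) {
  regions <- make_parcellation(n_per_side, n_midline = 1)
  withr::with_seed(seed, {
    block <- stats::cov2cor(crossprod(matrix(rnorm(n_per_side * 20),
                                             20, n_per_side)))
  })
  n <- nrow(regions)
  vals <- diag(n)
  left <- which(regions$hemisphere == "left")
  right <- which(regions$hemisphere == "right")
  vals[left, left] <- block
  vals[right, right] <- block
  corr_matrix(vals, regions = regions)
}
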