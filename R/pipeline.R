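#' Nodal metric profiles for every series of a cohort
#'
#' Runs the per-subject pipeline — wavelet correlation at the TR-selected (or
#' given) scale, cost-thresholded connected graph, five nodal metrics — for
#' every series of a [simulate_cohort()] object (or any named list of
#' [ts_matrix()]), over a grid of costs.
#'
#' @param cohort A `synthetic_cohort` or a named list of [ts_matrix()].
#' @param costs Numeric vector of costs (default 0.20).
#' @param scale Wavelet scale; `NULL` selects from the TR.
#' @param filter_name Wavelet filter (default `"la8"`).
#' @return Long tibble: `subject_id`, `session_id`, `hemisphere`, `cost`,
#'   `node_id`, `metric`, `value`, plus `group` and `disrupted` when a
#'   cohort manifest is available.
#' @export
cohort_profiles <- function(cohort, costs = 0.2, scale = NULL,
                            filter_name = "la8") {
  series <- if (inherits(cohort, "synthetic_cohort")) cohort$series else cohort
  manifest <- if (inherits(cohort, "synthetic_cohort")) cohort$manifest else NULL
  rows <- purrr::map(series, function(ts) {
    cm <- wavelet_cor(ts, scale = scale, filter_name = filter_name)
    hemi <- unique(ts$regions$hemisphere)
    hemi <- if (length(hemi) == 1) hemi else "all"
    purrr::map_dfr(costs, function(cst) {
      g <- threshold_to_cost(cm, cst)
      prof <- metric_profile(g)
      profile_long(prof) |>
        dplyr::mutate(hemisphere = hemi, cost = cst)
    })
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(manifest)) {
    out <- dplyr::left_join(
      out,
      dplyr::distinct(manifest, .data$subject_id, .data$session_id,
                      .data$hemisphere, .data$group, .data$disrupted,
                      .data$contralesional_side),
      by = c("subject_id", "session_id", "hemisphere")
    )
  }
  out
}

default_run_config <- function() {
  list(
    cohort = list(),             # overrides for cohort_spec()
    costs = c(0.1, 0.15, 0.2, 0.25, 0.3),
    metrics = c("D", "Eg", "B", "El", "C"),
    scale = NULL,                # NULL: select from TR
    design = "pooled",
    qc_threshold = 0.12,
    reliability = TRUE,          # ICC across sessions when >= 2 sessions
    robustness_iter = 0,         # > 0 enables the bootstrap robustness stage
    seed = 1L
  )
}

#' Validate and complete a pipeline run configuration
#'
#' @param config A list (or path to a JSON file) with any of: `cohort`
#'   (overrides for [cohort_spec()]), `costs`, `metrics`, `scale`, `design`
#'   (`"pooled"` or `"per-side"`), `qc_threshold`, `reliability`,
#'   `robustness_iter`, `seed`.
#' @return The completed config list with class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config, keep.null = TRUE)
  if (!cfg$design %in% c("pooled", "per-side")) {
    abort("`design` must be 'pooled' or 'per-side'.")
  }
  bad_metric <- setdiff(cfg$metrics, c("D", "Eg", "B", "El", "C"))
  if (length(bad_metric) > 0) {
    abort(paste0("Unknown metric(s): ", paste(bad_metric, collapse = ", ")))
  }
  for (cst in cfg$costs) assert_proportion(cst, "costs")
  cohort_args <- cfg$cohort
  if (is.null(cohort_args$seed)) cohort_args$seed <- cfg$seed
  spec <- do.call(cohort_spec, cohort_args)
  n_pairs <- spec$n_nodes * (spec$n_nodes - 1) / 2
  floor_cost <- (spec$n_nodes - 1) / n_pairs
  if (any(round(cfg$costs * n_pairs) < spec$n_nodes - 1)) {
    abort(sprintf(
      "Cost grid dips below the spanning-tree floor (%.4f for %d nodes).",
      floor_cost, spec$n_nodes
    ))
  }
  cfg$cohort_spec <- spec
  structure(cfg, class = "run_config")
}

#' Run the full simulate-then-analyze pipeline
#'
#' Executes the stages in dependency order: simulate cohort, per-subject
#' profiles over the cost grid, kappa tables for controls (mean-of-
#' hemispheres reference) and patients (contralesional hemisphere), Wilcoxon
#' comparison across costs, nodal difference map at the first cost, and —
#' when configured — session reliability (ICC) and bootstrap robustness.
#' Every output is written as TSV under `out_dir` together with a JSON
#' manifest carrying the config, its hash and the seed, so a rerun with the
#' same config reproduces the run bit-exactly.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    abort("`out_dir` exists and is not empty; runs are append-only.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cfg$cohort_spec
  cohort <- simulate_cohort(spec)
  profiles <- cohort_profiles(cohort, costs = cfg$costs, scale = cfg$scale)

  ses1 <- profiles[profiles$session_id == "ses1", ]
  ctl <- ses1[ses1$group == "control", ]
  pat <- ses1[ses1$group == "patient" & ses1$disrupted, ]

  kappa_ctl <- list(); kappa_pat <- list()
  for (m in cfg$metrics) {
    for (cst in cfg$costs) {
      ref <- reference_profile(ctl[ctl$cost == cst, ], m,
                               pooling = "left-right-mean",
                               regions = cohort$regions)
      pooled_ctl <- ctl[ctl$cost == cst, ] |>
        dplyr::filter(.data$metric == m) |>
        dplyr::mutate(node_id = pair_key(.data$node_id, cohort$regions)) |>
        dplyr::group_by(.data$subject_id, .data$node_id) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
        dplyr::mutate(metric = m, session_id = "ses1",
                      hemisphere = "pooled", cost = cst)
      kappa_ctl[[paste(m, cst)]] <- cohort_kappa(pooled_ctl, ref, m)
      kappa_pat[[paste(m, cst)]] <- cohort_kappa(
        pat[pat$cost == cst, ], ref, m
      )
    }
  }
  kappa_ctl <- dplyr::bind_rows(kappa_ctl)
  kappa_pat <- dplyr::bind_rows(kappa_pat)
  comparison <- compare_kappa_across_costs(kappa_ctl, kappa_pat,
                                           metrics = cfg$metrics,
                                           costs = cfg$costs)
  nodal <- nodal_group_difference(
    ctl[ctl$cost == cfg$costs[1] & ctl$hemisphere == "left", ],
    pat[pat$cost == cfg$costs[1] & pat$hemisphere == "left", ],
    metric = cfg$metrics[1]
  )

  reliability <- NULL
  if (isTRUE(cfg$reliability) && spec$n_sessions >= 2) {
    ctl_left <- profiles[profiles$group == "control" &
                           profiles$hemisphere == "left", ]
    reliability <- bootstrap_subgroup_reliability(
      ctl_left, metric = cfg$metrics[1], sizes = spec$n_controls,
      n_boot = 1
    )
  }
  robustness <- NULL
  if (cfg$robustness_iter > 0) {
    obs_z <- comparison$z[comparison$metric == cfg$metrics[1] &
                            comparison$cost == cfg$costs[1]]
    # split the available controls roughly in half, test side 55/45 as in
    # the clinical arm's lesion-side ratio
    n_ref <- floor(spec$n_controls / 2)
    n_test <- spec$n_controls - n_ref
    n_tr <- max(1L, round(0.55 * n_test))
    n_tl <- max(1L, n_test - n_tr)
    robustness <- bootstrap_robustness(
      ctl[ctl$cost == cfg$costs[1], ], metric = cfg$metrics[1],
      observed_z = obs_z,
      design = cfg$design, n_iter = cfg$robustness_iter,
      n_ref = n_ref - max(0L, n_tr + n_tl - n_test),
      n_test_right = n_tr, n_test_left = n_tl,
      regions = cohort$regions,
      seed = derive_seeds(cfg$seed, 1)
    )
  }

  paths <- list(
    manifest = file.path(out_dir, "manifest.json"),
    profiles = file.path(out_dir, "profiles.tsv"),
    kappa_controls = file.path(out_dir, "kappa_controls.tsv"),
    kappa_patients = file.path(out_dir, "kappa_patients.tsv"),
    comparison = file.path(out_dir, "comparison.tsv"),
    nodal_difference = file.path(out_dir, "nodal_difference.tsv")
  )
  readr::write_tsv(profiles, paths$profiles)
  readr::write_tsv(kappa_ctl, paths$kappa_controls)
  readr::write_tsv(kappa_pat, paths$kappa_patients)
  readr::write_tsv(comparison, paths$comparison)
  readr::write_tsv(nodal, paths$nodal_difference)
  if (!is.null(reliability)) {
    paths$reliability <- file.path(out_dir, "reliability.tsv")
    readr::write_tsv(reliability, paths$reliability)
  }
  if (!is.null(robustness)) {
    paths$robustness <- file.path(out_dir, "robustness_null_z.tsv")
    readr::write_tsv(robustness$null_z, paths$robustness)
  }
  cfg_plain <- unclass(cfg)
  cfg_plain$cohort_spec <- unclass(cfg_plain$cohort_spec)
  manifest <- list(
    config = cfg_plain,
    config_hash = rlang::hash(cfg_plain),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("hubdisrupt")),
    outputs = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(
    config = cfg, cohort = cohort, profiles = profiles,
    kappa_controls = kappa_ctl, kappa_patients = kappa_pat,
    comparison = comparison, nodal_difference = nodal,
    reliability = reliability, robustness = robustness, paths = paths
  ))
}

#' Plot a group comparison across costs
#'
#' @param comparison Tibble from [compare_kappa_across_costs()].
#' @return A ggplot of z against cost per metric, significance starred.
#' @export
plot_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$cost, y = .data$z,
                               colour = .data$metric)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.6,
                       show.legend = FALSE) +
    ggplot2::labs(x = "cost", y = "Wilcoxon z (patients vs controls)",
                  colour = "metric") +
    ggplot2::theme_minimal()
}

#' Plot ICC against cost per subgroup size
#'
#' @param reliability Tibble from [bootstrap_subgroup_reliability()].
#' @return A ggplot of the ICC distribution over draws by cost and size.
#' @export
plot_reliability <- function(reliability) {
  ggplot2::ggplot(reliability,
                  ggplot2::aes(x = factor(.data$cost), y = .data$icc,
                               colour = factor(.data$size))) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "cost", y = "ICC(1,1)", colour = "subgroup size") +
    ggplot2::theme_minimal()
}
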