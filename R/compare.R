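#' Two-sided Wilcoxon rank-sum test with z statistic
#'
#' Rank-sum test returning the z value of the normal approximation with tie
#' correction; for small samples (combined n <= `exact_max`) the p-value is
#' computed by exhaustive enumeration of group assignments (symmetric
#' two-sided counting), which remains valid under ties.
#'
#' @param x,y Numeric vectors (first group's ranks form the statistic; z > 0
#'   means `x` tends to be larger).
#' @param exact_max Largest combined sample size for exact enumeration
#'   (default 12).
#' @return A list with `statistic` (rank sum of `x`), `z`, `p_value`,
#'   `exact`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be nonempty.")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(statistic = w, z = 0, p_value = 1, exact = TRUE))
  }
  z <- (w - mu) / sqrt(sigma2)
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    stats_all <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(stats_all - mu) >= abs(w - mu) - 1e-9)
    return(list(statistic = w, z = z, p_value = p, exact = TRUE))
  }
  list(statistic = w, z = z, p_value = 2 * stats::pnorm(-abs(z)),
       exact = FALSE)
}

#' Significance stars at the conventional thresholds
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"***"` (< 0.001), `"**"` (< 0.01),
#'   `"*"` (< 0.05), `""` otherwise.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare hub disruption indices between groups across costs
#'
#' One Wilcoxon rank-sum comparison (patients vs controls) per metric and
#' cost. The z sign follows the patients-first convention, so hub-targeted
#' disruption shows as negative z.
#'
#' @param controls,patients Kappa tables as returned by [cohort_kappa()]
#'   (columns `metric`, `cost`, `kappa`; extra columns ignored).
#' @param metrics Metrics to compare; default: all present in both tables.
#' @param costs Costs to compare; default: all present in both tables. A
#'   cost or metric missing from either group is an error.
#' @return A comparison tibble: `metric`, `cost`, `n_control`, `n_patient`,
#'   `z`, `p_value`, `stars`.
#' @export
compare_kappa_across_costs <- function(controls, patients, metrics = NULL,
                                       costs = NULL) {
  metrics <- metrics %||% intersect(unique(controls$metric),
                                    unique(patients$metric))
  costs <- costs %||% intersect(unique(controls$cost), unique(patients$cost))
  if (length(metrics) == 0 || length(costs) == 0) {
    abort("No shared metrics/costs between the two groups.")
  }
  grid <- tidyr::expand_grid(metric = metrics, cost = costs)
  purrr::pmap_dfr(grid, function(metric, cost) {
    kc <- controls$kappa[controls$metric == metric & controls$cost == cost]
    kp <- patients$kappa[patients$metric == metric & patients$cost == cost]
    if (length(kc) == 0 || length(kp) == 0) {
      abort(sprintf("No kappa values for metric %s at cost %.3f in %s.",
                    metric, cost,
                    if (length(kc) == 0) "controls" else "patients"))
    }
    res <- wilcoxon_rank_sum(kp, kc)
    tibble::tibble(
      metric = metric, cost = cost,
      n_control = length(kc), n_patient = length(kp),
      z = res$z, p_value = res$p_value, stars = signif_stars(res$p_value)
    )
  })
}

#' Nodal group-difference map with 1/N false-positive correction
#'
#' Per-node mean difference (patients minus controls) in one metric with a
#' two-sided Wilcoxon rank-sum p-value, flagged significant at `p < 1/N`
#' where `N` is the number of nodes (0.023 for a 44-node hemisphere).
#'
#' @param control_profiles,patient_profiles Long nodal-value tibbles
#'   (`subject_id`, `node_id`, `metric`, `value`).
#' @param metric Metric name.
#' @return Tibble `node_id`, `mean_control`, `mean_patient`, `mean_diff`,
#'   `p_value`, `significant`; the threshold is in attribute
#'   `"p_threshold"`.
#' @export
nodal_group_difference <- function(control_profiles, patient_profiles,
                                   metric) {
  ctl <- dplyr::filter(control_profiles, .data$metric == !!metric)
  pat <- dplyr::filter(patient_profiles, .data$metric == !!metric)
  nodes <- sort(unique(ctl$node_id))
  if (!setequal(nodes, unique(pat$node_id))) {
    abort("Control and patient profiles must share the node set.")
  }
  n_nodes <- length(nodes)
  thr <- 1 / n_nodes
  out <- purrr::map_dfr(nodes, function(nd) {
    vc <- ctl$value[ctl$node_id == nd]
    vp <- pat$value[pat$node_id == nd]
    res <- wilcoxon_rank_sum(vp, vc)
    tibble::tibble(
      node_id = nd,
      mean_control = mean(vc), mean_patient = mean(vp),
      mean_diff = mean(vp) - mean(vc),
      p_value = res$p_value,
      significant = res$p_value < thr
    )
  })
  attr(out, "p_threshold") <- thr
  attr(out, "n_nodes") <- n_nodes
  out
}

# kappa slopes of many subjects against one reference vector.
# y_mat: nodes x subjects; x: reference vector.
fast_kappa <- function(y_mat, x) {
  xc <- x - mean(x)
  d <- y_mat - x
  dc <- sweep(d, 2, colMeans(d))
  as.numeric(colSums(dc * xc) / sum(xc^2))
}

# nodes x subjects matrix for one hemisphere, rows ordered by pair key
hemisphere_matrix <- function(profiles, metric, side, regions = NULL) {
  prof <- profiles[profiles$metric == metric & profiles$hemisphere == side, ]
  if (nrow(prof) == 0) abort(sprintf("No %s-hemisphere rows.", side))
  key <- if (!is.null(regions)) {
    pair_key(prof$node_id, regions)
  } else {
    prof$node_id
  }
  prof$key <- key
  wide <- tidyr::pivot_wider(
    prof[, c("subject_id", "key", "value")],
    names_from = "subject_id", values_from = "value"
  ) |>
    dplyr::arrange(.data$key)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$key
  mat
}

#' Bootstrap robustness of a group difference in kappa
#'
#' Replays the patient-versus-control design on a healthy cohort: in each
#' iteration a reference group and a disjoint test group are drawn, the test
#' group's hemispheres are assigned to mimic the clinical arm (11 right + 9
#' left contralesional hemispheres by default), kappa is computed for every
#' subject against the drawn reference group's mean profile, and the
#' Wilcoxon z of test-vs-reference kappa is recorded. The null distribution
#' of z quantifies how often a difference as extreme as the observed one
#' arises between same-population groups; `p` counts the fraction of null z
#' values at or below the observed z (lower tail: disruption predicts
#' reduced kappa).
#'
#' @param profiles Long nodal-value tibble for healthy subjects, both
#'   hemispheres (`subject_id`, `hemisphere`, `node_id`, `metric`, `value`),
#'   one session and one cost.
#' @param metric Metric name.
#' @param observed_z Observed z value from the clinical comparison, or `NULL`
#'   (null distribution only).
#' @param design `"pooled"` (test hemispheres pooled against the
#'   mean-of-hemispheres reference) or `"per-side"` (right test hemispheres
#'   vs right reference hemispheres and left vs left).
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param n_ref,n_test_right,n_test_left Group sizes (defaults 20, 11, 9).
#' @param regions Region tibble (required for `"pooled"`, used for homologue
#'   alignment).
#' @param seed Integer seed.
#' @return Object of class `robustness_result`: tibble `null_z` (`iter`,
#'   `contrast`, `z`), plus `observed_z`, `p_raw`, `p_plus1`, `n_iter`.
#' @export
bootstrap_robustness <- function(profiles, metric, observed_z = NULL,
                                 design = c("pooled", "per-side"),
                                 n_iter = 1000, n_ref = 20,
                                 n_test_right = 11, n_test_left = 9,
                                 regions = NULL, seed = NULL) {
  design <- match.arg(design)
  if (design == "pooled" && is.null(regions)) {
    abort("`regions` is required for the pooled design.")
  }
  left <- hemisphere_matrix(profiles, metric, "left", regions)
  right <- hemisphere_matrix(profiles, metric, "right", regions)
  right <- right[rownames(left), colnames(left), drop = FALSE]
  subjects <- colnames(left)
  n_test <- n_test_right + n_test_left
  if (length(subjects) < n_ref + n_test) {
    abort(sprintf("Need >= %d subjects for disjoint draws; have %d.",
                  n_ref + n_test, length(subjects)))
  }
  pooled_mat <- (left + right) / 2
  seeds <- derive_seeds(seed, n_iter)
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    draw <- with_seed(seeds[it], {
      picked <- sample(subjects, n_ref + n_test)
      list(ref = picked[seq_len(n_ref)],
           test = picked[n_ref + seq_len(n_test)])
    })
    test_r <- draw$test[seq_len(n_test_right)]
    test_l <- draw$test[n_test_right + seq_len(n_test_left)]
    if (design == "pooled") {
      x <- rowMeans(pooled_mat[, draw$ref, drop = FALSE])
      k_ref <- fast_kappa(pooled_mat[, draw$ref, drop = FALSE], x)
      k_test <- c(
        fast_kappa(right[, test_r, drop = FALSE], x),
        fast_kappa(left[, test_l, drop = FALSE], x)
      )
      z <- wilcoxon_rank_sum(k_test, k_ref)$z
      rows[[it]] <- tibble::tibble(iter = it, contrast = "pooled", z = z)
    } else {
      xr <- rowMeans(right[, draw$ref, drop = FALSE])
      xl <- rowMeans(left[, draw$ref, drop = FALSE])
      zr <- wilcoxon_rank_sum(
        fast_kappa(right[, test_r, drop = FALSE], xr),
        fast_kappa(right[, draw$ref, drop = FALSE], xr)
      )$z
      zl <- wilcoxon_rank_sum(
        fast_kappa(left[, test_l, drop = FALSE], xl),
        fast_kappa(left[, draw$ref, drop = FALSE], xl)
      )$z
      rows[[it]] <- tibble::tibble(iter = it,
                                   contrast = c("right", "left"),
                                   z = c(zr, zl))
    }
  }
  null_z <- dplyr::bind_rows(rows)
  res <- structure(
    list(null_z = null_z, observed_z = observed_z, n_iter = n_iter,
         design = design, metric = metric, seed = seed),
    class = "robustness_result"
  )
  if (!is.null(observed_z)) {
    by_contrast <- split(null_z$z, null_z$contrast)
    res$p_raw <- vapply(by_contrast, function(zv) mean(zv <= observed_z),
                        numeric(1))
    res$p_plus1 <- vapply(by_contrast, function(zv) {
      (sum(zv <= observed_z) + 1) / (length(zv) + 1)
    }, numeric(1))
  }
  res
}

#' @method print robustness_result
#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness_result> %s design, %d iterations, metric %s\n",
              x$design, x$n_iter, x$metric))
  if (!is.null(x$observed_z)) {
    for (ct in names(x$p_raw)) {
      cat(sprintf("  %s: p = %.4g (raw counting), %.4g ((b+1)/(B+1))\n",
                  ct, x$p_raw[ct], x$p_plus1[ct]))
    }
  }
  invisible(x)
}

#' Histogram of a bootstrap null z distribution
#'
#' @param object A [bootstrap_robustness()] result.
#' @param ... Unused.
#' @return A ggplot object; the observed z, when present, is marked.
#' @export
autoplot.robustness_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$null_z, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "Wilcoxon z under same-population draws",
                  y = "count",
                  title = sprintf("Bootstrap robustness (kappa_%s)",
                                  object$metric)) +
    ggplot2::theme_minimal()
  if (!is.null(object$observed_z)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed_z,
                                 colour = "#b2182b")
  }
  p
}
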