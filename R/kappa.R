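#' Canonical homologue-pair key for a node
#'
#' Maps every lateralized region to the smaller id of its left/right
#' homologue pair, so that a left-hemisphere profile and the corresponding
#' right-hemisphere profile align node-by-node. Midline regions keep their
#' own id.
#'
#' @param node_id Integer region ids.
#' @param regions Region tibble.
#' @return Integer vector of pair keys.
#' @export
pair_key <- function(node_id, regions) {
  idx <- match(node_id, regions$region_id)
  if (anyNA(idx)) abort("Unknown region id(s) in `node_id`.")
  hom <- regions$homologue_id[idx]
  pmin(node_id, ifelse(is.na(hom), node_id, hom))
}

#' Reference (normative) nodal profile of a group
#'
#' The nodewise mean of a metric over the reference subjects. With
#' `pooling = "left-right-mean"` each subject's left and right homologous
#' nodal values are averaged first (the normative intra-hemispheric profile),
#' then averaged across subjects; nodes are then indexed by homologue-pair
#' key so that either hemisphere of any subject can be regressed against the
#' reference.
#'
#' @param profiles Long tibble of nodal values with columns `subject_id`,
#'   `node_id`, `metric`, `value` (and `hemisphere` for pooling); see
#'   [profile_long()].
#' @param metric Which metric (`"D"`, `"Eg"`, `"B"`, `"El"` or `"C"`).
#' @param pooling `"single"` (plain nodewise mean over the rows supplied) or
#'   `"left-right-mean"`.
#' @param regions Region tibble; required for `"left-right-mean"`.
#' @return An object of class `reference_profile`: tibble columns `node_key`
#'   and `value`, with attributes `metric`, `n_reference`, `pooling`.
#' @export
reference_profile <- function(profiles, metric,
                              pooling = c("single", "left-right-mean"),
                              regions = NULL) {
  pooling <- match.arg(pooling)
  prof <- dplyr::filter(profiles, .data$metric == !!metric)
  if (nrow(prof) == 0) abort(sprintf("No rows for metric '%s'.", metric))
  n_ref <- dplyr::n_distinct(prof$subject_id)
  if (n_ref < 2) abort("Need at least 2 reference subjects.")
  if (pooling == "left-right-mean") {
    if (is.null(regions)) {
      abort("`regions` is required for left-right-mean pooling.")
    }
    prof <- prof |>
      dplyr::mutate(node_key = pair_key(.data$node_id, regions)) |>
      dplyr::group_by(.data$subject_id, .data$node_key) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  } else {
    prof <- dplyr::mutate(prof, node_key = .data$node_id)
  }
  per_subject <- prof |>
    dplyr::count(.data$subject_id, .data$node_key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(per_subject) > 0) {
    abort(paste0("Multiple values per subject and node; filter to one ",
                 "session/hemisphere/cost before building a reference."))
  }
  ref <- prof |>
    dplyr::group_by(.data$node_key) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$node_key)
  structure(ref, class = c("reference_profile", class(ref)),
            metric = metric, n_reference = n_ref, pooling = pooling,
            regions = regions)
}

# Align a subject's nodal vector to a reference profile's node keys.
align_to_reference <- function(node_id, value, ref) {
  key <- if (attr(ref, "pooling") == "left-right-mean") {
    pair_key(node_id, attr(ref, "regions"))
  } else {
    node_id
  }
  idx <- match(ref$node_key, key)
  if (anyNA(idx)) {
    abort("Subject profile does not cover the reference node set.")
  }
  value[idx]
}

#' Hub disruption index of one subject profile
#'
#' Regresses the subject-minus-reference nodal difference on the reference
#' group's mean nodal value (ordinary least squares with intercept); the
#' fitted slope is the hub disruption index. A subject whose topology
#' matches the norm scatters around a horizontal line (slope ~ 0); a subject
#' whose hubs lost relative value while peripheral nodes gained shows a
#' negative slope.
#'
#' @param subject A wide profile tibble ([metric_profile()]), a tibble with
#'   columns `node_id` and `value`, or a numeric vector aligned with the
#'   reference.
#' @param ref A [reference_profile()].
#' @param metric Metric name; defaults to the reference's metric (used to
#'   pick the column of a wide profile).
#' @return An object of class `kappa_result` with fields `kappa`,
#'   `intercept`, `r_squared`, `metric`, `n_nodes`, provenance, and the
#'   per-node scatter `data` (`node_key`, `ref`, `diff`).
#' @examples
#' refp <- structure(
#'   tibble::tibble(node_key = 1:5, value = c(1, 2, 3, 4, 5)),
#'   class = c("reference_profile", "tbl_df", "tbl", "data.frame"),
#'   metric = "D", n_reference = 2, pooling = "single"
#' )
#' kappa_index(c(1.5, 3, 4.5, 6, 7.5), refp)$kappa # 0.5: subject = 1.5 * ref
#' @export
kappa_index <- function(subject, ref, metric = NULL) {
  stopifnot(inherits(ref, "reference_profile"))
  metric <- metric %||% attr(ref, "metric")
  prov <- list(subject_id = NA_character_, session_id = NA_character_,
               hemisphere = NA_character_, cost = NA_real_)
  if (is.data.frame(subject)) {
    val_col <- if ("value" %in% names(subject)) "value" else metric
    if (!val_col %in% names(subject)) {
      abort(sprintf("Subject profile has no '%s' column.", metric))
    }
    prov$subject_id <- attr(subject, "subject_id") %||% NA_character_
    prov$session_id <- attr(subject, "session_id") %||% NA_character_
    prov$hemisphere <- attr(subject, "hemisphere") %||% NA_character_
    prov$cost <- attr(subject, "cost") %||% NA_real_
    y <- align_to_reference(subject$node_id, subject[[val_col]], ref)
  } else {
    y <- as.numeric(subject)
    if (length(y) != nrow(ref)) {
      abort("Subject vector length must match the reference node count.")
    }
  }
  x <- ref$value
  if (var(x) == 0) {
    abort("Reference profile is constant across nodes; kappa is undefined.")
  }
  d <- y - x
  slope <- stats::cov(d, x) / var(x)
  intercept <- mean(d) - slope * mean(x)
  ss_res <- sum((d - intercept - slope * x)^2)
  ss_tot <- sum((d - mean(d))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(kappa = slope, intercept = intercept, r_squared = r2,
         metric = metric, n_nodes = nrow(ref),
         subject_id = prov$subject_id, session_id = prov$session_id,
         hemisphere = prov$hemisphere, cost = prov$cost,
         data = tibble::tibble(node_key = ref$node_key, ref = x, diff = d)),
    class = "kappa_result"
  )
}

#' @method print kappa_result
#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "<kappa_result> kappa_%s = %.4f (intercept %.4f, R^2 %s, %d nodes)\n",
    x$metric, x$kappa, x$intercept,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)), x$n_nodes
  ))
  invisible(x)
}

#' Hub disruption index for every subject of a cohort
#'
#' @param profiles Long tibble of nodal values (`subject_id`, `session_id`,
#'   `hemisphere`, `cost`, `node_id`, `metric`, `value`).
#' @param ref A [reference_profile()], or `NULL` to build it from `profiles`
#'   itself (the plain group mean, the default normative choice).
#' @param metric Metric name.
#' @param pooling,regions Passed to [reference_profile()] when `ref` is
#'   built here.
#' @param leave_one_out When `TRUE`, each subject is evaluated against the
#'   mean of the *other* subjects instead of the full group mean.
#' @return Tibble with one row per subject/session/hemisphere/cost:
#'   `subject_id`, `session_id`, `hemisphere`, `cost`, `metric`, `kappa`,
#'   `intercept`, `r_squared`, `n_nodes`.
#' @export
cohort_kappa <- function(profiles, ref = NULL, metric,
                         pooling = "single", regions = NULL,
                         leave_one_out = FALSE) {
  prof <- dplyr::filter(profiles, .data$metric == !!metric)
  if (nrow(prof) == 0) abort(sprintf("No rows for metric '%s'.", metric))
  for (col in c("session_id", "hemisphere", "cost")) {
    if (!col %in% names(prof)) prof[[col]] <- NA
  }
  if (is.null(ref) && !leave_one_out) {
    ref <- reference_profile(profiles, metric, pooling = pooling,
                             regions = regions)
  }
  groups <- dplyr::distinct(prof, .data$subject_id, .data$session_id,
                            .data$hemisphere, .data$cost)
  purrr::pmap_dfr(groups, function(subject_id, session_id, hemisphere, cost) {
    rows <- prof[
      prof$subject_id == subject_id &
        prof$session_id %in% session_id &
        prof$hemisphere %in% hemisphere &
        prof$cost %in% cost,
    ]
    use_ref <- if (leave_one_out) {
      reference_profile(profiles[profiles$subject_id != subject_id, ],
                        metric, pooling = pooling, regions = regions)
    } else {
      ref
    }
    k <- kappa_index(
      tibble::tibble(node_id = rows$node_id, value = rows$value), use_ref,
      metric = metric
    )
    tibble::tibble(
      subject_id = subject_id, session_id = session_id,
      hemisphere = hemisphere, cost = cost, metric = metric,
      kappa = k$kappa, intercept = k$intercept, r_squared = k$r_squared,
      n_nodes = k$n_nodes
    )
  })
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "kappa"),
    estimate = c(x$intercept, x$kappa)
  )
}

#' @export
glance.kappa_result <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, kappa = x$kappa, intercept = x$intercept,
    r.squared = x$r_squared, n_nodes = x$n_nodes,
    subject_id = x$subject_id, session_id = x$session_id,
    hemisphere = x$hemisphere, cost = x$cost
  )
}

#' Scatter plot of a hub disruption fit
#'
#' Reference nodal value against the subject-minus-reference difference, with
#' the fitted regression line whose slope is kappa.
#'
#' @param object A [kappa_index()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kappa_result <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ref, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$kappa,
                         colour = "#b2182b") +
    ggplot2::labs(
      x = sprintf("Reference group mean %s", object$metric),
      y = sprintf("Subject %s - reference", object$metric),
      title = sprintf("Hub disruption index: kappa = %.3f", object$kappa)
    ) +
    ggplot2::theme_minimal()
}
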