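#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Decomposes a subject-by-session matrix with the one-way random-effects
#' ANOVA and forms `ICC = (s_b - s_w) / (s_b + (k - 1) s_w)`, where `s_b`
#' and `s_w` are the between- and within-subject mean squares and `k` the
#' number of sessions. Values near 1 indicate high test-retest reliability;
#' negative values (within-variability exceeding between) are returned as
#' computed and flagged non-reliable.
#'
#' @param values Numeric matrix, subjects x sessions, no missing cells.
#' @return An object of class `icc_result` with fields `icc`, `s_b`, `s_w`,
#'   `k`, `n`, `reliable` (`icc > 0`), `p_value` (NA until
#'   [icc_permutation_p()] fills it), `n_permutations_used`.
#' @examples
#' icc_one_way(rbind(c(1, 1), c(5, 5)))$icc  # 1: sessions identical
#' icc_one_way(rbind(c(0, 1), c(1, 0)))$icc  # -1: pure within-variability
#' @export
icc_one_way <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) abort("ICC requires complete subject x session data.")
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2 || k < 2) abort("Need >= 2 subjects and >= 2 sessions.")
  grand <- mean(values)
  subj_means <- rowMeans(values)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((values - subj_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    warn("All values identical; ICC defined as 1 with zero variance.")
    icc <- 1
  } else {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
  }
  structure(
    list(icc = icc, s_b = msb, s_w = msw, k = k, n = n,
         reliable = icc > 0, p_value = NA_real_,
         n_permutations_used = NA_integer_),
    class = "icc_result"
  )
}

#' @method print icc_result
#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(1,1) = %.4f (n = %d, k = %d%s)\n",
              x$icc, x$n, x$k,
              if (is.na(x$p_value)) "" else sprintf(", p = %.4g", x$p_value)))
  invisible(x)
}

#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, s_b = x$s_b, s_w = x$s_w, n = x$n, k = x$k,
    reliable = x$reliable, p_value = x$p_value,
    n_permutations_used = x$n_permutations_used
  )
}

permute_icc_null <- function(values, unit) {
  if (unit == "cells") {
    matrix(sample(values), nrow = nrow(values))
  } else {
    # shuffle subjects independently within each session column
    apply(values, 2, sample)
  }
}

#' Permutation p-value for an observed ICC
#'
#' Generates the no-reliability null by randomly reassigning observations to
#' subject slots (breaking subject identity) and estimates
#' `P(ICC_null >= ICC_obs)`, one-sided since high ICC means reliable. The
#' default is an open-ended sequential Monte-Carlo procedure: sampling
#' continues until a Clopper-Pearson confidence sequence (error budget
#' `resampling_risk`, spent geometrically over looks) lies entirely on one
#' side of `alpha`, bounding the probability that the accept/reject decision
#' differs from the infinite-sampling one. A fixed-budget mode
#' (`p = (b + 1) / (B + 1)`) is available as the reference procedure.
#'
#' @param values Subject x session matrix.
#' @param alpha Decision threshold the sequential boundary tests against
#'   (default 0.05).
#' @param resampling_risk Uniform bound on the probability of a wrong
#'   decision (default 1e-3).
#' @param max_steps Permutation budget (default 1e5).
#' @param batch Draws between sequential looks (default 100).
#' @param mode `"sequential"` (default) or `"fixed"`.
#' @param n_fixed Budget for `mode = "fixed"` (default 9999).
#' @param unit `"cells"` (default: full reassignment of the pooled
#'   observations) or `"sessions"` (shuffle subjects within each session
#'   column).
#' @param seed Integer seed or `NULL`.
#' @return The [icc_one_way()] result with `p_value`,
#'   `n_permutations_used`, `decision` (`"significant"`,
#'   `"not significant"`, `"unresolved"`) filled in.
#' @export
icc_permutation_p <- function(values, alpha = 0.05, resampling_risk = 1e-3,
                              max_steps = 1e5, batch = 100,
                              mode = c("sequential", "fixed"),
                              n_fixed = 9999, unit = c("cells", "sessions"),
                              seed = NULL) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  obs <- icc_one_way(values)
  icc_stat <- function(m) {
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m); sm <- rowMeans(m)
    msb <- k * sum((sm - grand)^2) / (n - 1)
    msw <- sum((m - sm)^2) / (n * (k - 1))
    if (msb == 0 && msw == 0) 1 else (msb - msw) / (msb + (k - 1) * msw)
  }
  with_seed(seed, {
    if (mode == "fixed") {
      exceed <- sum(vapply(seq_len(n_fixed), function(i) {
        icc_stat(permute_icc_null(values, unit)) >= obs$icc
      }, logical(1)))
      obs$p_value <- (exceed + 1) / (n_fixed + 1)
      obs$n_permutations_used <- as.integer(n_fixed)
      obs$decision <- if (obs$p_value < alpha) "significant" else "not significant"
      return(obs)
    }
    b <- 0L; t_used <- 0L; look <- 0L
    decision <- "unresolved"
    while (t_used < max_steps) {
      this_batch <- min(batch, max_steps - t_used)
      b <- b + sum(vapply(seq_len(this_batch), function(i) {
        icc_stat(permute_icc_null(values, unit)) >= obs$icc
      }, logical(1)))
      t_used <- t_used + this_batch
      look <- look + 1L
      alpha_look <- resampling_risk / 2^look
      lo <- if (b == 0) 0 else qbeta(alpha_look / 2, b, t_used - b + 1)
      hi <- if (b == t_used) 1 else qbeta(1 - alpha_look / 2, b + 1, t_used - b)
      if (hi < alpha) {
        decision <- "significant"
        break
      }
      if (lo > alpha) {
        decision <- "not significant"
        break
      }
    }
    obs$p_value <- (b + 1) / (t_used + 1)
    obs$n_permutations_used <- as.integer(t_used)
    obs$decision <- decision
    obs
  })
}

#' Bootstrap subgroup reliability of the hub disruption index
#'
#' Assesses how test-retest reliability of kappa depends on group size: for
#' every requested subgroup size, subjects are drawn without replacement,
#' kappa is recomputed for each drawn subject and session against that
#' subgroup's own per-session mean profile, and the ICC(1,1) across the two
#' (or more) sessions is recorded.
#'
#' @param profiles Long tibble of nodal values with columns `subject_id`,
#'   `session_id`, `cost`, `node_id`, `metric`, `value`, covering >= 2
#'   sessions per subject (one hemisphere scope at a time).
#' @param metric Metric name.
#' @param sizes Integer vector of subgroup sizes.
#' @param n_boot Draws per size (a size equal to the full cohort collapses to
#'   one deterministic draw).
#' @param icc_p Also compute the sequential permutation p-value per draw.
#' @param seed Integer seed.
#' @param ... Passed to [icc_permutation_p()] when `icc_p = TRUE`.
#' @return Tibble with columns `size`, `draw`, `cost`, `icc`, `s_b`, `s_w`
#'   and (optionally) `p_value`, `n_permutations_used`.
#' @export
bootstrap_subgroup_reliability <- function(profiles, metric, sizes,
                                           n_boot = 100, icc_p = FALSE,
                                           seed = NULL, ...) {
  subjects <- unique(profiles$subject_id)
  sessions <- sort(unique(profiles$session_id))
  costs <- sort(unique(profiles$cost))
  if (length(sessions) < 2) abort("Need >= 2 sessions.")
  if (max(sizes) > length(subjects)) {
    abort("Subgroup size exceeds cohort size.")
  }
  seeds <- derive_seeds(seed, length(sizes) * n_boot + length(sizes) * n_boot)
  out <- list()
  row_i <- 0L
  for (s_i in seq_along(sizes)) {
    size <- sizes[s_i]
    draws <- if (size == length(subjects)) 1L else n_boot
    for (d in seq_len(draws)) {
      row_i <- row_i + 1L
      sub <- with_seed(seeds[row_i], sample(subjects, size))
      sub_prof <- profiles[profiles$subject_id %in% sub, ]
      for (cst in costs) {
        cost_prof <- sub_prof[sub_prof$cost %in% cst, ]
        kap <- matrix(NA_real_, nrow = size, ncol = length(sessions),
                      dimnames = list(sub, sessions))
        for (ses in sessions) {
          ses_prof <- cost_prof[cost_prof$session_id == ses, ]
          ref <- reference_profile(ses_prof, metric)
          kt <- cohort_kappa(ses_prof, ref, metric)
          kap[kt$subject_id, ses] <- kt$kappa
        }
        res <- if (icc_p) {
          icc_permutation_p(kap, seed = seeds[length(sizes) * n_boot + row_i],
                            ...)
        } else {
          icc_one_way(kap)
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          size = size, draw = d, cost = cst, icc = res$icc,
          s_b = res$s_b, s_w = res$s_w,
          p_value = res$p_value,
          n_permutations_used = res$n_permutations_used
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Left/right hemispheric symmetry test
#'
#' Wilcoxon comparison of left- versus right-hemisphere kappa values
#' (typically computed against the mean-of-hemispheres reference). A
#' non-significant result supports pooling contralesional hemispheres across
#' lesion sides.
#'
#' @param left,right Numeric vectors of per-subject values.
#' @param paired Use the signed-rank test on per-subject differences
#'   (default `FALSE`: rank-sum).
#' @return One-row tibble with `statistic` (z for the rank-sum test, V for
#'   the signed-rank test), `p_value` and `method`.
#' @export
hemispheric_symmetry_test <- function(left, right, paired = FALSE) {
  if (paired) {
    if (length(left) != length(right)) {
      abort("Paired test needs equal-length vectors.")
    }
    d <- left - right
    if (all(d == 0)) {
      return(tibble::tibble(statistic = 0, p_value = 1,
                            method = "wilcoxon signed-rank"))
    }
    wt <- suppressWarnings(stats::wilcox.test(left, right, paired = TRUE))
    return(tibble::tibble(statistic = unname(wt$statistic),
                          p_value = wt$p.value,
                          method = "wilcoxon signed-rank"))
  }
  res <- wilcoxon_rank_sum(left, right)
  tibble::tibble(statistic = res$z, p_value = res$p_value,
                 method = "wilcoxon rank-sum")
}
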