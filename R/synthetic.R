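#' Specification of a synthetic two-hemisphere cohort
#'
#' Defines the study conditions emulated by the generator: a control group
#' and a patient group, two hemispheres of `n_nodes` regions each, optional
#' repeated sessions, and a spatial correlation structure in which a
#' designated fraction of nodes act as hubs (elevated correlation to every
#' other node). Patients carry a hub-targeted attenuation (`disruption_gamma`)
#' of the contralesional hemisphere, optionally with a periphery boost,
#' emulating the combination of underconnected hubs and overconnected
#' peripheral regions seen after focal lesions.
#'
#' Defaults mirror a small clinical arm: 20 controls + 20 patients, 44 nodes
#' per hemisphere, 512 timepoints at TR 2 s (wavelet scale 3 is selected
#' automatically), two sessions, 20% hubs with correlation 0.5 against a 0.1
#' background, lag-1 temporal autocorrelation 0.3 and observation noise SD
#' 0.5 (about 20% correlation attenuation).
#'
#' @param n_controls,n_patients Group sizes.
#' @param n_nodes Regions per hemisphere.
#' @param n_timepoints Timepoints per series (>= 64).
#' @param tr Repetition time in seconds.
#' @param n_sessions Sessions per subject.
#' @param hub_fraction Fraction of nodes designated hubs.
#' @param base_corr,hub_corr Background and hub correlation targets.
#' @param disruption_gamma Hub attenuation strength in \[0, 1\] for patients.
#' @param periphery_boost Added correlation among non-hub pairs in patients.
#' @param noise_sd Observation (white) noise SD; signal variance is 1.
#' @param temporal_ar1 Lag-1 autocorrelation of the latent series.
#' @param subject_corr_jitter Weight in \[0, 1\] of a stable subject-specific
#'   random correlation structure blended into the group covariance (shared
#'   across sessions); diffuse individual variability.
#' @param subject_hub_sd SD of the stable per-subject multiplier on hub
#'   correlation strength (mean 1, shared across sessions); individual
#'   variability along the hub gradient itself, which is what makes the hub
#'   disruption index a trait-like, test-retest-reliable quantity.
#' @param seed Integer seed driving every draw of the cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 20, n_patients = 20, n_nodes = 44,
                        n_timepoints = 512, tr = 2.0, n_sessions = 2,
                        hub_fraction = 0.2, base_corr = 0.1, hub_corr = 0.5,
                        disruption_gamma = 0.6, periphery_boost = 0,
                        noise_sd = 0.5, temporal_ar1 = 0.3,
                        subject_corr_jitter = 0.2, subject_hub_sd = 0.15,
                        seed = 1L) {
  assert_proportion(hub_fraction, "hub_fraction")
  assert_proportion(disruption_gamma, "disruption_gamma")
  assert_proportion(abs(base_corr), "abs(base_corr)")
  assert_proportion(abs(hub_corr), "abs(hub_corr)")
  assert_scalar_number(tr, "tr", positive = TRUE)
  spec <- list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    n_nodes = as.integer(n_nodes), n_timepoints = as.integer(n_timepoints),
    tr = tr, n_sessions = as.integer(n_sessions),
    hub_fraction = hub_fraction, base_corr = base_corr, hub_corr = hub_corr,
    disruption_gamma = disruption_gamma, periphery_boost = periphery_boost,
    noise_sd = noise_sd, temporal_ar1 = temporal_ar1,
    subject_corr_jitter = subject_corr_jitter,
    subject_hub_sd = subject_hub_sd,
    seed = as.integer(seed)
  )
  assert_proportion(subject_corr_jitter, "subject_corr_jitter")
  assert_scalar_number(subject_hub_sd, "subject_hub_sd")
  structure(spec, class = "cohort_spec")
}

#' @method print cohort_spec
#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_spec> %d controls + %d patients, %d nodes/hemisphere, ",
           "%d timepoints @ TR %g s, %d session(s)\n",
           "  hubs: %.0f%% at r = %g over base %g; gamma = %g, seed = %d\n"),
    x$n_controls, x$n_patients, x$n_nodes, x$n_timepoints, x$tr,
    x$n_sessions, 100 * x$hub_fraction, x$hub_corr, x$base_corr,
    x$disruption_gamma, x$seed
  ))
  invisible(x)
}

# eigenvalue floor used to declare a matrix acceptably PSD
.psd_tol <- 1e-10

repair_psd <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -.psd_tol) {
    return(list(sigma = sigma, repaired = FALSE))
  }
  rep <- tryCatch(Matrix::nearPD(sigma, corr = TRUE, maxit = 500),
                  warning = function(w) NULL, error = function(e) NULL)
  if (!is.null(rep) && rep$converged) {
    return(list(sigma = as.matrix(rep$mat), repaired = TRUE))
  }
  # eigenvalue clipping as fallback: still a valid correlation matrix,
  # slightly further from the target than the Higham projection
  ed <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  fixed <- ed$vectors %*% (pmax(ed$values, 1e-8) * t(ed$vectors))
  fixed <- stats::cov2cor(fixed)
  ev2 <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) < -.psd_tol) {
    abort("Correlation targets are infeasible: PSD repair failed.")
  }
  list(sigma = fixed, repaired = TRUE)
}

#' Hub-structured target covariance
#'
#' Builds a correlation matrix in which designated hub nodes carry elevated
#' correlation (`hub_corr`) to every node while non-hub pairs sit at
#' `base_corr`; the nearest positive-semi-definite correlation matrix is
#' substituted (and flagged) if the targets are not directly feasible.
#'
#' @param spec A [cohort_spec()].
#' @return Correlation matrix with attributes `hubs` (node indices),
#'   `base_corr` and `repaired`.
#' @export
make_hub_covariance <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_nodes
  n_hubs <- round(spec$hub_fraction * n)
  hubs <- seq_len(n_hubs)
  sigma <- matrix(spec$base_corr, n, n)
  if (n_hubs > 0) {
    sigma[hubs, ] <- spec$hub_corr
    sigma[, hubs] <- spec$hub_corr
  }
  diag(sigma) <- 1
  fixed <- repair_psd(sigma)
  structure(fixed$sigma, hubs = hubs, base_corr = spec$base_corr,
            repaired = fixed$repaired)
}

#' Attenuate hub correlations toward the background level
#'
#' Moves every correlation involving a hub toward `base_corr` by factor
#' `gamma` (`gamma = 0`: untouched; `gamma = 1`: hubs indistinguishable from
#' the background), and optionally raises non-hub (periphery) correlations.
#' PSD repair is applied as in [make_hub_covariance()].
#'
#' @param cov Matrix from [make_hub_covariance()] (attribute `hubs`).
#' @param gamma Attenuation strength in \[0, 1\].
#' @param periphery_boost Added to non-hub pair correlations (capped at
#'   0.99).
#' @return Correlation matrix with the same attributes.
#' @export
apply_hub_disruption <- function(cov, gamma, periphery_boost = 0) {
  assert_proportion(gamma, "gamma")
  hubs <- attr(cov, "hubs")
  base <- attr(cov, "base_corr")
  sigma <- unclass(cov)
  attributes(sigma) <- list(dim = dim(cov))
  if (length(hubs) > 0 && gamma > 0) {
    touch <- matrix(FALSE, nrow(sigma), ncol(sigma))
    touch[hubs, ] <- TRUE
    touch[, hubs] <- TRUE
    diag(touch) <- FALSE
    sigma[touch] <- base + (sigma[touch] - base) * (1 - gamma)
  }
  if (periphery_boost != 0) {
    periph <- setdiff(seq_len(nrow(sigma)), hubs)
    blk <- sigma[periph, periph]
    blk <- pmin(blk + periphery_boost, 0.99)
    diag(blk) <- 1
    sigma[periph, periph] <- blk
  }
  fixed <- repair_psd(sigma)
  structure(fixed$sigma, hubs = hubs, base_corr = base,
            repaired = fixed$repaired || isTRUE(attr(cov, "repaired")))
}

#' Simulate one subject's regional time series
#'
#' Zero-mean Gaussian series with the given spatial correlation and AR(1)
#' temporal structure (stationary unit variance), plus white observation
#' noise.
#'
#' @param cov Spatial correlation/covariance matrix.
#' @param n_timepoints Number of timepoints (>= 64, for wavelet-scale
#'   support).
#' @param tr Repetition time in seconds.
#' @param ar1 Lag-1 autocorrelation in \[0, 1).
#' @param noise_sd White-noise SD added to every series.
#' @param seed Integer seed or `NULL`.
#' @param regions Region tibble (one row per covariance row); autogenerated
#'   left-hemisphere labels when `NULL`.
#' @inheritParams ts_matrix
#' @return A [ts_matrix()].
#' @export
simulate_subject <- function(cov, n_timepoints, tr, ar1 = 0, noise_sd = 0,
                             seed = NULL, regions = NULL,
                             subject_id = NA_character_,
                             session_id = NA_character_) {
  n <- nrow(cov)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 64) {
    abort("`n_timepoints` must be >= 64 for wavelet-scale support.")
  }
  if (ar1 < 0 || ar1 >= 1) abort("`ar1` must lie in [0, 1).")
  ed <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  root <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  if (is.null(regions)) {
    regions <- tibble::tibble(
      region_id = seq_len(n), name = sprintf("region_%02d", seq_len(n)),
      hemisphere = "left", homologue_id = NA_integer_
    )
  }
  data <- with_seed(seed, {
    innov <- matrix(rnorm(n * n_timepoints), n, n_timepoints)
    if (ar1 > 0) {
      init <- rnorm(n)
      lat <- matrix(0, n, n_timepoints)
      scale_innov <- sqrt(1 - ar1^2)
      prev <- init
      for (t_i in seq_len(n_timepoints)) {
        prev <- ar1 * prev + scale_innov * innov[, t_i]
        lat[, t_i] <- prev
      }
    } else {
      lat <- innov
    }
    sig <- root %*% lat
    if (noise_sd > 0) {
      sig <- sig + noise_sd * matrix(rnorm(n * n_timepoints), n, n_timepoints)
    }
    sig
  })
  ts_matrix(data, tr = tr, regions = regions,
            subject_id = subject_id, session_id = session_id)
}

#' Simulate a full two-hemisphere control + patient cohort
#'
#' Controls are drawn from the intact hub-structured covariance in both
#' hemispheres; each patient has one (contralesional) hemisphere drawn from
#' the hub-disrupted covariance and the other from the intact one. By
#' default 55% of patients have a right contralesional hemisphere and 45% a
#' left one (11 + 9 at the default group size), mirroring the lesion-side
#' split of a clinical arm. Hemispheres are generated as independent blocks
#' with homologous node naming.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `series` (named list of
#'   [ts_matrix()], key `subject.session.hemisphere`), `manifest` (tibble:
#'   `subject_id`, `group`, `session_id`, `hemisphere`, `lesion_side`,
#'   `contralesional`, `disrupted`, `key`), `ground_truth` (hub region ids
#'   per hemisphere, gamma, spec echo), `regions` (both hemispheres,
#'   homologue-paired).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  regions <- make_parcellation(spec$n_nodes, n_midline = 0)
  left_regions <- regions[regions$hemisphere == "left", ]
  right_regions <- regions[regions$hemisphere == "right", ]
  intact <- make_hub_covariance(spec)
  disrupted <- apply_hub_disruption(intact, spec$disruption_gamma,
                                    spec$periphery_boost)
  n_contra_right <- round(0.55 * spec$n_patients)
  manifest <- tidyr::expand_grid(
    subject_id = c(sprintf("ctl%02d", seq_len(spec$n_controls)),
                   sprintf("pat%02d", seq_len(spec$n_patients))),
    session_id = sprintf("ses%d", seq_len(spec$n_sessions)),
    hemisphere = c("left", "right")
  ) |>
    dplyr::mutate(
      group = ifelse(startsWith(.data$subject_id, "ctl"), "control",
                     "patient"),
      contralesional_side = dplyr::case_when(
        .data$group == "control" ~ NA_character_,
        as.integer(substr(.data$subject_id, 4, 5)) <= n_contra_right ~ "right",
        TRUE ~ "left"
      ),
      lesion_side = dplyr::case_when(
        .data$contralesional_side == "right" ~ "left",
        .data$contralesional_side == "left" ~ "right",
        TRUE ~ NA_character_
      ),
      contralesional = .data$hemisphere == .data$contralesional_side,
      disrupted = !is.na(.data$contralesional) & .data$contralesional,
      key = paste(.data$subject_id, .data$session_id, .data$hemisphere,
                  sep = ".")
    )
  # Stable individual connectivity, shared across a subject's sessions:
  # (a) a per-subject multiplier on hub correlation strength (individual
  # differences along the hub gradient -- what makes kappa trait-like), and
  # (b) a diffuse random-correlation blend. Disruption is applied to the
  # subject's own hub structure on the contralesional side.
  traits <- dplyr::distinct(manifest, .data$subject_id, .data$hemisphere,
                            .data$disrupted)
  trait_seeds <- derive_seeds(spec$seed + 1L, 2L * nrow(traits))
  w <- spec$subject_corr_jitter
  n <- spec$n_nodes
  hubs <- attr(intact, "hubs")
  traits$cov <- purrr::map(seq_len(nrow(traits)), function(i) {
    mult <- with_seed(trait_seeds[i], {
      max(0.2, min(1.8, 1 + rnorm(1, sd = spec$subject_hub_sd)))
    })
    hub_corr_i <- spec$base_corr +
      (spec$hub_corr - spec$base_corr) * mult
    hub_corr_i <- min(hub_corr_i, 0.85)
    sig <- matrix(spec$base_corr, n, n)
    if (length(hubs) > 0) {
      sig[hubs, ] <- hub_corr_i
      sig[, hubs] <- hub_corr_i
    }
    diag(sig) <- 1
    sig <- structure(sig, hubs = hubs, base_corr = spec$base_corr)
    if (traits$disrupted[i]) {
      sig <- apply_hub_disruption(sig, spec$disruption_gamma,
                                  spec$periphery_boost)
    }
    sig <- unclass(sig)
    if (w > 0) {
      jit <- with_seed(trait_seeds[nrow(traits) + i], {
        stats::cov2cor(crossprod(matrix(rnorm(n * (n + 5)), n + 5, n)))
      })
      sig <- (1 - w) * sig + w * (jit + t(jit)) / 2
      diag(sig) <- 1
    }
    repair_psd(sig)$sigma
  })
  seeds <- derive_seeds(spec$seed, nrow(manifest))
  series <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    cov_i <- traits$cov[[which(traits$subject_id == row$subject_id &
                                 traits$hemisphere == row$hemisphere)]]
    simulate_subject(
      cov_i,
      n_timepoints = spec$n_timepoints, tr = spec$tr,
      ar1 = spec$temporal_ar1, noise_sd = spec$noise_sd,
      seed = seeds[i],
      regions = if (row$hemisphere == "left") left_regions else right_regions,
      subject_id = row$subject_id, session_id = row$session_id
    )
  })
  names(series) <- manifest$key
  structure(
    list(
      series = series, manifest = manifest,
      ground_truth = list(
        hub_region_ids = list(
          left = left_regions$region_id[attr(intact, "hubs")],
          right = right_regions$region_id[attr(intact, "hubs")]
        ),
        gamma = spec$disruption_gamma,
        covariance_repaired = isTRUE(attr(intact, "repaired")) ||
          isTRUE(attr(disrupted, "repaired")),
        spec = unclass(spec)
      ),
      regions = regions
    ),
    class = "synthetic_cohort"
  )
}

#' @method print synthetic_cohort
#' @export
print.synthetic_cohort <- function(x, ...) {
  gt <- x$ground_truth$spec
  cat(sprintf(
    "<synthetic_cohort> %d controls + %d patients, %d sessions, %d series\n",
    gt$n_controls, gt$n_patients, gt$n_sessions, length(x$series)
  ))
  invisible(x)
}

#' Synthesize a nodal profile with a known hub disruption slope
#'
#' Constructs `profile_i = (1 + a) * ref_i + noise`, so that regressing the
#' profile-minus-reference difference on the reference recovers slope `a`
#' (exactly when `noise_sd = 0`).
#'
#' @param ref A [reference_profile()].
#' @param a Target slope.
#' @param noise_sd Gaussian noise SD added per node.
#' @param seed Integer seed or `NULL`.
#' @return Tibble with columns `node_id` and `value`, aligned with `ref`.
#' @export
make_profile_with_slope <- function(ref, a, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(ref, "reference_profile"))
  eps <- with_seed(seed, rnorm(nrow(ref), sd = noise_sd))
  tibble::tibble(node_id = ref$node_key,
                 value = (1 + a) * ref$value + eps)
}

#' Write a synthetic cohort to a directory tree
#'
#' One TSV per series under `series/`, the manifest as TSV, the region table
#' as TSV, and the ground truth (hub ids, gamma, spec) as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "series"), recursive = TRUE,
             showWarnings = FALSE)
  for (key in names(cohort$series)) {
    write_ts_tsv(cohort$series[[key]],
                 file.path(dir, "series", paste0(key, ".tsv")))
  }
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(cohort$regions, file.path(dir, "regions.tsv"))
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
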