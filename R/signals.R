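#' Construct a regional time-series matrix
#'
#' The basic signal container of the pipeline: one row per region, one column
#' per timepoint, with the repetition time (TR) and region definitions
#' attached. All downstream wavelet and correlation operations consume this
#' object.
#'
#' @param data Numeric matrix, regions x timepoints. Row names, if absent, are
#'   set from `regions$region_id`.
#' @param tr Repetition time in seconds.
#' @param regions Region tibble ([make_parcellation()]); must have one row per
#'   matrix row, in matrix row order.
#' @param subject_id,session_id Identifiers carried as provenance.
#' @return An object of class `ts_matrix`.
#' @export
ts_matrix <- function(data, tr, regions, subject_id = NA_character_,
                      session_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  assert_scalar_number(tr, "tr", positive = TRUE)
  validate_regions(regions)
  if (nrow(data) != nrow(regions)) {
    abort("`data` must have one row per region.")
  }
  if (anyNA(data)) abort("Time series must not contain missing values.")
  if (ncol(data) < 2) abort("Need at least 2 timepoints.")
  rownames(data) <- as.character(regions$region_id)
  structure(
    list(data = data, tr = tr, regions = regions,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id)),
    class = "ts_matrix"
  )
}

#' @method print ts_matrix
#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf(
    "<ts_matrix> %d regions x %d timepoints, TR = %g s (subject %s, session %s)\n",
    nrow(x$data), ncol(x$data), x$tr, x$subject_id, x$session_id
  ))
  invisible(x)
}

#' @export
dim.ts_matrix <- function(x) dim(x$data)

#' Extract gray-matter-weighted regional mean time series
#'
#' For each labelled region, averages the functional signal over its voxels
#' at every timepoint, weighting each voxel by its gray-matter probability.
#' The weighting suppresses contamination from white matter and CSF without
#' applying any hard gray-matter threshold: a zero-probability voxel simply
#' contributes nothing.
#'
#' @param fmri 4D numeric array (x, y, z, time), e.g. as returned by
#'   `RNifti::readNifti()`.
#' @param labels 3D integer array of region labels (0 = background), same
#'   spatial grid as `fmri`.
#' @param gm_prob 3D array of gray-matter probabilities in \[0, 1\], same grid.
#' @param regions Region tibble; every `region_id` must have at least one
#'   voxel with positive weight.
#' @param tr Repetition time in seconds.
#' @inheritParams ts_matrix
#' @return A [ts_matrix()] with one row per region, in `regions` order.
#' @export
extract_regional_series <- function(fmri, labels, gm_prob, regions, tr,
                                    subject_id = NA_character_,
                                    session_id = NA_character_) {
  fmri <- unclass(fmri); labels <- unclass(labels); gm_prob <- unclass(gm_prob)
  df <- dim(fmri)
  if (length(df) != 4) abort("`fmri` must be a 4D array (x, y, z, time).")
  if (!identical(dim(labels), df[1:3]) || !identical(dim(gm_prob), df[1:3])) {
    abort("`labels` and `gm_prob` must share the spatial grid of `fmri`.")
  }
  if (any(gm_prob < 0 | gm_prob > 1, na.rm = TRUE)) {
    abort("`gm_prob` values must lie in [0, 1].")
  }
  validate_regions(regions)
  n_t <- df[4]
  vol <- matrix(fmri, nrow = prod(df[1:3]), ncol = n_t)
  lab <- as.integer(labels)
  w <- as.numeric(gm_prob)
  out <- matrix(NA_real_, nrow = nrow(regions), ncol = n_t)
  for (r in seq_len(nrow(regions))) {
    id <- regions$region_id[r]
    vox <- which(lab == id & w > 0)
    total <- sum(w[vox])
    if (length(vox) == 0 || total <= 0) {
      abort(sprintf("Region %d (%s) has no voxel with positive GM weight.",
                    id, regions$name[r]))
    }
    out[r, ] <- crossprod(vol[vox, , drop = FALSE], w[vox]) / total
  }
  ts_matrix(out, tr = tr, regions = regions,
            subject_id = subject_id, session_id = session_id)
}

#' Regress nuisance signals out of regional time series
#'
#' Replaces every regional series by its least-squares residual against a
#' design made of an intercept, the confound columns (e.g. motion
#' parameters), and one indicator column per flagged outlier volume. Spike
#' (indicator) regression rather than volume deletion keeps the sampling
#' regular, which the wavelet transform requires.
#'
#' @param ts A [ts_matrix()].
#' @param confounds Numeric matrix, timepoints x regressors, or `NULL`.
#' @param outlier_flags Logical vector per timepoint, or `NULL`.
#' @return A [ts_matrix()] of residuals (same shape and metadata).
#' @export
regress_nuisance <- function(ts, confounds = NULL, outlier_flags = NULL) {
  stopifnot(inherits(ts, "ts_matrix"))
  n_t <- ncol(ts$data)
  design <- matrix(1, nrow = n_t, ncol = 1,
                   dimnames = list(NULL, "intercept"))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n_t) {
      abort("`confounds` rows must align with timepoints.")
    }
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- sprintf("confound_%d", seq_len(ncol(confounds)))
    }
    design <- cbind(design, confounds)
  }
  if (!is.null(outlier_flags)) {
    outlier_flags <- as.logical(outlier_flags)
    if (length(outlier_flags) != n_t) {
      abort("`outlier_flags` must have one entry per timepoint.")
    }
    for (t_i in which(outlier_flags)) {
      spike <- numeric(n_t)
      spike[t_i] <- 1
      design <- cbind(design, spike)
      colnames(design)[ncol(design)] <- sprintf("spike_%d", t_i)
    }
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(paste0("Nuisance design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  resid <- t(qr.resid(qrd, t(ts$data)))
  dimnames(resid) <- dimnames(ts$data)
  out <- ts
  out$data <- resid
  out
}

#' Motion quality control on outlier volume counts
#'
#' A scan passes when the fraction of flagged (outlier) volumes does not
#' exceed the threshold; the conventional cutoff rejects scans with more than
#' 12% of volumes flagged.
#'
#' @param n_volumes Total number of fMRI volumes.
#' @param outlier_flags Logical vector of per-volume outlier flags, or an
#'   integer count of outliers.
#' @param threshold Maximum tolerated rejected fraction (default 0.12).
#' @return A one-row tibble with `n_volumes`, `n_outliers`,
#'   `fraction_rejected` and `passed`.
#' @examples
#' motion_qc(400, 48)  # exactly 12%: passes
#' motion_qc(400, 49)  # 12.25%: fails
#' @export
motion_qc <- function(n_volumes, outlier_flags, threshold = 0.12) {
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 1) abort("`n_volumes` must be >= 1.")
  n_outliers <- if (is.logical(outlier_flags)) {
    sum(outlier_flags)
  } else {
    as.integer(outlier_flags)
  }
  if (n_outliers < 0 || n_outliers > n_volumes) {
    abort("Outlier count must lie in [0, n_volumes].")
  }
  frac <- n_outliers / n_volumes
  tibble::tibble(
    n_volumes = n_volumes,
    n_outliers = n_outliers,
    fraction_rejected = frac,
    passed = frac <= threshold
  )
}

#' Write a regional time-series matrix as TSV
#'
#' First column `region_id`, one column per timepoint (`t1`, `t2`, ...).
#'
#' @param ts A [ts_matrix()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_ts_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "ts_matrix"))
  out <- tibble::as_tibble(as.data.frame(ts$data),
                           .name_repair = ~ sprintf("t%d", seq_along(.x)))
  out <- dplyr::bind_cols(
    tibble::tibble(region_id = ts$regions$region_id), out
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a regional time-series matrix from TSV
#'
#' @param path TSV written by [write_ts_tsv()] (first column `region_id`).
#' @param tr Repetition time in seconds.
#' @param regions Region tibble; reconstructed (all-left, no homologues)
#'   from the ids when `NULL`.
#' @inheritParams ts_matrix
#' @return A [ts_matrix()].
#' @export
read_ts_tsv <- function(path, tr, regions = NULL,
                        subject_id = NA_character_,
                        session_id = NA_character_) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.integer(tab[[1]])
  data <- as.matrix(tab[, -1, drop = FALSE])
  if (is.null(regions)) {
    regions <- tibble::tibble(
      region_id = ids, name = sprintf("region_%02d", ids),
      hemisphere = "left", homologue_id = NA_integer_
    )
  } else {
    regions <- regions[match(ids, regions$region_id), ]
  }
  ts_matrix(data, tr = tr, regions = regions,
            subject_id = subject_id, session_id = session_id)
}
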