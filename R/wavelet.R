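# Orthonormal scaling filters (sum = sqrt(2)). "la8" is the Daubechies
# least-asymmetric 8-tap filter, the default for wavelet correlation of fMRI
# series; "d4" and "haar" are provided for short series and cross-checks.
.scaling_filters <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  d4 = c(0.48296291314453416, 0.83651630373780794,
         0.22414386804201339, -0.12940952255126037),
  la8 = c(0.032223100604042702, -0.012603967262037833,
          -0.099219543576847216, 0.29785779560527736,
          0.80373875180591614, 0.49761866763201545,
          -0.02963552764599851, -0.075765714789273325)
)

wavelet_filter <- function(filter_name = c("la8", "d4", "haar")) {
  filter_name <- match.arg(filter_name)
  g <- .scaling_filters[[filter_name]]
  L <- length(g)
  # quadrature mirror: h_l = (-1)^l g_{L-1-l}
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  list(name = filter_name, g = g, h = h, length = L)
}

#' Nyquist frequency of a sampling interval
#'
#' @param tr Repetition time (sampling interval) in seconds.
#' @return Maximum resolvable frequency `1 / (2 * tr)` in Hz.
#' @examples
#' nyquist_frequency(0.72) # 0.694 Hz
#' nyquist_frequency(2.0)  # 0.25 Hz
#' @export
nyquist_frequency <- function(tr) {
  assert_scalar_number(tr, "tr", positive = TRUE)
  1 / (2 * tr)
}

#' Dyadic frequency band of a wavelet scale
#'
#' Scale `j` spans the interval `(nyquist / 2^j, nyquist / 2^(j-1))`:
#' successive scales halve the band and together tile the full spectrum.
#'
#' @inheritParams nyquist_frequency
#' @param scale Positive integer wavelet scale.
#' @return Named numeric vector `c(f_low, f_high)` in Hz.
#' @examples
#' scale_band(0.72, 4) # ~0.043-0.087 Hz
#' @export
scale_band <- function(tr, scale) {
  f_n <- nyquist_frequency(tr)
  scale <- as.integer(scale)
  if (scale < 1) abort("`scale` must be >= 1.")
  c(f_low = f_n / 2^scale, f_high = f_n / 2^(scale - 1))
}

#' Select the wavelet scale for low-frequency connectivity
#'
#' Resting-state connectivity is carried by fluctuations below ~0.1 Hz; this
#' picks the smallest (finest) scale whose whole dyadic band lies at or below
#' the ceiling.
#'
#' @inheritParams nyquist_frequency
#' @param f_ceiling Upper frequency bound in Hz (default 0.1).
#' @param max_scale Largest scale to consider before giving up.
#' @return Integer scale.
#' @examples
#' select_scale(0.72) # 4
#' select_scale(2.0)  # 3
#' @export
select_scale <- function(tr, f_ceiling = 0.1, max_scale = 30L) {
  assert_scalar_number(f_ceiling, "f_ceiling", positive = TRUE)
  f_n <- nyquist_frequency(tr)
  for (j in seq_len(max_scale)) {
    if (f_n / 2^(j - 1) <= f_ceiling) {
      return(j)
    }
  }
  abort("No wavelet scale has its full band below `f_ceiling`.")
}

# Number of coefficients at scale j affected by circular boundary wrap:
# L_j - 1 with L_j = (2^j - 1) (L - 1) + 1.
modwt_n_boundary <- function(filter_length, scale) {
  (2^scale - 1) * (filter_length - 1)
}

#' Maximal overlap discrete wavelet transform
#'
#' Undecimated (maximal-overlap) wavelet decomposition by circular filtering:
#' each scale yields a detail-coefficient series of the original length, plus
#' a final smooth. The transform is linear and preserves energy exactly:
#' `sum(x^2) = sum_j sum(W_j^2) + sum(V_J^2)`.
#'
#' The first `(2^j - 1) * (L - 1)` coefficients at scale `j` (filter length
#' `L`) are affected by the circular wrap-around; their count is reported in
#' `n_boundary` so correlation estimation can exclude them.
#'
#' @param x Numeric vector, or matrix with one series per column.
#' @param max_scale Deepest scale to compute.
#' @param filter_name One of `"la8"` (default), `"d4"`, `"haar"`.
#' @return A list of class `modwt` with elements `details` (list of length
#'   `max_scale`; each a vector/matrix like `x`), `smooth`, `n_boundary`
#'   (per-scale boundary-coefficient counts), `filter_name` and `n`.
#' @export
modwt <- function(x, max_scale, filter_name = c("la8", "d4", "haar")) {
  filt <- wavelet_filter(match.arg(filter_name))
  vec_in <- is.null(dim(x))
  x <- as.matrix(x)
  if (anyNA(x)) abort("Series must not contain missing values.")
  n <- nrow(x)
  max_scale <- as.integer(max_scale)
  if (max_scale < 1) abort("`max_scale` must be >= 1.")
  l_max <- modwt_n_boundary(filt$length, max_scale) + 1
  if (n < l_max) {
    abort(sprintf(
      paste0("Series of length %d is too short for scale %d with the %s ",
             "filter (needs >= %d timepoints); use fewer scales."),
      n, max_scale, filt$name, l_max
    ))
  }
  # MODWT filters are the orthonormal pair rescaled by 1/sqrt(2); level-j
  # filtering is level-1 filtering with taps upsampled by 2^(j-1), which in
  # the Fourier domain is index dilation of the transfer function.
  hf <- fft(c(filt$h / sqrt(2), numeric(n - filt$length)))
  gf <- fft(c(filt$g / sqrt(2), numeric(n - filt$length)))
  vf <- mvfft(x)
  details <- vector("list", max_scale)
  for (j in seq_len(max_scale)) {
    idx <- (((seq_len(n) - 1) * 2^(j - 1)) %% n) + 1
    wj <- Re(mvfft(vf * hf[idx], inverse = TRUE)) / n
    vf <- vf * gf[idx]
    details[[j]] <- if (vec_in) drop(wj) else wj
  }
  smooth <- Re(mvfft(vf, inverse = TRUE)) / n
  structure(
    list(
      details = details,
      smooth = if (vec_in) drop(smooth) else smooth,
      n_boundary = vapply(seq_len(max_scale), function(j) {
        min(modwt_n_boundary(filt$length, j), n)
      }, numeric(1)),
      filter_name = filt$name,
      n = n
    ),
    class = "modwt"
  )
}

#' Wavelet specification for a correlation matrix
#'
#' @inheritParams nyquist_frequency
#' @param scale Wavelet scale used.
#' @param filter_name Wavelet filter name.
#' @param boundary_rule Boundary handling description.
#' @return A list of class `wavelet_spec` with the dyadic band attached.
#' @export
wavelet_spec <- function(tr, scale, filter_name = "la8",
                         boundary_rule = "periodic; boundary coefficients excluded") {
  band <- scale_band(tr, scale)
  structure(
    list(tr = tr, scale = as.integer(scale), band = band,
         filter_name = filter_name, boundary_rule = boundary_rule),
    class = "wavelet_spec"
  )
}

#' @method print wavelet_spec
#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> scale %d (%.4f-%.4f Hz), TR = %g s, %s filter\n",
              x$scale, x$band[["f_low"]], x$band[["f_high"]], x$tr,
              x$filter_name))
  invisible(x)
}

#' Scale-specific wavelet correlation matrix
#'
#' Decomposes every regional series with the MODWT and computes the Pearson
#' correlation of the detail coefficients at one scale for every region pair.
#' Coefficients affected by the circular boundary are excluded to avoid
#' wrap-around bias.
#'
#' @param ts A [ts_matrix()].
#' @param scale Wavelet scale; `NULL` (default) selects it from the TR via
#'   [select_scale()].
#' @param filter_name Wavelet filter (default `"la8"`).
#' @param exclude_boundary Drop boundary-affected coefficients before
#'   correlating (default `TRUE`).
#' @return An object of class `corr_matrix`: fields `values` (symmetric
#'   matrix, unit diagonal), `spec` ([wavelet_spec()]), `regions`,
#'   `subject_id`, `session_id`, `hemisphere_scope`.
#' @export
wavelet_cor <- function(ts, scale = NULL, filter_name = "la8",
                        exclude_boundary = TRUE) {
  stopifnot(inherits(ts, "ts_matrix"))
  scale <- scale %||% select_scale(ts$tr)
  dec <- modwt(t(ts$data), max_scale = scale, filter_name = filter_name)
  w <- dec$details[[scale]]
  if (exclude_boundary) {
    nb <- dec$n_boundary[scale]
    if (nb >= nrow(w) - 1) {
      abort("Too few interior coefficients left after boundary exclusion.")
    }
    w <- w[-seq_len(nb), , drop = FALSE]
  }
  sds <- apply(w, 2, sd)
  if (any(sds == 0)) {
    bad <- ts$regions$region_id[sds == 0]
    abort(paste0("Zero-variance detail coefficients for region(s): ",
                 paste(bad, collapse = ", ")))
  }
  vals <- stats::cor(w)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  dimnames(vals) <- list(ts$regions$region_id, ts$regions$region_id)
  corr_matrix(vals, spec = wavelet_spec(ts$tr, scale, filter_name),
              regions = ts$regions, subject_id = ts$subject_id,
              session_id = ts$session_id)
}

#' Construct a correlation-matrix object
#'
#' @param values Symmetric correlation matrix with unit diagonal.
#' @param spec A [wavelet_spec()] (or `NULL` for correlations of other
#'   provenance).
#' @param regions Region tibble aligned with the matrix rows.
#' @param subject_id,session_id,hemisphere_scope Provenance.
#' @return An object of class `corr_matrix`.
#' @export
corr_matrix <- function(values, spec = NULL, regions = NULL,
                        subject_id = NA_character_,
                        session_id = NA_character_,
                        hemisphere_scope = "all") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("Correlation matrix must be square.")
  if (max(abs(values - t(values))) > 1e-8) {
    abort("Correlation matrix must be symmetric.")
  }
  if (any(abs(values) > 1 + 1e-8)) {
    abort("Correlation entries must lie in [-1, 1].")
  }
  if (is.null(regions)) {
    ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
    regions <- tibble::tibble(
      region_id = as.integer(seq_len(nrow(values))),
      name = as.character(ids), hemisphere = "left",
      homologue_id = NA_integer_
    )
  }
  if (nrow(regions) != nrow(values)) {
    abort("`regions` must have one row per matrix row.")
  }
  dimnames(values) <- list(regions$region_id, regions$region_id)
  structure(
    list(values = values, spec = spec, regions = regions,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         hemisphere_scope = hemisphere_scope),
    class = "corr_matrix"
  )
}

#' @method print corr_matrix
#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d x %d (%s hemisphere scope)\n",
              nrow(x$values), ncol(x$values), x$hemisphere_scope))
  if (!is.null(x$spec)) print(x$spec)
  invisible(x)
}
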