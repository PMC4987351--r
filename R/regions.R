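#' Build a parcellation region table
#'
#' Defines the node set of the analysis: `n_per_hemisphere` regions per
#' hemisphere plus optional midline regions (e.g. the cerebellar vermis).
#' Left/right regions are paired as homologues by position, mirroring
#' AAL-style templates where each cortical region has a contralateral
#' counterpart. Midline regions have no homologue and are dropped from
#' intra-hemispheric analyses.
#'
#' @param n_per_hemisphere Number of regions per hemisphere (default 44, the
#'   size of each hemisphere in an 89-region whole-brain template with one
#'   midline region).
#' @param n_midline Number of midline regions without a homologue (default 1).
#' @param names Optional character vector of base region names (recycled with
#'   `L`/`R` prefixes); autogenerated when `NULL`.
#' @return A tibble with columns `region_id` (integer), `name`,
#'   `hemisphere` (`"left"`, `"right"` or `"midline"`) and `homologue_id`
#'   (`NA` for midline regions).
#' @examples
#' parc <- make_parcellation()
#' nrow(parc) # 89
#' table(parc$hemisphere)
#' @export
make_parcellation <- function(n_per_hemisphere = 44, n_midline = 1,
                              names = NULL) {
  n_per_hemisphere <- as.integer(n_per_hemisphere)
  n_midline <- as.integer(n_midline)
  if (n_per_hemisphere < 1) abort("`n_per_hemisphere` must be >= 1.")
  base <- names %||% sprintf("region_%02d", seq_len(n_per_hemisphere))
  if (length(base) != n_per_hemisphere) {
    abort("`names` must have length `n_per_hemisphere`.")
  }
  left_ids <- seq_len(n_per_hemisphere)
  right_ids <- n_per_hemisphere + seq_len(n_per_hemisphere)
  mid_ids <- 2L * n_per_hemisphere + seq_len(n_midline)
  tbl <- dplyr::bind_rows(
    tibble::tibble(
      region_id = left_ids, name = paste0("L_", base),
      hemisphere = "left", homologue_id = right_ids
    ),
    tibble::tibble(
      region_id = right_ids, name = paste0("R_", base),
      hemisphere = "right", homologue_id = left_ids
    ),
    if (n_midline > 0) {
      tibble::tibble(
        region_id = mid_ids,
        name = sprintf("M_midline_%02d", seq_len(n_midline)),
        hemisphere = "midline", homologue_id = NA_integer_
      )
    }
  )
  validate_regions(tbl)
  tbl
}

#' Validate a region table
#'
#' Checks the structural invariants of a region definition table: unique
#' region ids, a one-to-one left/right homologue pairing, and no homologue on
#' midline regions.
#'
#' @param regions A region tibble as returned by [make_parcellation()].
#' @return The table, invisibly, on success; otherwise an error.
#' @export
validate_regions <- function(regions) {
  req <- c("region_id", "name", "hemisphere", "homologue_id")
  missing <- setdiff(req, names(regions))
  if (length(missing) > 0) {
    abort(paste0("Region table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(regions$region_id)) {
    abort("Region ids must be unique.")
  }
  bad_side <- setdiff(unique(regions$hemisphere),
                      c("left", "right", "midline"))
  if (length(bad_side) > 0) {
    abort(paste0("Unknown hemisphere label(s): ",
                 paste(bad_side, collapse = ", ")))
  }
  mid <- regions$hemisphere == "midline"
  if (any(!is.na(regions$homologue_id[mid]))) {
    abort("Midline regions must not declare a homologue.")
  }
  lat <- regions[!mid, ]
  # homologues pointing outside the table are fine (single-hemisphere
  # subsets); pairs present together must be one-to-one and cross-sided
  with_hom <- lat[!is.na(lat$homologue_id) &
                    lat$homologue_id %in% regions$region_id, ]
  if (nrow(with_hom) > 0) {
    idx <- match(with_hom$homologue_id, regions$region_id)
    back <- regions$homologue_id[idx]
    if (anyDuplicated(with_hom$homologue_id) ||
        !identical(back, with_hom$region_id)) {
      abort("Homologue mapping must be a one-to-one left/right pairing.")
    }
    same_side <- regions$hemisphere[idx] == with_hom$hemisphere
    if (any(same_side)) {
      abort("A homologue must lie in the opposite hemisphere.")
    }
  }
  invisible(regions)
}

#' Homologous left/right region pairs
#'
#' @param regions A region tibble.
#' @return A tibble with columns `left_id` and `right_id`, ordered by
#'   `left_id`; midline regions are excluded.
#' @export
homologue_pairs <- function(regions) {
  validate_regions(regions)
  left <- regions[regions$hemisphere == "left" & !is.na(regions$homologue_id), ]
  tibble::tibble(left_id = left$region_id, right_id = left$homologue_id) |>
    dplyr::arrange(.data$left_id)
}
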