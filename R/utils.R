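#' Evaluate an expression with a local, restorable RNG state
#'
#' All stochastic operations in the package route their `seed` argument
#' through this helper so that a call is reproducible without clobbering the
#' caller's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use (and advance) the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

assert_proportion <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

#' Write a matrix as TSV with row identifiers in the first column
#' @keywords internal
#' @noRd
write_matrix_tsv <- function(mat, path, id_col = "region_id") {
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  out <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := ids), out)
  readr::write_tsv(out, path)
  invisible(path)
}

read_matrix_tsv <- function(path, id_col = "region_id") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- ids
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
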