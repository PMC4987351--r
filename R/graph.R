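#' Restrict a correlation matrix to one hemisphere
#'
#' Takes the principal submatrix over the requested hemisphere's regions.
#' Midline regions (no contralateral homologue) are excluded, so an 89-region
#' whole-brain matrix with one midline region yields a 44 x 44
#' intra-hemispheric matrix. Node order is preserved.
#'
#' @param corr A [corr_matrix()].
#' @param side `"left"` or `"right"`.
#' @return A [corr_matrix()] over that hemisphere's regions.
#' @export
subset_hemisphere <- function(corr, side = c("left", "right")) {
  stopifnot(inherits(corr, "corr_matrix"))
  side <- match.arg(side)
  keep <- which(corr$regions$hemisphere == side)
  if (length(keep) == 0) {
    abort(sprintf("No regions on the %s side.", side))
  }
  corr_matrix(
    corr$values[keep, keep, drop = FALSE],
    spec = corr$spec,
    regions = corr$regions[keep, ],
    subject_id = corr$subject_id,
    session_id = corr$session_id,
    hemisphere_scope = side
  )
}

#' Maximum-|r| spanning tree backbone
#'
#' Prim's algorithm on edge weights `1 - |r|`: the resulting spanning tree
#' collects the strongest absolute correlations while guaranteeing
#' connectivity, and seeds the cost-thresholded graph. Ties are broken
#' lexicographically on node index, making the tree deterministic.
#'
#' @param corr A [corr_matrix()] (or a plain symmetric matrix).
#' @return Integer matrix with `N - 1` rows and columns `i`, `j`
#'   (`i < j`, positions in the node order).
#' @export
mst_backbone <- function(corr) {
  a <- if (inherits(corr, "corr_matrix")) abs(corr$values) else abs(as.matrix(corr))
  n <- nrow(a)
  if (n < 2) abort("Need at least 2 nodes for a spanning tree.")
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  # best[v]: strongest |r| from v into the tree; parent[v]: the tree end.
  best <- a[1, ]
  parent <- rep(1L, n)
  edges <- matrix(0L, nrow = n - 1, ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    # max |r|; ties resolved by smallest parent index then smallest node index
    b <- best[cand]
    top <- cand[b == max(b)]
    if (length(top) > 1) {
      p <- parent[top]
      top <- top[p == min(p)]
      top <- min(top)
    }
    v <- top
    in_tree[v] <- TRUE
    edges[k, ] <- sort(c(parent[v], v))
    upd <- !in_tree & (a[v, ] > best |
                         (a[v, ] == best & v < parent))
    parent[upd] <- v
    best[upd] <- a[v, upd]
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

#' Threshold a correlation matrix to a fixed-cost connected binary graph
#'
#' Cost is the fraction of realized edges among all `N (N - 1) / 2` node
#' pairs; the target edge count is `M = round(cost * N (N - 1) / 2)`
#' (banker's rounding). The maximum-|r| spanning tree is always included to
#' keep the graph connected, and the remaining `M - (N - 1)` edges are the
#' strongest non-tree absolute correlations. The realized |r| cutoff is
#' recorded as `threshold_r`.
#'
#' @param corr A [corr_matrix()].
#' @param cost Target cost in (0, 1]; must leave room for the spanning tree.
#' @return An object of class `binary_graph`: `adjacency` (0/1 symmetric
#'   matrix), `n_nodes`, `n_edges`, `cost` (realized), `threshold_r`,
#'   `regions`, provenance fields.
#' @export
threshold_to_cost <- function(corr, cost) {
  stopifnot(inherits(corr, "corr_matrix"))
  assert_proportion(cost, "cost")
  a <- abs(corr$values)
  n <- nrow(a)
  n_pairs <- n * (n - 1) / 2
  m <- round(cost * n_pairs)
  if (m < n - 1) {
    abort(sprintf(
      "cost %.4f gives M = %d < N - 1 = %d edges; minimum feasible cost is %.4f.",
      cost, m, n - 1, (n - 1) / n_pairs
    ))
  }
  mst <- mst_backbone(corr)
  adj <- matrix(0L, n, n)
  adj[mst] <- 1L
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  vals <- a[pairs]
  in_mst <- adj[pairs] == 1L
  free <- which(!in_mst)
  # strongest first; ties lexicographic on (i, j) for determinism and
  # cost-monotonic edge sets
  ord <- free[order(-vals[free], pairs[free, 1], pairs[free, 2])]
  n_extra <- m - (n - 1)
  take <- head(ord, n_extra)
  threshold_r <- if (n_extra > 0) min(vals[take]) else min(a[mst])
  adj[pairs[take, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  adj[adj > 1] <- 1L
  diag(adj) <- 0L
  binary_graph(adj, regions = corr$regions, threshold_r = threshold_r,
               subject_id = corr$subject_id, session_id = corr$session_id,
               hemisphere_scope = corr$hemisphere_scope,
               scale = if (!is.null(corr$spec)) corr$spec$scale else NA_integer_)
}

#' Construct a binary graph object
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param regions Region tibble aligned with the nodes (optional).
#' @param threshold_r Realized |correlation| cutoff, if any.
#' @param subject_id,session_id,hemisphere_scope,scale Provenance.
#' @param check_connected Error when the graph is disconnected (default TRUE).
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, regions = NULL, threshold_r = NA_real_,
                         subject_id = NA_character_,
                         session_id = NA_character_,
                         hemisphere_scope = "all", scale = NA_integer_,
                         check_connected = TRUE) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) abort("Adjacency must be square.")
  if (!all(adjacency %in% c(0L, 1L))) abort("Adjacency must be 0/1.")
  if (any(diag(adjacency) != 0L)) abort("Adjacency diagonal must be zero.")
  if (!identical(adjacency, t(adjacency))) abort("Adjacency must be symmetric.")
  m <- sum(adjacency) / 2
  if (is.null(regions)) {
    regions <- tibble::tibble(
      region_id = seq_len(n), name = sprintf("node_%02d", seq_len(n)),
      hemisphere = "left", homologue_id = NA_integer_
    )
  }
  if (nrow(regions) != n) abort("`regions` must have one row per node.")
  dimnames(adjacency) <- list(regions$region_id, regions$region_id)
  g <- structure(
    list(adjacency = adjacency, n_nodes = n, n_edges = as.integer(m),
         cost = m / (n * (n - 1) / 2), threshold_r = threshold_r,
         regions = regions, subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         hemisphere_scope = hemisphere_scope, scale = scale),
    class = "binary_graph"
  )
  if (check_connected && !is_connected_graph(g)) {
    abort("Graph is disconnected.")
  }
  g
}

is_connected_graph <- function(g) {
  comp <- igraph::components(as_igraph(g))
  comp$no == 1L
}

#' Convert a binary graph to an igraph object
#'
#' @param g A [binary_graph()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' @method print binary_graph
#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf(
    "<binary_graph> N = %d, M = %d (cost %.3f, |r| threshold %.3f, %s)\n",
    x$n_nodes, x$n_edges, x$cost, x$threshold_r, x$hemisphere_scope
  ))
  invisible(x)
}

#' Edge list of a binary graph
#'
#' @param g A [binary_graph()].
#' @return Tibble with columns `i`, `j` (node positions, `i < j`) and
#'   `region_i`, `region_j` (region ids).
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  idx <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  tibble::tibble(
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    region_i = g$regions$region_id[idx[, 1]],
    region_j = g$regions$region_id[idx[, 2]]
  ) |>
    dplyr::arrange(.data$i, .data$j)
}
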