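#' Nodal degree
#'
#' Number of edges incident to each node; over a graph the degrees sum to
#' twice the edge count.
#'
#' @param g A [binary_graph()].
#' @return Integer vector, one value per node.
#' @export
node_degree <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  as.integer(rowSums(g$adjacency))
}

#' Nodal global efficiency
#'
#' Inverse harmonic mean of the shortest-path lengths from a node to every
#' other node: `Eg_i = mean over j != i of 1 / L_ij`, with `1 / Inf = 0` for
#' unreachable nodes. Equal to 1 on a complete graph.
#'
#' @param g A [binary_graph()].
#' @return Numeric vector in \[0, 1\], one value per node.
#' @export
nodal_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- igraph::distances(as_igraph(g))
  inv <- 1 / d
  diag(inv) <- 0
  as.numeric(rowSums(inv) / (g$n_nodes - 1))
}

#' Nodal betweenness centrality
#'
#' Sum over unordered node pairs (excluding the node itself) of the fraction
#' of shortest paths between the pair that pass through the node;
#' unnormalized.
#'
#' @param g A [binary_graph()].
#' @return Numeric vector, one value per node.
#' @export
node_betweenness <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  as.numeric(igraph::betweenness(as_igraph(g), directed = FALSE,
                                 normalized = FALSE))
}

#' Nodal local efficiency
#'
#' Efficiency of the subgraph induced by a node's neighbors: the average over
#' ordered neighbor pairs of the inverse shortest-path length computed
#' *within* that subgraph. Nodes with fewer than two neighbors score 0.
#'
#' @param g A [binary_graph()].
#' @return Numeric vector in \[0, 1\], one value per node.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  adj <- g$adjacency
  vapply(seq_len(g$n_nodes), function(i) {
    nb <- which(adj[i, ] == 1L)
    k <- length(nb)
    if (k < 2) {
      return(0)
    }
    sub <- igraph::graph_from_adjacency_matrix(
      adj[nb, nb, drop = FALSE], mode = "undirected", diag = FALSE
    )
    d <- igraph::distances(sub)
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

#' Nodal clustering coefficient
#'
#' Fraction of realized edges among each node's neighbor pairs,
#' `C_i = 2 t_i / (D_i (D_i - 1))` with `t_i` the number of triangles through
#' the node. Nodes with fewer than two neighbors score 0.
#'
#' @param g A [binary_graph()].
#' @return Numeric vector in \[0, 1\], one value per node.
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  a <- g$adjacency
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  c_i <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  as.numeric(c_i)
}

#' All five nodal metrics of a graph
#'
#' Computes degree (`D`), nodal global efficiency (`Eg`), betweenness (`B`),
#' local efficiency (`El`) and clustering (`C`) in one pass.
#'
#' @param g A [binary_graph()].
#' @return A tibble with columns `node_id`, `D`, `Eg`, `B`, `El`, `C`;
#'   provenance (`subject_id`, `session_id`, `hemisphere`, `cost`) is carried
#'   in attributes and by [profile_long()].
#' @export
metric_profile <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  out <- tibble::tibble(
    node_id = g$regions$region_id,
    D = node_degree(g),
    Eg = nodal_efficiency(g),
    B = node_betweenness(g),
    El = local_efficiency(g),
    C = clustering_coefficient(g)
  )
  attr(out, "subject_id") <- g$subject_id
  attr(out, "session_id") <- g$session_id
  attr(out, "hemisphere") <- g$hemisphere_scope
  attr(out, "cost") <- g$cost
  out
}

#' Reshape a metric profile to long format with provenance columns
#'
#' @param profile A tibble from [metric_profile()].
#' @return Long tibble with columns `subject_id`, `session_id`, `hemisphere`,
#'   `cost`, `node_id`, `metric`, `value`.
#' @export
profile_long <- function(profile) {
  tidyr::pivot_longer(profile, cols = c("D", "Eg", "B", "El", "C"),
                      names_to = "metric", values_to = "value") |>
    dplyr::mutate(
      subject_id = attr(profile, "subject_id") %||% NA_character_,
      session_id = attr(profile, "session_id") %||% NA_character_,
      hemisphere = attr(profile, "hemisphere") %||% NA_character_,
      cost = attr(profile, "cost") %||% NA_real_,
      .before = 1
    )
}

#' Node-averaged (global) metric summary
#'
#' @param profile A tibble from [metric_profile()].
#' @return One-row tibble of the arithmetic mean over nodes of each metric.
#' @export
global_summary <- function(profile) {
  dplyr::summarise(
    profile,
    dplyr::across(c("D", "Eg", "B", "El", "C"), mean)
  )
}
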