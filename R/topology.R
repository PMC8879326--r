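#' Topological distance matrix
#'
#' Shortest-path lengths between heavy atoms on the
#' hydrogen-suppressed molecular graph.
#'
#' @param mol an `af_molecule`.
#' @return symmetric integer matrix with zero diagonal, one row/column
#'   per heavy atom (in atom-table order).
#' @export
topo_distance_matrix <- function(mol) {
  hg <- heavy_graph(mol)
  if (!igraph::is_connected(hg$graph)) {
    stop("hydrogen-suppressed graph is disconnected; standardize() first")
  }
  d <- igraph::distances(hg$graph)
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

## heavy-atom degrees in the H-suppressed graph
heavy_degrees <- function(mol) {
  hg <- heavy_graph(mol)
  as.numeric(igraph::degree(hg$graph))
}

## heavy-atom adjacency (0/1) in H-suppressed graph
heavy_adjacency <- function(mol) {
  hg <- heavy_graph(mol)
  a <- as.matrix(igraph::as_adjacency_matrix(hg$graph, sparse = FALSE))
  dimnames(a) <- NULL
  a
}
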