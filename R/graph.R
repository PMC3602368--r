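#' Build a dispersal-threshold graph
#'
#' Nodes are the sites suitable in the chosen epoch; two nodes share an edge
#' when the inter-site distance is less than *or equal to* the species'
#' dispersal distance (the threshold is inclusive). For the `"future"` epoch
#' only range contraction is modelled: a site is a future node only if it is
#' suitable both currently and under the future scenario, so the future
#' graph is always an induced subgraph of the current one.
#'
#' @param sites A site table (see [validate_sites()]).
#' @param dispersal_km Dispersal-distance threshold in km (> 0).
#' @param epoch `"current"` or `"future"`.
#' @param distances Optional precomputed distance matrix (km) covering all
#'   selected sites; when `NULL`, distances are computed with
#'   [pairwise_distances()] in `distance_mode`.
#' @param distance_mode Mode for computed distances; `"centroid"` (default
#'   for graph topology) or `"edge_approx"`.
#' @return A `dispersal_graph`: a list with the igraph `graph`, the node
#'   `sites` tibble, the node-subset `distances` matrix, and the
#'   `threshold`, `distance_mode` and `epoch` used.
#' @examples
#' g <- build_graph(worked_fixture(), dispersal_km = 10)
#' g
#' @export
build_graph <- function(sites, dispersal_km,
                        epoch = c("current", "future"),
                        distances = NULL,
                        distance_mode = c("centroid", "edge_approx",
                                          "matrix")) {
  epoch <- match.arg(epoch)
  distance_mode <- match.arg(distance_mode)
  stopifnot(is.numeric(dispersal_km), length(dispersal_km) == 1,
            dispersal_km > 0)
  sites <- validate_sites(sites)

  keep <- if (epoch == "current") {
    sites$suitable_current
  } else {
    sites$suitable_current & sites$suitable_future
  }
  nodes <- sites[keep, , drop = FALSE]
  if (nrow(nodes) == 0) {
    warning("no suitable sites in epoch \"", epoch,
            "\"; returning an empty graph", call. = FALSE)
  }

  if (is.null(distances)) {
    if (distance_mode == "matrix") {
      stop("distance_mode = \"matrix\" requires a precomputed `distances` ",
           "matrix", call. = FALSE)
    }
    d <- if (nrow(nodes) > 0) pairwise_distances(nodes, distance_mode) else
      matrix(numeric(0), 0, 0)
  } else {
    check_distance_matrix(distances)
    d <- subset_distances(distances, nodes$site_id)
  }

  g <- if (nrow(nodes) > 0) {
    adj <- (d <= dispersal_km)
    diag(adj) <- FALSE
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }

  structure(
    list(graph = g, sites = nodes, distances = d,
         threshold = dispersal_km, distance_mode = distance_mode,
         epoch = epoch),
    class = "dispersal_graph")
}

#' @export
print.dispersal_graph <- function(x, ...) {
  cat(sprintf(
    "Dispersal-threshold graph (%s epoch): %d nodes, %d edges, threshold %g km (%s distances)\n",
    x$epoch, igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$threshold, x$distance_mode))
  invisible(x)
}

#' Node and edge tables of a dispersal graph
#'
#' @param graph A `dispersal_graph`.
#' @return `graph_nodes()` returns the node site tibble; `graph_edges()` a
#'   tibble `source, target, distance_km`, one row per undirected edge.
#' @export
graph_nodes <- function(graph) {
  stopifnot(inherits(graph, "dispersal_graph"))
  graph$sites
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "dispersal_graph"))
  if (igraph::ecount(graph$graph) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          distance_km = numeric()))
  }
  el <- igraph::as_edgelist(graph$graph, names = TRUE)
  tibble::tibble(
    source = el[, 1],
    target = el[, 2],
    distance_km = graph$distances[cbind(el[, 1], el[, 2])])
}
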