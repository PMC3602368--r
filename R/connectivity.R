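#' Maximum-product-probability paths
#'
#' For the habitat-weighted indices every pair of sites is a potential link:
#' the direct dispersal probability is `p_ij = p(d_ij)` under the kernel,
#' and the *path* probability of connecting i and j is the maximum, over all
#' paths, of the product of step probabilities — any site can serve as a
#' stepping stone. Taking `-log` turns products into sums, so the maximum
#' product is found exactly by Dijkstra shortest paths on the complete graph
#' with weights `-log p_ij`. By convention `p*_ii = 1`.
#'
#' @param distances Symmetric distance matrix in km (site ids as dimnames).
#' @param kernel A [dispersal_kernel()].
#' @return Symmetric matrix `p*` with unit diagonal, same dimnames.
#' @examples
#' s <- worked_fixture()
#' p <- max_product_paths(pairwise_distances(s, "edge_approx"),
#'                        dispersal_kernel(10))
#' @export
max_product_paths <- function(distances, kernel) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  check_distance_matrix(unclass_dist(distances))
  ids <- rownames(distances)
  n <- nrow(distances)
  if (n == 1) {
    return(matrix(1, 1, 1, dimnames = list(ids, ids)))
  }
  w <- kernel$rate * distances  # -log p, elementwise
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  el <- data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                   weight = w[pairs])
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = ids))
  D <- igraph::distances(g, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  D <- D[ids, ids, drop = FALSE]
  pstar <- exp(-D)
  diag(pstar) <- 1
  pstar
}

unclass_dist <- function(d) {
  attr(d, "distance_mode") <- NULL
  d
}

#' Equivalent Connected Area
#'
#' The probability-of-connectivity numerator is
#' `PCnum = sum_i sum_j a_i a_j p*_ij` (ha^2), summed over *all* ordered
#' pairs including `i = j` (with `p*_ii = 1`), where `a_i` are habitat areas
#' in hectares and `p*` the maximum-product path probabilities. The
#' Equivalent Connected Area is `ECA = sqrt(PCnum)` (ha): the size of a
#' single perfectly connected patch that would give the same connectivity.
#' ECA equals the total habitat area when all `p* = 1` and falls to
#' `sqrt(sum a_i^2)` when every pair is fully disconnected.
#'
#' @param sites A site table (rows must match `p_star`'s dimnames).
#' @param p_star A max-product path probability matrix from
#'   [max_product_paths()].
#' @return A list with `pc_numerator` (ha^2), `eca` (ha) and `total_area`
#'   (ha).
#' @examples
#' s <- worked_fixture()
#' p <- max_product_paths(pairwise_distances(s, "edge_approx"),
#'                        dispersal_kernel(10))
#' eca(s, p)$eca
#' @export
eca <- function(sites, p_star) {
  sites <- validate_sites(sites)
  if (nrow(sites) == 0) {
    return(list(pc_numerator = 0, eca = 0, total_area = 0))
  }
  stopifnot(identical(rownames(p_star), sites$site_id))
  a <- sites$area_ha
  pc <- as.numeric(t(a) %*% p_star %*% a)
  list(pc_numerator = pc, eca = sqrt(pc), total_area = sum(a))
}

#' Generalized Betweenness Centrality
#'
#' GBC weights classical betweenness by what actually flows through a node:
#' for each unordered pair `{i, j}` (both distinct from `k`) whose optimal
#' (maximum-product) path passes through `k`, node `k` accrues
#' `a_i a_j p*_ij` (ha^2). A node lies on an optimal i-j path exactly when
#' `-log p*_ik - log p*_kj = -log p*_ij` (within a small tolerance); when
#' several optimal paths tie, the pair contributes to every node on at
#' least one of them.
#'
#' @inheritParams max_product_paths
#' @param sites A site table aligned with `distances`.
#' @param tol Relative tolerance for detecting ties between optimal paths.
#' @return A tibble `site_id, gbc_ha2`.
#' @export
gbc <- function(sites, distances, kernel, tol = 1e-9) {
  sites <- validate_sites(sites)
  n <- nrow(sites)
  if (n == 0) return(tibble::tibble(site_id = character(),
                                    gbc_ha2 = numeric()))
  stopifnot(identical(rownames(distances), sites$site_id))
  if (n <= 2) {
    return(tibble::tibble(site_id = sites$site_id, gbc_ha2 = rep(0, n)))
  }
  w <- kernel$rate * distances
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  ids <- sites$site_id
  el <- data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                   weight = w[pairs])
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = ids))
  D <- igraph::distances(g, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")[ids, ids, drop = FALSE]
  pstar <- exp(-D); diag(pstar) <- 1
  a <- sites$area_ha
  contrib <- outer(a, a) * pstar
  diag(contrib) <- 0
  slack <- tol * (1 + abs(D))
  val <- vapply(seq_len(n), function(k) {
    on_path <- (outer(D[, k], D[k, ], "+") - D) <= slack
    on_path[k, ] <- FALSE
    on_path[, k] <- FALSE
    diag(on_path) <- FALSE
    sum(contrib[on_path]) / 2  # symmetric: each unordered pair counted twice
  }, numeric(1))
  tibble::tibble(site_id = ids, gbc_ha2 = val)
}

#' Habitat-weighted connectivity indices for one epoch
#'
#' Convenience wrapper computing [max_product_paths()], [eca()] and [gbc()]
#' on the sites suitable in the chosen epoch, using edge-to-edge
#' approximated distances by default (a precomputed matrix may be supplied
#' instead).
#'
#' @inheritParams build_graph
#' @param kernel A [dispersal_kernel()].
#' @param distance_mode Distance mode for habitat indices; default
#'   `"edge_approx"`.
#' @return A `connectivity_indices` object: `pc_numerator` (ha^2), `eca`
#'   (ha), `total_area` (ha), `gbc` (tibble), `kernel`, `n_sites`.
#' @examples
#' connectivity_indices(worked_fixture(), dispersal_kernel(10))
#' @export
connectivity_indices <- function(sites, kernel,
                                 epoch = c("current", "future"),
                                 distances = NULL,
                                 distance_mode = c("edge_approx", "centroid",
                                                   "matrix")) {
  epoch <- match.arg(epoch)
  distance_mode <- match.arg(distance_mode)
  stopifnot(inherits(kernel, "dispersal_kernel"))
  sites <- validate_sites(sites)
  keep <- if (epoch == "current") sites$suitable_current else
    sites$suitable_current & sites$suitable_future
  nodes <- sites[keep, , drop = FALSE]
  if (nrow(nodes) == 0) {
    out <- list(pc_numerator = 0, eca = 0, total_area = 0,
                gbc = tibble::tibble(site_id = character(),
                                     gbc_ha2 = numeric()),
                kernel = kernel, epoch = epoch, n_sites = 0L)
    return(structure(out, class = "connectivity_indices"))
  }
  if (is.null(distances)) {
    if (distance_mode == "matrix") {
      stop("distance_mode = \"matrix\" requires a `distances` matrix",
           call. = FALSE)
    }
    d <- pairwise_distances(nodes, distance_mode)
  } else {
    check_distance_matrix(distances)
    d <- subset_distances(distances, nodes$site_id)
  }
  pstar <- max_product_paths(d, kernel)
  e <- eca(nodes, pstar)
  structure(
    list(pc_numerator = e$pc_numerator, eca = e$eca,
         total_area = e$total_area,
         gbc = gbc(nodes, d, kernel),
         kernel = kernel, epoch = epoch, n_sites = nrow(nodes)),
    class = "connectivity_indices")
}

#' @export
print.connectivity_indices <- function(x, ...) {
  cat(sprintf(
    "Connectivity indices (%s epoch, %d sites): ECA = %.1f ha of %.1f ha total (PCnum = %.4g ha^2)\n",
    x$epoch, x$n_sites, x$eca, x$total_area, x$pc_numerator))
  invisible(x)
}

#' Relative change in area and in Equivalent Connected Area
#'
#' `dA = 100 (A_fut - A_cur) / A_cur` and
#' `dECA = 100 (ECA_fut - ECA_cur) / ECA_cur`, both in percent. Under pure
#' range contraction both are typically negative; `dECA > dA` flags a
#' comparatively *weaker* impact on connectivity than on raw habitat area
#' (the lost sites mattered less than average for connectivity).
#'
#' @param current,future Objects carrying `eca` and `total_area` in ha
#'   ([connectivity_indices()] results, or plain lists with those fields).
#' @return A list `dA`, `dECA` (percent, full precision) and
#'   `weaker_impact` (`dECA > dA`).
#' @examples
#' d_metrics(list(eca = 6348903, total_area = 13381774),
#'           list(eca = 5592091, total_area = 11631070))
#' @export
d_metrics <- function(current, future) {
  stopifnot(is.numeric(current$eca), is.numeric(future$eca),
            is.numeric(current$total_area), is.numeric(future$total_area))
  if (current$total_area <= 0 || current$eca <= 0) {
    stop("current area/ECA must be > 0 to express relative change",
         call. = FALSE)
  }
  kc <- current$kernel; kf <- future$kernel
  if (!is.null(kc) && !is.null(kf) &&
      !isTRUE(all.equal(kc$half_distance_km, kf$half_distance_km))) {
    warning("current and future indices use different kernels", call. = FALSE)
  }
  dA <- 100 * (future$total_area - current$total_area) / current$total_area
  dECA <- 100 * (future$eca - current$eca) / current$eca
  list(dA = dA, dECA = dECA, weaker_impact = dECA > dA)
}

#' Half-up rounding
#'
#' Rounds halves away from zero (`round_half_up(14.745, 2)` is 14.75, and
#' `-11.915` rounds to `-11.92`), the convention used for reported
#' percentages; base `round()` rounds halves to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
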