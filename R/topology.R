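#' Connected components and articulation points
#'
#' A component is a maximal set of mutually reachable nodes; its *order* is
#' its node count, and an order-1 component is an isolated site. An
#' articulation point (cut node) is a node whose removal increases the
#' number of components — a single site whose loss would split a group of
#' reserves into disconnected parts. Components are labelled 1, 2, ... in
#' decreasing order of size (ties broken by smallest member id) so labels
#' are deterministic.
#'
#' @param graph A `dispersal_graph`.
#' @return A `component_summary`: list with `membership` (tibble `site_id`,
#'   `component_id`), `orders` (int vector, decreasing), `n_components`,
#'   `n_isolated`, `largest_order`, `smallest_order`, `mean_order`,
#'   `sd_order`, and `articulation_points` (character vector of site ids).
#' @examples
#' summarize_components(build_graph(worked_fixture(), 10))
#' @export
summarize_components <- function(graph) {
  stopifnot(inherits(graph, "dispersal_graph"))
  g <- graph$graph
  n <- igraph::vcount(g)
  if (n == 0) {
    out <- list(
      membership = tibble::tibble(site_id = character(),
                                  component_id = integer()),
      orders = integer(0), n_components = 0L, n_isolated = 0L,
      largest_order = 0L, smallest_order = 0L,
      mean_order = NA_real_, sd_order = NA_real_,
      articulation_points = character(0))
    return(structure(out, class = "component_summary"))
  }
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  ## deterministic relabelling: by decreasing size, ties by smallest member
  first_member <- vapply(seq_len(comp$no), function(k) {
    min(ids[comp$membership == k])
  }, character(1))
  ord <- order(-comp$csize, first_member)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  membership <- tibble::tibble(
    site_id = ids,
    component_id = relabel[comp$membership])
  orders <- as.integer(comp$csize[ord])
  art <- igraph::articulation_points(g)
  structure(list(
    membership = membership,
    orders = orders,
    n_components = as.integer(comp$no),
    n_isolated = sum(orders == 1L),
    largest_order = max(orders),
    smallest_order = min(orders),
    mean_order = mean(orders),
    sd_order = if (length(orders) > 1) sd(orders) else NA_real_,
    articulation_points = sort(ids[as.integer(art)])),
    class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf(
    "%d component(s), %d isolated node(s); orders %s; %d articulation point(s)\n",
    x$n_components, x$n_isolated,
    paste(head(x$orders, 10), collapse = "/"),
    length(x$articulation_points)))
  invisible(x)
}

#' Per-node topology metrics
#'
#' Computes, for every node of the graph:
#'
#' * **degree** — number of incident edges (sites within one dispersal step);
#' * **betweenness** — fraction of all-pairs shortest paths passing through
#'   the node, normalized by `(n-1)(n-2)/2` with `n` the *total* number of
#'   graph nodes (one normalizer for the whole, possibly fragmented,
#'   network); pairs in different components contribute nothing, tied
#'   shortest paths split their contribution equally; all zeros when n < 3;
#' * **clustering** — fraction of a node's neighbour pairs that are
#'   themselves adjacent; nodes of degree < 2 are assigned 0 and kept in
#'   any mean, so the network mean stays defined on fragmented graphs;
#' * **component_id** — label from [summarize_components()].
#'
#' @param graph A `dispersal_graph`.
#' @return A tibble `site_id, degree, betweenness, clustering, component_id`.
#' @export
node_metrics <- function(graph) {
  stopifnot(inherits(graph, "dispersal_graph"))
  g <- graph$graph
  n <- igraph::vcount(g)
  if (n == 0) {
    return(tibble::tibble(site_id = character(), degree = integer(),
                          betweenness = numeric(), clustering = numeric(),
                          component_id = integer()))
  }
  deg <- igraph::degree(g)
  btw <- if (n < 3) rep(0, n) else
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  clu <- igraph::transitivity(g, type = "local", isolates = "NaN")
  clu[!is.finite(clu)] <- 0
  comp <- summarize_components(graph)
  tibble::tibble(site_id = igraph::V(g)$name,
                 degree = as.integer(deg),
                 betweenness = as.numeric(btw),
                 clustering = as.numeric(clu)) |>
    dplyr::left_join(comp$membership, by = "site_id")
}

#' Degree distribution and Poisson goodness of fit
#'
#' In a random (Erdos-Renyi-like) network the node-degree distribution is
#' approximately Poisson, whereas scale-free networks show a heavy power-law
#' tail. `degree_distribution_summary()` tabulates the degree histogram and,
#' when the graph has at least 20 nodes, fits a Poisson by the method of
#' moments (`lambda_hat` = mean degree) and tests goodness of fit;
#' below 20 nodes the fit is refused and only the histogram is returned.
#'
#' The test is a chi-square on binned degree counts against expected
#' `Poisson(lambda_hat)` frequencies: degree bins are pooled left-to-right
#' (tail lumped) until every expected count is at least 5, and the degrees
#' of freedom are `bins - 2` (one for the total, one for the estimated
#' rate). With fewer than 3 pooled bins the fit is undefined and flagged.
#'
#' @param graph A `dispersal_graph`.
#' @param degrees An integer vector of node degrees.
#' @return `degree_distribution_summary()`: list with `histogram` (tibble
#'   `degree, count`), `fit` (a `poisson_fit` or `NULL` when refused) and
#'   `n`. `poisson_fit()`: object of class `poisson_fit` with `lambda_hat`,
#'   `statistic`, `df`, `p_value`, `fit_ok`, and the pooled `bins` tibble.
#' @export
degree_distribution_summary <- function(graph) {
  stopifnot(inherits(graph, "dispersal_graph"))
  deg <- as.integer(igraph::degree(graph$graph))
  n <- length(deg)
  hist <- if (n == 0) {
    tibble::tibble(degree = integer(), count = integer())
  } else {
    tab <- table(factor(deg, levels = 0:max(deg)))
    tibble::tibble(degree = as.integer(names(tab)),
                   count = as.integer(tab))
  }
  fit <- if (n >= 20) poisson_fit(deg) else NULL
  list(histogram = hist, fit = fit, n = n)
}

#' @rdname degree_distribution_summary
#' @export
poisson_fit <- function(degrees) {
  degrees <- as.integer(degrees)
  n <- length(degrees)
  if (n < 20) {
    stop("Poisson fit refused: needs at least 20 degrees, got ", n,
         call. = FALSE)
  }
  lambda <- mean(degrees)
  kmax <- max(degrees)
  ## expected probabilities for 0..kmax-1 plus the lumped tail >= kmax
  p <- c(dpois(0:max(kmax - 1, 0), lambda), ppois(kmax - 1, lambda,
                                                  lower.tail = FALSE))
  obs <- tabulate(degrees + 1L, nbins = kmax + 1L)
  expected <- n * p

  ## pool adjacent bins left-to-right until each expected >= 5
  pooled_obs <- numeric(0); pooled_exp <- numeric(0); labels <- character(0)
  acc_o <- 0; acc_e <- 0; start <- 0L
  for (k in seq_along(expected)) {
    acc_o <- acc_o + obs[k]; acc_e <- acc_e + expected[k]
    if (acc_e >= 5 || k == length(expected)) {
      pooled_obs <- c(pooled_obs, acc_o)
      pooled_exp <- c(pooled_exp, acc_e)
      labels <- c(labels, if (start == k - 1L) as.character(start) else
        paste0(start, "-", k - 1L))
      acc_o <- 0; acc_e <- 0; start <- k
    }
  }
  ## a trailing underfilled bin was appended above; merge it back if < 5
  nb <- length(pooled_exp)
  if (nb > 1 && pooled_exp[nb] < 5) {
    pooled_obs[nb - 1] <- pooled_obs[nb - 1] + pooled_obs[nb]
    pooled_exp[nb - 1] <- pooled_exp[nb - 1] + pooled_exp[nb]
    labels[nb - 1] <- paste0(sub("-.*", "", labels[nb - 1]), "+")
    pooled_obs <- pooled_obs[-nb]; pooled_exp <- pooled_exp[-nb]
    labels <- labels[-nb]
    nb <- nb - 1
  }

  bins <- tibble::tibble(bin = labels, observed = pooled_obs,
                         expected = pooled_exp)
  if (nb < 3) {
    out <- list(lambda_hat = lambda, statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_, fit_ok = FALSE,
                reason = "fewer than 3 pooled bins: fit undefined",
                bins = bins, n = n)
    return(structure(out, class = "poisson_fit"))
  }
  stat <- sum((pooled_obs - pooled_exp)^2 / pooled_exp)
  df <- nb - 2L
  structure(list(lambda_hat = lambda, statistic = stat, df = as.integer(df),
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 fit_ok = TRUE, reason = NULL, bins = bins, n = n),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  if (x$fit_ok) {
    cat(sprintf(
      "Poisson fit: lambda = %.3f, X2 = %.3f on %d df, p = %.4g (n = %d)\n",
      x$lambda_hat, x$statistic, x$df, x$p_value, x$n))
  } else {
    cat(sprintf("Poisson fit undefined (lambda = %.3f, n = %d): %s\n",
                x$lambda_hat, x$n, x$reason))
  }
  invisible(x)
}
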