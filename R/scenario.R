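#' Compare current and future reserve networks
#'
#' Runs the whole comparison for one species: builds the current and future
#' dispersal-threshold graphs (future = pure range contraction, i.e. the
#' sites suitable in both epochs), summarizes components and per-node
#' topology metrics for each, computes the habitat-weighted indices and the
#' dA/dECA contrast, and books which nodes and components are lost.
#'
#' @param sites A site table.
#' @param dispersal_km Dispersal threshold in km.
#' @param kernel_half_distance_km Kernel anchor for the habitat indices;
#'   defaults to `dispersal_km` (the species' median dispersal distance).
#' @param distances Optional precomputed distance matrix used for *both*
#'   the graph and the indices (overrides the mode defaults).
#' @param topology_mode Distance mode for the threshold graph (default
#'   `"centroid"`).
#' @param habitat_mode Distance mode for ECA/GBC (default `"edge_approx"`).
#' @param indices Compute the habitat-weighted indices? Set `FALSE` to do a
#'   topology-only comparison (e.g. when site areas are placeholders).
#' @return A `scenario_comparison` with node counts (`n_current`,
#'   `n_future`, `n_lost`, `pct_lost`), `lost_ids`/`retained_ids`,
#'   `current_summary`/`future_summary` ([summarize_components()]),
#'   `current_metrics`/`future_metrics` ([node_metrics()]),
#'   `current_indices`/`future_indices`, `d` (from [d_metrics()]),
#'   `components_lost`, `split_events`, and `lost_by_component` (tibble
#'   `component_id, order, n_lost`).
#' @examples
#' cmp <- compare_scenarios(worked_fixture(), dispersal_km = 10)
#' glance(cmp)
#' @export
compare_scenarios <- function(sites, dispersal_km,
                              kernel_half_distance_km = dispersal_km,
                              distances = NULL,
                              topology_mode = "centroid",
                              habitat_mode = "edge_approx",
                              indices = TRUE) {
  sites <- validate_sites(sites)
  if (!any(sites$suitable_current)) {
    stop("no currently suitable sites", call. = FALSE)
  }
  cur <- build_graph(sites, dispersal_km, "current",
                     distances = distances, distance_mode = topology_mode)
  fut <- suppressWarnings(
    build_graph(sites, dispersal_km, "future",
                distances = distances, distance_mode = topology_mode))
  cur_sum <- summarize_components(cur)
  fut_sum <- summarize_components(fut)
  cur_met <- node_metrics(cur)
  fut_met <- node_metrics(fut)

  lost_ids <- sort(setdiff(cur$sites$site_id, fut$sites$site_id))
  retained_ids <- sort(fut$sites$site_id)
  n_current <- nrow(cur$sites)
  n_future <- nrow(fut$sites)
  n_lost <- n_current - n_future
  pct_lost <- 100 * n_lost / n_current

  change <- component_change(cur_sum, fut_sum, lost_ids)
  lost_by_component <- cur_sum$membership |>
    dplyr::mutate(order = table(.data$component_id)[
      as.character(.data$component_id)] |> as.integer()) |>
    dplyr::group_by(.data$component_id, .data$order) |>
    dplyr::summarise(
      n_lost = sum(.data$site_id %in% lost_ids), .groups = "drop") |>
    dplyr::arrange(.data$component_id)

  if (indices) {
    kernel <- dispersal_kernel(kernel_half_distance_km)
    cur_idx <- connectivity_indices(sites, kernel, "current",
                                    distances = distances,
                                    distance_mode = habitat_mode)
    fut_idx <- connectivity_indices(sites, kernel, "future",
                                    distances = distances,
                                    distance_mode = habitat_mode)
    d <- if (fut_idx$n_sites > 0 || cur_idx$eca > 0) {
      dm <- d_metrics(cur_idx, fut_idx)
      dm
    } else NULL
  } else {
    cur_idx <- NULL; fut_idx <- NULL; d <- NULL
  }

  structure(list(
    n_current = n_current, n_future = n_future, n_lost = n_lost,
    pct_lost = pct_lost,
    lost_ids = lost_ids, retained_ids = retained_ids,
    current_summary = cur_sum, future_summary = fut_sum,
    current_metrics = cur_met, future_metrics = fut_met,
    current_indices = cur_idx, future_indices = fut_idx,
    d = d,
    components_lost = change$components_lost,
    split_events = change$split_events,
    lost_by_component = lost_by_component,
    dispersal_km = dispersal_km,
    kernel_half_distance_km = kernel_half_distance_km,
    current_graph = cur, future_graph = fut),
    class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf(
    "Scenario comparison: %d -> %d nodes (%d lost, %.2f%%); components %d -> %d (%d lost, %d split)\n",
    x$n_current, x$n_future, x$n_lost, x$pct_lost,
    x$current_summary$n_components, x$future_summary$n_components,
    x$components_lost, x$split_events))
  if (!is.null(x$d)) {
    cat(sprintf("  dA = %.2f%%, dECA = %.2f%%, weaker impact on connectivity: %s\n",
                x$d$dA, x$d$dECA, x$d$weaker_impact))
  }
  invisible(x)
}

#' Component-level bookkeeping of a scenario
#'
#' A current component is *lost* when none of its nodes persist into the
#' future network; it *splits* when its surviving nodes fall into more than
#' one future component (the removal of an articulation point, for
#' instance).
#'
#' @param current_summary,future_summary [summarize_components()] results
#'   from the same site table.
#' @param lost_ids Site ids present currently but not in the future.
#' @return List with `components_lost` and `split_events` counts.
#' @export
component_change <- function(current_summary, future_summary, lost_ids) {
  stopifnot(inherits(current_summary, "component_summary"),
            inherits(future_summary, "component_summary"))
  fut_comp <- setNames(future_summary$membership$component_id,
                       future_summary$membership$site_id)
  by_comp <- split(current_summary$membership$site_id,
                   current_summary$membership$component_id)
  lost <- 0L; splits <- 0L
  for (members in by_comp) {
    surviving <- setdiff(members, lost_ids)
    if (length(surviving) == 0) {
      lost <- lost + 1L
    } else if (length(unique(fut_comp[surviving])) > 1) {
      splits <- splits + 1L
    }
  }
  list(components_lost = lost, split_events = splits)
}

#' Statistical comparison of lost vs retained nodes
#'
#' Applies the package's statistical layer to a [compare_scenarios()]
#' result: subset-resampling permutation tests on degree, betweenness and
#' GBC of lost vs retained nodes; Mann-Whitney U on the clustering
#' coefficient of lost vs retained nodes and on the orders of components
#' that lost nodes vs those left unchanged; and a Spearman correlation
#' between the number of nodes each component loses and its order.
#'
#' @param comparison A `scenario_comparison`.
#' @param n_perm Permutations for the resampling tests (default 999).
#' @param seed Integer seed for the resampling tests.
#' @param sidedness Sidedness of the permutation tests (default two-sided).
#' @return A tibble `metric, method, estimate, p_value, n_perm, seed`. Rows
#'   whose test is undefined for this comparison (e.g. no losses) are
#'   omitted.
#' @export
scenario_tests <- function(comparison, n_perm = 999, seed,
                           sidedness = "two_sided") {
  stopifnot(inherits(comparison, "scenario_comparison"))
  out <- list()
  met <- comparison$current_metrics
  lost <- comparison$lost_ids
  if (length(lost) > 0 && length(comparison$retained_ids) >= length(lost)) {
    vals <- list(degree = met$degree, betweenness = met$betweenness)
    if (!is.null(comparison$current_indices)) {
      g <- comparison$current_indices$gbc
      vals$gbc <- g$gbc_ha2[match(met$site_id, g$site_id)]
    }
    for (i in seq_along(vals)) {
      v <- vals[[i]]
      is_lost <- met$site_id %in% lost
      pr <- permutation_test(v[is_lost], v[!is_lost], n_perm = n_perm,
                             sidedness = sidedness, seed = seed + i)
      out[[length(out) + 1]] <- tibble::tibble(
        metric = names(vals)[i], method = "permutation",
        estimate = pr$observed_diff, p_value = pr$p_value,
        n_perm = n_perm, seed = seed + i)
    }
    is_lost <- met$site_id %in% lost
    mw <- mann_whitney_u(met$clustering[is_lost], met$clustering[!is_lost])
    out[[length(out) + 1]] <- tibble::tibble(
      metric = "clustering", method = "mann_whitney",
      estimate = mw$U, p_value = mw$p_value,
      n_perm = NA_integer_, seed = NA_integer_)
  }
  lb <- comparison$lost_by_component
  affected <- lb$order[lb$n_lost > 0]
  unchanged <- lb$order[lb$n_lost == 0]
  if (length(affected) > 0 && length(unchanged) > 0) {
    mw <- mann_whitney_u(affected, unchanged)
    out[[length(out) + 1]] <- tibble::tibble(
      metric = "component_order", method = "mann_whitney",
      estimate = mw$U, p_value = mw$p_value,
      n_perm = NA_integer_, seed = NA_integer_)
  }
  if (nrow(lb) >= 3 && sd(lb$n_lost) > 0 && sd(lb$order) > 0) {
    sp <- spearman_cor(lb$n_lost, lb$order)
    out[[length(out) + 1]] <- tibble::tibble(
      metric = "losses_vs_order", method = "spearman",
      estimate = sp$rho, p_value = sp$p_value,
      n_perm = NA_integer_, seed = NA_integer_)
  }
  if (length(out) == 0) {
    return(tibble::tibble(metric = character(), method = character(),
                          estimate = numeric(), p_value = numeric(),
                          n_perm = integer(), seed = integer()))
  }
  dplyr::bind_rows(out)
}
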