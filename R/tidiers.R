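#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects.
#'
#' * `tidy(scenario_comparison)` — one row per current-network node:
#'   topology metrics, GBC (when computed) and a `lost` flag.
#' * `glance(scenario_comparison)` — one-row network-level summary (counts,
#'   percent lost, component bookkeeping, ECA and dA/dECA when computed).
#' * `tidy(connectivity_indices)` — per-node GBC; `glance()` the scalar
#'   indices.
#' * `tidy(component_summary)` — one row per component; `glance()` the
#'   counts.
#' * `glance(permutation_result)`, `tidy(poisson_fit)`,
#'   `glance(poisson_fit)` — analogous.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy scenario_comparison
#' @export
tidy.scenario_comparison <- function(x, ...) {
  out <- x$current_metrics
  if (!is.null(x$current_indices) && nrow(x$current_indices$gbc) > 0) {
    out <- dplyr::left_join(out, x$current_indices$gbc, by = "site_id")
  }
  dplyr::mutate(out, lost = .data$site_id %in% x$lost_ids)
}

#' @rdname tidiers
#' @method glance scenario_comparison
#' @export
glance.scenario_comparison <- function(x, ...) {
  tibble::tibble(
    n_current = x$n_current, n_future = x$n_future, n_lost = x$n_lost,
    pct_lost = x$pct_lost,
    components_current = x$current_summary$n_components,
    components_future = x$future_summary$n_components,
    components_lost = x$components_lost,
    split_events = x$split_events,
    isolated_current = x$current_summary$n_isolated,
    isolated_future = x$future_summary$n_isolated,
    articulation_current = length(x$current_summary$articulation_points),
    articulation_future = length(x$future_summary$articulation_points),
    eca_current = if (!is.null(x$current_indices)) x$current_indices$eca
      else NA_real_,
    eca_future = if (!is.null(x$future_indices)) x$future_indices$eca
      else NA_real_,
    dA = if (!is.null(x$d)) x$d$dA else NA_real_,
    dECA = if (!is.null(x$d)) x$d$dECA else NA_real_,
    weaker_impact = if (!is.null(x$d)) x$d$weaker_impact else NA)
}

#' @rdname tidiers
#' @method tidy connectivity_indices
#' @export
tidy.connectivity_indices <- function(x, ...) x$gbc

#' @rdname tidiers
#' @method glance connectivity_indices
#' @export
glance.connectivity_indices <- function(x, ...) {
  tibble::tibble(pc_numerator_ha2 = x$pc_numerator, eca_ha = x$eca,
                 total_area_ha = x$total_area, n_sites = x$n_sites,
                 kernel_half_distance_km = x$kernel$half_distance_km)
}

#' @rdname tidiers
#' @method tidy component_summary
#' @export
tidy.component_summary <- function(x, ...) {
  tibble::tibble(component_id = seq_along(x$orders), order = x$orders)
}

#' @rdname tidiers
#' @method glance component_summary
#' @export
glance.component_summary <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components, n_isolated = x$n_isolated,
    largest_order = x$largest_order, smallest_order = x$smallest_order,
    mean_order = x$mean_order, sd_order = x$sd_order,
    n_articulation_points = length(x$articulation_points))
}

#' @rdname tidiers
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed_diff = x$observed_diff,
                 p_value = x$p_value,
                 n_permutations = x$n_permutations,
                 sidedness = x$sidedness,
                 n_lost = x$n_lost, n_pool = x$n_pool,
                 seed = x$seed)
}

#' @rdname tidiers
#' @method tidy poisson_fit
#' @export
tidy.poisson_fit <- function(x, ...) x$bins

#' @rdname tidiers
#' @method glance poisson_fit
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble::tibble(lambda_hat = x$lambda_hat, statistic = x$statistic,
                 df = x$df, p_value = x$p_value, fit_ok = x$fit_ok,
                 n = x$n)
}
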