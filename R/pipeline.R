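#' Run the full scenario pipeline and write reports
#'
#' End-to-end convenience wrapper: read (or accept) a site table, run
#' [compare_scenarios()] and [scenario_tests()], and write the standard
#' report files to `out_dir`:
#'
#' * `node_metrics_current.csv`, `node_metrics_future.csv` — per-node
#'   topology metrics (plus `gbc_ha2` when indices are computed);
#' * `edges_current.csv`, `edges_future.csv` — edge lists
#'   (`source,target,distance_km`);
#' * `indices.json` — ECA/PC numerator/total area per epoch plus dA/dECA;
#' * `comparison.json` — the network-level comparison and test results;
#' * `run_log.txt` — parameters, seed and session versions.
#'
#' The JSON reports contain no timestamps and a fixed key set, so two runs
#' with identical inputs and seed are byte-identical.
#'
#' @param input A site table, or the path of a site-table CSV.
#' @param out_dir Output directory (created if needed).
#' @param species_name Label recorded in the reports.
#' @param dispersal_km Dispersal threshold in km.
#' @param kernel_half_distance_km Kernel anchor; default `dispersal_km`.
#' @param n_perm Permutations for the statistical layer (>= 99).
#' @param seed Integer seed for all randomness in the run.
#' @param decimal_comma Passed to [read_sites()] when `input` is a path.
#' @param indices Compute habitat-weighted indices (default `TRUE`).
#' @inheritParams compare_scenarios
#' @return Invisibly, a list with `comparison`, `tests` and `files`.
#' @examples
#' res <- run_pipeline(worked_fixture(), tempfile("run"),
#'                     dispersal_km = 10, n_perm = 99, seed = 1)
#' res$comparison
#' @export
run_pipeline <- function(input, out_dir, species_name = "species",
                         dispersal_km,
                         kernel_half_distance_km = dispersal_km,
                         n_perm = 999, seed = 1,
                         topology_mode = "centroid",
                         habitat_mode = "edge_approx",
                         distances = NULL,
                         decimal_comma = FALSE,
                         indices = TRUE) {
  stopifnot(n_perm >= 99, dispersal_km > 0)
  sites <- if (is.character(input)) {
    read_sites(input, decimal_comma = decimal_comma)
  } else {
    validate_sites(input)
  }
  cmp <- compare_scenarios(sites, dispersal_km,
                           kernel_half_distance_km = kernel_half_distance_km,
                           distances = distances,
                           topology_mode = topology_mode,
                           habitat_mode = habitat_mode,
                           indices = indices)
  tests <- scenario_tests(cmp, n_perm = n_perm, seed = seed)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  metrics_with_gbc <- function(met, idx) {
    if (!is.null(idx) && nrow(idx$gbc) > 0) {
      dplyr::left_join(met, idx$gbc, by = "site_id")
    } else met
  }
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p, progress = FALSE)
    p
  }
  files <- c(files,
    w(metrics_with_gbc(cmp$current_metrics, cmp$current_indices),
      "node_metrics_current.csv"),
    w(metrics_with_gbc(cmp$future_metrics, cmp$future_indices),
      "node_metrics_future.csv"),
    w(graph_edges(cmp$current_graph), "edges_current.csv"),
    w(graph_edges(cmp$future_graph), "edges_future.csv"))

  idx_json <- file.path(out_dir, "indices.json")
  jsonlite::write_json(indices_report(cmp), idx_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cmp_json <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(comparison_report(cmp, tests, species_name),
                       cmp_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, idx_json, cmp_json)

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("species: ", species_name),
    paste0("dispersal_km: ", dispersal_km),
    paste0("kernel_half_distance_km: ", kernel_half_distance_km),
    paste0("topology_mode: ", topology_mode),
    paste0("habitat_mode: ", habitat_mode),
    paste0("n_perm: ", n_perm),
    paste0("seed: ", seed),
    paste0("n_sites_input: ", nrow(sites)),
    paste0("reservenet_version: ",
           as.character(utils::packageVersion("reservenet"))),
    paste0("R_version: ", R.version.string),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))),
    log_path)
  files <- c(files, log_path)

  invisible(list(comparison = cmp, tests = tests, files = files))
}

indices_report <- function(cmp) {
  one <- function(idx) {
    if (is.null(idx)) return(NULL)
    list(pc_numerator_ha2 = idx$pc_numerator, eca_ha = idx$eca,
         total_area_ha = idx$total_area, n_sites = idx$n_sites,
         kernel_half_distance_km = idx$kernel$half_distance_km)
  }
  list(current = one(cmp$current_indices),
       future = one(cmp$future_indices),
       dA_pct = if (!is.null(cmp$d)) round_half_up(cmp$d$dA, 2) else NULL,
       dECA_pct = if (!is.null(cmp$d)) round_half_up(cmp$d$dECA, 2) else NULL,
       weaker_impact = if (!is.null(cmp$d)) cmp$d$weaker_impact else NULL)
}

comparison_report <- function(cmp, tests, species_name) {
  sum_fields <- function(s) {
    list(n_components = s$n_components, n_isolated = s$n_isolated,
         largest_order = s$largest_order, smallest_order = s$smallest_order,
         mean_order = s$mean_order, sd_order = s$sd_order,
         n_articulation_points = length(s$articulation_points),
         articulation_points = as.list(s$articulation_points))
  }
  list(
    species = species_name,
    dispersal_km = cmp$dispersal_km,
    n_current = cmp$n_current, n_future = cmp$n_future,
    n_lost = cmp$n_lost,
    pct_lost = round_half_up(cmp$pct_lost, 2),
    components_lost = cmp$components_lost,
    split_events = cmp$split_events,
    current = sum_fields(cmp$current_summary),
    future = sum_fields(cmp$future_summary),
    tests = tests)
}
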