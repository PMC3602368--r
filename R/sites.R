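#' Site tables
#'
#' A site table is the package's basic input: one row per protected site,
#' with a unique identifier, planar (already-projected) centroid coordinates
#' in kilometres, the habitat area of the site in hectares, and two logical
#' suitability flags (current climate/land use, and a modelled future
#' scenario). No geodesy is performed: coordinates must be projected before
#' they reach this package.
#'
#' Required columns: `site_id`, `x_km`, `y_km`, `area_ha`,
#' `suitable_current`, `suitable_future`.
#'
#' @param sites A data frame with the columns listed above.
#' @return `validate_sites()` returns the table as a tibble, with the
#'   suitability flags coerced to logical, or throws an informative error.
#' @examples
#' validate_sites(worked_fixture())
#' @export
validate_sites <- function(sites) {
  required <- c("site_id", "x_km", "y_km", "area_ha",
                "suitable_current", "suitable_future")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    stop("site table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sites <- tibble::as_tibble(sites)
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id) > 0) {
    dup <- unique(sites$site_id[duplicated(sites$site_id)])
    stop("duplicate site_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(sites$x_km)) || !all(is.finite(sites$y_km))) {
    stop("non-finite site coordinates", call. = FALSE)
  }
  if (!all(is.finite(sites$area_ha)) || any(sites$area_ha <= 0)) {
    stop("site areas must be finite and > 0 (hectares)", call. = FALSE)
  }
  sites$suitable_current <- as_flag(sites$suitable_current, "suitable_current")
  sites$suitable_future <- as_flag(sites$suitable_future, "suitable_future")
  sites
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  stop(what, " must be logical or 0/1", call. = FALSE)
}

#' Read and write site tables
#'
#' Site tables are comma-separated UTF-8 text with a header row
#' `site_id,x_km,y_km,area_ha,suitable_current,suitable_future`; the
#' suitability flags may be written 0/1 or TRUE/FALSE. Some European data
#' sources print decimal commas; set `decimal_comma = TRUE` to parse
#' "14,75" as 14.75 (fields must then be semicolon-separated, the usual
#' pairing for that dialect).
#'
#' @param path Path to a CSV file.
#' @param decimal_comma Parse decimal commas (semicolon-separated file)?
#' @return A validated site tibble (see [validate_sites()]).
#' @export
read_sites <- function(path, decimal_comma = FALSE) {
  if (decimal_comma) {
    raw <- suppressMessages(
      readr::read_csv2(path, show_col_types = FALSE, progress = FALSE))
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed site table at line(s) ",
         paste(unique(prob$row), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  validate_sites(raw)
}

#' @rdname read_sites
#' @param sites A site table.
#' @export
write_sites <- function(sites, path) {
  sites <- validate_sites(sites)
  out <- dplyr::mutate(sites,
    suitable_current = as.integer(.data$suitable_current),
    suitable_future = as.integer(.data$suitable_future))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Pairwise inter-site distances
#'
#' Computes the symmetric matrix of distances (km) between every pair of
#' sites. Two modes are supported:
#'
#' * `"centroid"` — plain Euclidean distance between site centroids; used by
#'   default for the dispersal-threshold graph.
#' * `"edge_approx"` — an edge-to-edge approximation that treats each site
#'   as a circle of equal area centred on its centroid:
#'   `max(0, centroid distance - r_i - r_j)` with
#'   `r = sqrt(area_km2 / pi)` (areas converted ha to km2, 100 ha = 1 km2).
#'   Used by default for the habitat-weighted indices, where what matters is
#'   the gap an animal must cross between patches, not centre-to-centre
#'   distance.
#'
#' Passing `mode = "matrix"` is an error: it signals that a precomputed
#' matrix (e.g. from [read_distance_matrix()]) should be supplied to the
#' downstream function instead.
#'
#' @param sites A site table.
#' @param mode Distance mode, see Details.
#' @return A symmetric numeric matrix in km with `site_id` dimnames and a
#'   `"distance_mode"` attribute.
#' @examples
#' s <- worked_fixture()
#' d <- pairwise_distances(s, "centroid")
#' d["S01", "S07"]
#' @export
pairwise_distances <- function(sites, mode = c("centroid", "edge_approx",
                                               "matrix")) {
  mode <- match.arg(mode)
  if (mode == "matrix") {
    stop("mode = \"matrix\" means a precomputed distance matrix must be ",
         "supplied by the caller; see read_distance_matrix()", call. = FALSE)
  }
  sites <- validate_sites(sites)
  d <- as.matrix(stats::dist(cbind(sites$x_km, sites$y_km)))
  if (mode == "edge_approx") {
    r <- sqrt((sites$area_ha / 100) / pi)
    d <- d - outer(r, r, "+")
    d[d < 0] <- 0
    diag(d) <- 0
  }
  dimnames(d) <- list(sites$site_id, sites$site_id)
  attr(d, "distance_mode") <- mode
  d
}

#' Read a precomputed distance matrix
#'
#' CSV with site ids in the first row and first column, values in km.
#'
#' @param path Path to the CSV file.
#' @return A symmetric km matrix with site_id dimnames.
#' @export
read_distance_matrix <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), ids)) {
    stop("distance matrix row and column ids disagree", call. = FALSE)
  }
  dimnames(m) <- list(ids, ids)
  check_distance_matrix(m)
  attr(m, "distance_mode") <- "matrix"
  m
}

check_distance_matrix <- function(d) {
  if (!all(is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix not symmetric",
                                      call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be 0",
                              call. = FALSE)
  invisible(d)
}

## Subset a distance matrix to the given ids, in the given order.
subset_distances <- function(d, ids) {
  missing <- setdiff(ids, rownames(d))
  if (length(missing) > 0) {
    stop("distance matrix is missing site id(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- d[ids, ids, drop = FALSE]
  attr(out, "distance_mode") <- attr(d, "distance_mode")
  out
}
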