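#' Simulate a clustered reserve network
#'
#' Generates synthetic site tables with the statistical structure typical of
#' continental protected-area systems: sites fall in geographic clusters
#' (producing a multi-component dispersal graph), site areas are log-normal,
#' and future unsuitability preferentially strikes poorly connected sites.
#'
#' Cluster centres are placed by rejection sampling, at least
#' `inter_cluster_km` apart, in a square arena of side
#' `6 * inter_cluster_km * sqrt(n_clusters)`; sites scatter around their
#' centre with isotropic Gaussian noise of sd `cluster_spread_km`. All sites
#' are currently suitable. Future suitability follows a pure-contraction
#' process: each site is lost with probability proportional to
#' `exp(-degree_bias * degree)` (degree measured on the current graph at
#' `dispersal_km`), rescaled by iterative capping at 1 (water-filling) so
#' the *expected* number of losses is exactly `loss_rate * n`. With
#' `degree_bias = 0` every site is equally at risk; larger values
#' concentrate losses on weakly connected sites.
#'
#' @param n_clusters Number of geographic clusters.
#' @param sites_per_cluster Sites per cluster: a single count, or a
#'   length-2 range sampled uniformly per cluster.
#' @param cluster_spread_km SD (km) of within-cluster scatter.
#' @param inter_cluster_km Minimum distance (km) between cluster centres;
#'   should exceed `2 * cluster_spread_km`.
#' @param area_meanlog,area_sdlog Log-normal parameters of site area (ha).
#' @param loss_rate Target expected fraction of sites lost, in `[0, 1)`.
#' @param degree_bias Strength (>= 0) of the preference for losing
#'   low-degree sites.
#' @param dispersal_km Dispersal threshold (km) used to compute the degrees
#'   that drive the loss bias.
#' @param seed Integer seed; the same seed yields a byte-identical table.
#' @return A site tibble (see [validate_sites()]).
#' @examples
#' sites <- simulate_sites(n_clusters = 3, sites_per_cluster = 10, seed = 1)
#' summarize_components(build_graph(sites, 90))
#' @export
simulate_sites <- function(n_clusters = 5, sites_per_cluster = 40,
                           cluster_spread_km = 30, inter_cluster_km = 450,
                           area_meanlog = 9, area_sdlog = 1,
                           loss_rate = 0.15, degree_bias = 2,
                           dispersal_km = 90, seed) {
  stopifnot(n_clusters >= 1, all(sites_per_cluster >= 1),
            cluster_spread_km > 0, inter_cluster_km > 0,
            loss_rate >= 0, loss_rate < 1, degree_bias >= 0,
            dispersal_km > 0, is.numeric(seed))
  withr::with_seed(as.integer(seed), {
    arena <- 6 * inter_cluster_km * sqrt(n_clusters)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < n_clusters) {
      cand <- runif(2, 0, arena)
      ok <- nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2))) >=
          inter_cluster_km
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1
      if (tries > 1000 * n_clusters) {
        stop("arena too crowded: could not place cluster centres ",
             "inter_cluster_km apart", call. = FALSE)
      }
    }
    per <- if (length(sites_per_cluster) == 1) {
      rep(sites_per_cluster, n_clusters)
    } else {
      sample(sites_per_cluster[1]:sites_per_cluster[2], n_clusters,
             replace = TRUE)
    }
    n <- sum(per)
    cl <- rep(seq_len(n_clusters), per)
    x <- centers[cl, 1] + stats::rnorm(n, 0, cluster_spread_km)
    y <- centers[cl, 2] + stats::rnorm(n, 0, cluster_spread_km)
    area <- rlnorm(n, area_meanlog, area_sdlog)
    sites <- tibble::tibble(
      site_id = sprintf("S%04d", seq_len(n)),
      x_km = x, y_km = y, area_ha = area,
      suitable_current = TRUE, suitable_future = TRUE)

    if (loss_rate > 0) {
      d <- as.matrix(stats::dist(cbind(x, y)))
      deg <- colSums(d <= dispersal_km) - 1L
      p <- loss_probabilities(deg, loss_rate * n, degree_bias)
      sites$suitable_future <- !(runif(n) < p)
    }
    sites
  })
}

## Water-filling scaler: cap probabilities at 1 and redistribute the excess
## over the uncapped sites so that sum(p) equals the target expected count.
loss_probabilities <- function(degree, target, degree_bias) {
  n <- length(degree)
  w <- exp(-degree_bias * degree)
  p <- numeric(n)
  free <- rep(TRUE, n)
  t <- target
  repeat {
    sw <- sum(w[free])
    if (sw <= 0) {          # weights underflowed: spread uniformly
      p[free] <- t / sum(free)
      break
    }
    p[free] <- t / sw * w[free]
    over <- free & p > 1
    if (!any(over)) break
    p[over] <- 1
    free[over] <- FALSE
    t <- target - sum(p[!free])
    if (!any(free) || t <= 0) break
  }
  pmin(pmax(p, 0), 1)
}

#' A deterministic worked example network
#'
#' Twelve sites in three components: a 7-site component (a hexagonal ring
#' plus one pendant site, giving exactly one articulation point), a 4-site
#' square cycle, and one isolated site. Under the future scenario the
#' pendant site (S07) and the isolated site (S12) become unsuitable, so the
#' future network keeps 10 sites in 2 components. At a 10 km dispersal
#' threshold the component orders are 7/4/1 and the hexagon vertex S01 is
#' the only articulation point. Intended for examples, vignettes and as a
#' fixed test fixture.
#'
#' @return A site tibble.
#' @examples
#' build_graph(worked_fixture(), dispersal_km = 10)
#' @export
worked_fixture <- function() {
  s3 <- 4 * sqrt(3)  # hexagon of circumradius 8: side length 8
  tibble::tibble(
    site_id = sprintf("S%02d", 1:12),
    x_km = c(8, 4, -4, -8, -4, 4, 17, 200, 208, 208, 200, 400),
    y_km = c(0, s3, s3, 0, -s3, -s3, 0, 0, 0, 8, 8, 0),
    area_ha = c(1200, 800, 1500, 950, 1100, 700, 300, 2000, 1800, 600,
                900, 400),
    suitable_current = TRUE,
    suitable_future = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                        TRUE, TRUE, TRUE, TRUE, FALSE))
}

#' Published network summaries for the four study raptors
#'
#' Per-species published summary values used as arithmetic inputs for
#' cross-checks: median dispersal distance, current/future node counts, and
#' current/future Equivalent Connected Area and total habitat area (ha) of
#' the European protected-area networks of Griffon vulture, Golden eagle,
#' Egyptian vulture and Lesser spotted eagle. The underlying per-site data
#' are not public; these network-level numbers let the package's arithmetic
#' (percent of nodes lost, dA, dECA) be verified against the published
#' values.
#'
#' @return A tibble with one row per species.
#' @examples
#' ref <- raptor_reference()
#' d_metrics(list(eca = ref$eca_current_ha[1], total_area = ref$area_current_ha[1]),
#'           list(eca = ref$eca_future_ha[1], total_area = ref$area_future_ha[1]))
#' @export
raptor_reference <- function() {
  tibble::tibble(
    species = c("Gyps fulvus", "Aquila chrysaetos",
                "Neophron percnopterus", "Aquila pomarina"),
    dispersal_km = c(145, 90, 54, 44),
    nodes_current = c(522L, 1383L, 514L, 624L),
    nodes_future = c(445L, 1348L, 474L, 465L),
    eca_current_ha = c(6348903, 8234347, 4044250, 4170549),
    eca_future_ha = c(5592091, 8282544, 3963968, 3049496),
    area_current_ha = c(13381774, 25678502, 12612170, 13959316),
    area_future_ha = c(11631070, 24968535, 12223346, 9811228))
}
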