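path_graph <- function() {
  s <- tibble::tibble(site_id = c("A", "B", "C"), x_km = c(0, 40, 80),
                      y_km = 0, area_ha = 100, suitable_current = TRUE,
                      suitable_future = TRUE)
  build_graph(s, 44)
}

triangle_graph <- function() {
  s <- tibble::tibble(site_id = c("A", "B", "C"),
                      x_km = c(0, 10, 5), y_km = c(0, 0, 8),
                      area_ha = 100, suitable_current = TRUE,
                      suitable_future = TRUE)
  build_graph(s, 12)
}

test_that("components, orders and articulation points on hand-built graphs", {
  p <- summarize_components(path_graph())
  expect_equal(p$n_components, 1)
  expect_equal(p$orders, 3L)
  expect_equal(p$articulation_points, "B")

  t <- summarize_components(triangle_graph())
  expect_equal(t$n_components, 1)
  expect_equal(t$articulation_points, character(0))

  # two triangles sharing one vertex: that vertex is the only cut node
  adj <- matrix(FALSE, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(3, 5))) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
  }
  dg <- graph_from_adj(adj)
  cs <- summarize_components(dg)
  expect_equal(cs$n_components, 1)
  expect_equal(cs$articulation_points, "N03")
})

test_that("component orders partition the node set", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      dg <- graph_from_adj(random_graph(sample(5:25, 1), runif(1, 0.05, 0.3)))
      cs <- summarize_components(dg)
      expect_equal(sum(cs$orders), igraph::vcount(dg$graph))
      expect_lte(cs$n_isolated, cs$n_components)
      expect_true(all(cs$largest_order >= cs$orders))
    }
  })
})

test_that("betweenness matches hand-computed values", {
  nm <- node_metrics(path_graph())
  expect_equal(nm$betweenness[nm$site_id == "B"], 1)
  expect_equal(nm$betweenness[nm$site_id != "B"], c(0, 0))

  expect_equal(node_metrics(triangle_graph())$betweenness, rep(0, 3))

  # 4-node star: centre carries all 3 leaf pairs, normalizer 3
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2:4] <- adj[2:4, 1] <- TRUE
  nm2 <- node_metrics(graph_from_adj(adj))
  expect_equal(nm2$betweenness, c(1, 0, 0, 0))
})

test_that("betweenness is zero on graphs with fewer than 3 nodes", {
  s <- tibble::tibble(site_id = c("A", "B"), x_km = c(0, 1), y_km = 0,
                      area_ha = 1, suitable_current = TRUE,
                      suitable_future = TRUE)
  expect_equal(node_metrics(build_graph(s, 5))$betweenness, c(0, 0))
})

test_that("clustering matches neighbour-pair enumeration", {
  expect_equal(node_metrics(triangle_graph())$clustering, rep(1, 3))
  expect_equal(node_metrics(path_graph())$clustering, rep(0, 3))

  # K4 minus one edge: two deg-3 nodes at 2/3, two deg-2 nodes at 1
  adj <- matrix(TRUE, 4, 4); diag(adj) <- FALSE
  adj[3, 4] <- adj[4, 3] <- FALSE
  clu <- node_metrics(graph_from_adj(adj))$clustering
  expect_equal(clu, c(2/3, 2/3, 1, 1))
  expect_equal(mean(clu), 5/6)
})

test_that("degree sum equals twice the edge count", {
  withr::with_seed(32, {
    for (rep in 1:10) {
      dg <- graph_from_adj(random_graph(sample(4:20, 1), runif(1, 0.1, 0.5)))
      nm <- node_metrics(dg)
      expect_equal(sum(nm$degree), 2 * igraph::ecount(dg$graph))
    }
  })
})

test_that("worked fixture reproduces its frozen oracle constants", {
  g <- build_graph(worked_fixture(), 10)
  cs <- summarize_components(g)
  expect_equal(cs$orders, c(7L, 4L, 1L))
  expect_equal(cs$n_isolated, 1L)
  expect_equal(cs$articulation_points, "S01")
  nm <- node_metrics(g)
  # hexagon hub with pendant: 7 of 55 normalized shortest-path pairs
  expect_equal(nm$betweenness[nm$site_id == "S01"], 7 / 55)
  expect_equal(nm$degree[nm$site_id == "S01"], 3L)
})

test_that("degree fit is refused below 20 nodes and histogram is exact", {
  g <- build_graph(worked_fixture(), 10)
  dd <- degree_distribution_summary(g)
  expect_null(dd$fit)
  expect_equal(dd$histogram$count,
               as.integer(table(factor(node_metrics(g)$degree, levels = 0:3))))
  expect_error(poisson_fit(rep(2, 10)), "refused")
})

test_that("edgeless graphs give an all-zero-degree histogram", {
  s <- line_sites(25, 25)  # 200 km apart, threshold below spacing
  dd <- degree_distribution_summary(build_graph(s, 50))
  expect_equal(dd$histogram, tibble::tibble(degree = 0L, count = 25L))
  # all degrees identical: too few pooled bins, fit flagged undefined
  expect_false(dd$fit$fit_ok)
})

test_that("Poisson degrees are accepted and the rate is the mean", {
  withr::with_seed(33, {
    deg <- stats::rpois(500, 5)
    fit <- poisson_fit(deg)
    expect_true(fit$fit_ok)
    expect_equal(fit$lambda_hat, mean(deg))
    expect_gt(fit$p_value, 0.05)
    expect_true(all(fit$bins$expected >= 5))
  })
})

test_that("nodes in small components have lower degree and betweenness", {
  # clusters of very different sizes: small components come from small
  # clusters, whose nodes have fewer in-reach neighbours
  s <- simulate_sites(n_clusters = 8, sites_per_cluster = c(2, 40),
                      loss_rate = 0, seed = 97)
  nm <- node_metrics(build_graph(s, 90))
  cs <- summarize_components(build_graph(s, 90))
  small <- tibble::tibble(order = cs$orders,
                          component_id = seq_along(cs$orders))
  nm <- dplyr::left_join(nm, small, by = "component_id")
  expect_gt(mean(nm$degree[nm$order >= 10]), mean(nm$degree[nm$order < 10]))
  expect_gte(mean(nm$betweenness[nm$order >= 10]),
             mean(nm$betweenness[nm$order < 10]))
})
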