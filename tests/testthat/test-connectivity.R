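sym_matrix <- function(ids, entries) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in entries) m[e[[1]], e[[2]]] <- m[e[[2]], e[[1]]] <- e[[3]]
  m
}

sites_of <- function(ids, areas) {
  tibble::tibble(site_id = ids, x_km = 0, y_km = 0, area_ha = areas,
                 suitable_current = TRUE, suitable_future = TRUE)
}

test_that("the kernel is anchored at the median dispersal distance", {
  k <- dispersal_kernel(44)
  expect_equal(dispersal_prob(k, 0), 1)
  expect_equal(dispersal_prob(k, 44), 0.5)
  expect_equal(dispersal_prob(k, 88), 0.25)
  d <- sort(runif(50, 0, 500))
  expect_true(all(diff(dispersal_prob(k, d)) < 0))
  expect_error(dispersal_kernel(0))
})

test_that("a two-step path beats a weak direct link", {
  k <- dispersal_kernel(50)
  # distances chosen so p(AB) = p(BC) = 0.7 and p(AC) = 0.4
  d <- function(p) -log(p) / k$rate
  dm <- sym_matrix(c("A", "B", "C"),
                   list(list("A", "B", d(0.7)), list("B", "C", d(0.7)),
                        list("A", "C", d(0.4))))
  ps <- max_product_paths(dm, k)
  expect_equal(ps["A", "C"], 0.49, tolerance = 1e-12)
  expect_equal(ps["A", "B"], 0.7, tolerance = 1e-12)
  expect_equal(diag(ps), c(A = 1, B = 1, C = 1))
})

test_that("with two sites the path probability is the direct one", {
  k <- dispersal_kernel(30)
  dm <- sym_matrix(c("A", "B"), list(list("A", "B", 45)))
  ps <- max_product_paths(dm, k)
  expect_equal(ps["A", "B"], dispersal_prob(k, 45))
})

test_that("max-product paths match exhaustive enumeration on random sites", {
  withr::with_seed(41, {
    k <- dispersal_kernel(40)
    for (rep in 1:10) {
      s <- random_sites(8)
      dm <- pairwise_distances(s, "centroid")
      p <- dispersal_prob(k, dm); diag(p) <- 1
      expected <- oracle_pstar_gbc(s$area_ha, p)
      got <- max_product_paths(dm, k)
      expect_equal(unname(got), expected$pstar, tolerance = 1e-9)
      got_gbc <- gbc(s, dm, k)
      expect_equal(got_gbc$gbc_ha2, expected$gbc, tolerance = 1e-9)
    }
  })
})

test_that("ECA closed forms hold exactly", {
  one <- sites_of("A", 100)
  expect_equal(eca(one, matrix(1, 1, 1, dimnames = list("A", "A")))$eca, 100,
               tolerance = 1e-9)
  two <- sites_of(c("A", "B"), c(100, 100))
  disconnected <- diag(2); dimnames(disconnected) <- list(two$site_id,
                                                          two$site_id)
  expect_equal(eca(two, disconnected)$eca, sqrt(2 * 100^2),
               tolerance = 1e-9)
  connected <- matrix(1, 2, 2, dimnames = dimnames(disconnected))
  expect_equal(eca(two, connected)$eca, 200, tolerance = 1e-9)
})

test_that("ECA respects its bounds and p* dominates the direct kernel", {
  withr::with_seed(42, {
    k <- dispersal_kernel(60)
    for (rep in 1:10) {
      s <- random_sites(12, span = 300)
      dm <- pairwise_distances(s, "edge_approx")
      ps <- max_product_paths(dm, k)
      expect_true(all(abs(ps - t(ps)) < 1e-12))
      expect_true(all(ps - dispersal_prob(k, dm) >= -1e-12))
      e <- eca(s, ps)
      expect_gte(e$eca, sqrt(sum(s$area_ha^2)) - 1e-9)
      expect_lte(e$eca, sum(s$area_ha) + 1e-9)
    }
  })
})

test_that("collinear sites exercise the GBC tie rule", {
  # on collinear points the two-step product equals the direct probability
  # exactly, so the middle site lies on an optimal path and collects the
  # full pair contribution
  s <- tibble::tibble(site_id = c("A", "B", "C"), x_km = c(0, 40, 80),
                      y_km = 0, area_ha = 1, suitable_current = TRUE,
                      suitable_future = TRUE)
  k <- dispersal_kernel(44)
  dm <- pairwise_distances(s, "centroid")
  g <- gbc(s, dm, k)
  p_ac <- dispersal_prob(k, 80)
  expect_equal(g$gbc_ha2[g$site_id == "B"], 1 * 1 * p_ac, tolerance = 1e-9)
  expect_equal(g$gbc_ha2[g$site_id %in% c("A", "C")], c(0, 0))
})

test_that("nodes on no optimal path have zero GBC", {
  s <- sites_of(c("A", "B"), c(10, 20))
  dm <- sym_matrix(c("A", "B"), list(list("A", "B", 100)))
  g <- gbc(s, dm, dispersal_kernel(50))
  expect_equal(g$gbc_ha2, c(0, 0))
})

test_that("dA/dECA arithmetic reproduces published index contrasts", {
  # long-range disperser: both indices fall, connectivity less than area
  d1 <- d_metrics(list(eca = 6348903, total_area = 13381774),
                  list(eca = 5592091, total_area = 11631070))
  expect_equal(round_half_up(d1$dECA, 2), -11.92)
  expect_equal(round_half_up(d1$dA, 2), -13.08)
  expect_true(d1$weaker_impact)

  # connectivity can even rise while area falls
  d2 <- d_metrics(list(eca = 8234347, total_area = 25678502),
                  list(eca = 8282544, total_area = 24968535))
  expect_equal(round_half_up(d2$dECA, 2), 0.59)
  expect_equal(round_half_up(d2$dA, 2), -2.76)
  expect_true(d2$weaker_impact)

  d3 <- d_metrics(list(eca = 100, total_area = 500),
                  list(eca = 100, total_area = 500))
  expect_equal(d3$dA, 0)
  expect_equal(d3$dECA, 0)
  expect_false(d3$weaker_impact)

  expect_error(d_metrics(list(eca = 0, total_area = 0),
                         list(eca = 1, total_area = 1)), "> 0")
})

test_that("removing a site never increases the PC numerator", {
  withr::with_seed(43, {
    k <- dispersal_kernel(50)
    for (rep in 1:10) {
      s <- random_sites(10, span = 250)
      full <- eca(s, max_product_paths(pairwise_distances(s), k))
      drop <- s[-sample(nrow(s), 1), ]
      reduced <- eca(drop, max_product_paths(pairwise_distances(drop), k))
      expect_lte(reduced$pc_numerator, full$pc_numerator + 1e-9)
    }
  })
})

test_that("ECA never decreases as the kernel half-distance grows", {
  withr::with_seed(44, {
    for (rep in 1:10) {
      s <- random_sites(10, span = 250)
      dm <- pairwise_distances(s)
      h1 <- runif(1, 10, 80)
      h2 <- h1 + runif(1, 0, 100)
      e1 <- eca(s, max_product_paths(dm, dispersal_kernel(h1)))$eca
      e2 <- eca(s, max_product_paths(dm, dispersal_kernel(h2)))$eca
      expect_gte(e2, e1 - 1e-9)
    }
  })
})

test_that("round_half_up rounds halves away from zero", {
  # binary-exact halves, where base round() would go to even
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
})
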