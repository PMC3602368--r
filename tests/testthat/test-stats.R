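test_that("identical constant groups give p = 1", {
  r <- permutation_test(rep(3, 5), rep(3, 20), seed = 1)
  expect_equal(r$p_value, 1)
  expect_equal(r$observed_diff, 0)
})

test_that("maximal separation attains the permutation floor", {
  r <- permutation_test(rep(0, 5), rep(10, 50), n_perm = 999,
                        sidedness = "lower", seed = 123)
  expect_equal(r$observed_diff, -10)
  # only the unique all-zero subset replicates the observed mean; at 999
  # draws from choose(55, 5) subsets it is effectively never drawn
  expect_equal(r$p_value, 1 / 1000)
})

test_that("p-values respect the 1/(n_perm + 1) floor and the statistic is
           independent of n_perm", {
  lost <- c(1, 2); ret <- c(5, 6, 7, 8)
  r1 <- permutation_test(lost, ret, n_perm = 99, seed = 9)
  r2 <- permutation_test(lost, ret, n_perm = 199, seed = 9)
  expect_equal(r1$observed_diff, r2$observed_diff)
  expect_gte(r1$p_value, 1 / 100)
  expect_gte(r2$p_value, 1 / 200)
  # same seed, same answer
  expect_equal(permutation_test(lost, ret, n_perm = 99, seed = 9)$p_value,
               r1$p_value)
})

test_that("the permutation test is calibrated under exchangeability", {
  # both groups drawn from one distribution: p should be ~uniform
  withr::with_seed(51, {
    ps <- vapply(1:400, function(i) {
      pool <- stats::rnorm(40)
      permutation_test(pool[1:10], pool[11:40], n_perm = 99,
                       seed = i)$p_value
    }, numeric(1))
    expect_gt(mean(ps <= 0.05), 0.02)
    expect_lt(mean(ps <= 0.05), 0.09)
    expect_gt(mean(ps), 0.4)
  })
})

test_that("more lost than retained values is an error", {
  expect_error(permutation_test(1:5, 1:3, seed = 1), "undefined")
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  count_u <- function(a, b) {
    u <- 0
    for (x in a) for (y in b) u <- u + (x < y) + 0.5 * (x == y)
    min(u, length(a) * length(b) - u)
  }
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$U, 1)
  a <- c(2, 2, 5); b <- c(2, 4, 7, 7)
  expect_equal(mann_whitney_u(a, b)$U, count_u(a, b))
  withr::with_seed(52, {
    for (rep in 1:20) {
      a <- sample(1:6, sample(2:8, 1), replace = TRUE)
      b <- sample(1:6, sample(2:8, 1), replace = TRUE)
      expect_equal(mann_whitney_u(a, b)$U, count_u(a, b))
    }
  })
})

test_that("identical multisets give U = n_a n_b / 2 and p near 1", {
  a <- c(1, 2, 2, 9)
  r <- mann_whitney_u(a, a)
  expect_equal(r$U, length(a)^2 / 2)
  expect_gt(r$p_value, 0.9)
})

test_that("Mann-Whitney p agrees with the base-R reference", {
  withr::with_seed(53, {
    # large groups (n_a n_b > 400): normal approximation on both sides
    a <- stats::rnorm(25); b <- stats::rnorm(20, 1)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = FALSE)$p.value)
    # small tie-free groups: exact enumeration on both sides
    a2 <- stats::rnorm(8); b2 <- stats::rnorm(9, 0.5)
    expect_equal(mann_whitney_u(a2, b2)$p_value,
                 stats::wilcox.test(a2, b2, exact = TRUE)$p.value)
  })
})

test_that("Spearman handles monotone, hand-ranked and degenerate input", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  r <- spearman_cor(1:4, c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
})

test_that("Spearman rho with ties equals the midrank Pearson reference", {
  withr::with_seed(54, {
    x <- sample(1:5, 30, replace = TRUE)
    y <- x + sample(1:3, 30, replace = TRUE)
    r <- spearman_cor(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(r$rho, unname(ref$estimate))
  })
})
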