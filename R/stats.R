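#' Subset-resampling permutation test for lost vs retained nodes
#'
#' Tests whether the nodes removed under a scenario differ, in the mean of
#' some per-node metric, from the nodes that persist. The observed statistic
#' is `mean(lost) - mean(retained)`. The null distribution is built by
#' drawing `n_perm` random subsets of size `|lost|` (without replacement)
#' from the pooled current-network values and recomputing the statistic with
#' that subset playing the role of the lost set. The p-value uses add-one
#' smoothing, `p = (1 + #as-or-more-extreme) / (n_perm + 1)`, so it can
#' never be 0 and is bounded below by `1/(n_perm + 1)`.
#'
#' @param lost_values Metric values of the lost nodes (nonempty).
#' @param retained_values Metric values of the retained nodes (nonempty, at
#'   least as many as lost).
#' @param n_perm Number of permutations (default 999).
#' @param sidedness `"two_sided"` (default), `"lower"` (lost smaller) or
#'   `"greater"`.
#' @param seed Integer seed; required so every run is reproducible.
#' @return A `permutation_result`: `observed_diff`, `n_permutations`,
#'   `p_value`, `sidedness`, `seed`, `n_lost`, `n_pool`.
#' @examples
#' permutation_test(c(0, 1, 0), c(4, 5, 6, 7, 5), seed = 1)
#' @export
permutation_test <- function(lost_values, retained_values, n_perm = 999,
                             sidedness = c("two_sided", "lower", "greater"),
                             seed) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(lost_values) >= 1, length(retained_values) >= 1,
            n_perm >= 1, is.numeric(seed))
  if (length(lost_values) > length(retained_values)) {
    stop("more lost than retained values; the subset resample is undefined",
         call. = FALSE)
  }
  pool <- c(lost_values, retained_values)
  m <- length(lost_values)
  n <- length(pool)
  observed <- mean(lost_values) - mean(retained_values)
  if (sd(pool) == 0) {
    return(structure(list(observed_diff = observed, n_permutations = n_perm,
                          p_value = 1, sidedness = sidedness, seed = seed,
                          n_lost = m, n_pool = n),
                     class = "permutation_result"))
  }
  total <- sum(pool)
  null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n, m)
    s <- sum(pool[idx])
    s / m - (total - s) / (n - m)
  }, numeric(1)))
  extreme <- switch(sidedness,
    two_sided = sum(abs(null) >= abs(observed)),
    lower = sum(null <= observed),
    greater = sum(null >= observed))
  structure(list(observed_diff = observed, n_permutations = n_perm,
                 p_value = (1 + extreme) / (n_perm + 1),
                 sidedness = sidedness, seed = seed,
                 n_lost = m, n_pool = n),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %d perms, seed %d): observed diff = %.4g, p = %.4g\n",
    x$sidedness, x$n_permutations, as.integer(x$seed), x$observed_diff,
    x$p_value))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' `U` is computed from midranks as `min(U_a, U_b)`; the p-value (two-sided)
#' comes from exact enumeration when there are no ties and
#' `n_a * n_b <= 400`, otherwise from the normal approximation with tie
#' correction.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return List with `U` and `p_value`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b)
  if (sd(c(a, b)) == 0) {
    # every pooled value tied: no evidence of a shift in either direction
    return(list(U = na * nb / 2, p_value = 1))
  }
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  ties <- anyDuplicated(c(a, b)) > 0
  wt <- suppressWarnings(wilcox.test(a, b,
                                     exact = !ties && na * nb <= 400,
                                     correct = TRUE))
  list(U = min(u_a, u_b), p_value = unname(wt$p.value))
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of midranks; the p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (two-sided). A constant input vector leaves rho
#' undefined and is flagged with a warning and `NA`.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return List with `rho` and `p_value`.
#' @examples
#' spearman_cor(1:4, c(2, 1, 4, 3))  # rho = 0.6
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    return(list(rho = rho, p_value = 0))
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(abs(t), df = n - 2, lower.tail = FALSE))
}
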