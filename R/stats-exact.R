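#' Barnard's exact unconditional test for a 2x2 table
#'
#' Tests association in a 2x2 table under the two-independent-binomials
#' model (row totals fixed), using the pooled-variance z statistic as the
#' ordering criterion. The p-value is the maximum, over a grid of the
#' nuisance success probability, of the probability of all tables at least
#' as extreme (|z| >= |z observed|) -- the classic unconditional
#' construction, which does not condition on the column margin.
#'
#' @param table 2x2 matrix or table of counts; rows are the two groups,
#'   column 1 the successes.
#' @param grid_size Number of nuisance-parameter grid points (default 1000,
#'   i.e. step 0.001).
#' @return An object of class `htest` with the two-sided p-value, the
#'   observed z `statistic`, and the maximizing nuisance probability.
#' @export
#' @examples
#' barnard_test(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
barnard_test <- function(table, grid_size = 1000) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L)) || any(x < 0) || any(x != round(x))) {
    abort("`table` must be a 2x2 matrix of nonnegative counts.")
  }
  n1 <- sum(x[1, ]); n2 <- sum(x[2, ])
  if (n1 == 0L || n2 == 0L) abort("both row margins must be positive.")
  z_obs <- pooled_z(x[1, 1], n1, x[2, 1], n2)
  # |z| for every possible table under fixed row totals
  grid_x <- expand.grid(x1 = 0:n1, x2 = 0:n2)
  z_all <- abs(pooled_z(grid_x$x1, n1, grid_x$x2, n2))
  extreme <- z_all >= abs(z_obs) - 1e-9
  pis <- seq_len(grid_size) / (grid_size + 1)
  x1e <- grid_x$x1[extreme]; x2e <- grid_x$x2[extreme]
  pr <- vapply(pis, function(p) {
    sum(exp(dbinom(x1e, n1, p, log = TRUE) +
              dbinom(x2e, n2, p, log = TRUE)))
  }, 0)
  p_max <- max(pr); pi_max <- pis[which.max(pr)]
  structure(list(
    statistic = c(z = z_obs), p.value = min(p_max, 1),
    estimate = c(`nuisance pi at maximum` = pi_max),
    method = "Barnard's exact unconditional test (pooled-z ordering)",
    alternative = "two.sided",
    data.name = deparse(substitute(table))
  ), class = "htest")
}

pooled_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  z <- (p1 - p2) / sqrt(v)
  z[v == 0] <- 0
  z
}

#' Two-proportions z-test
#'
#' Pooled-variance z statistic with a two-sided normal p-value (no
#' continuity correction).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return An object of class `htest`.
#' @export
#' @examples
#' two_prop_ztest(9, 26, 8, 13)
two_prop_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) abort("n1 and n2 must be positive.")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0) {
    abort("counts must satisfy 0 <= k <= n.")
  }
  z <- pooled_z(k1, n1, k2, n2)
  structure(list(
    statistic = c(z = z), p.value = 2 * pnorm(-abs(z)),
    estimate = c(`prop 1` = k1 / n1, `prop 2` = k2 / n2),
    method = "Two-proportions z-test (pooled variance)",
    alternative = "two.sided",
    data.name = sprintf("%d/%d vs %d/%d", k1, n1, k2, n2)
  ), class = "htest")
}
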