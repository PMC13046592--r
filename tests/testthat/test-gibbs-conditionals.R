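# Closed-form helpers for the lower-truncated normal
.tn_lambda <- function(a) dnorm(a) / (1 - pnorm(a))
.tn_mean <- function(m, s) { a <- -m / s; m + s * .tn_lambda(a) }
.tn_var <- function(m, s) {
  a <- -m / s; l <- .tn_lambda(a)
  s^2 * (1 + a * l - l^2)
}

test_that("the inefficiency prior rate follows gamma0 = shape * ln(r*)^2", {
  expect_equal(compute_gamma0(0.8), 5 * log(0.8)^2)
  expect_equal(compute_gamma0(0.8), 0.24896522, tolerance = 1e-7)
  expect_equal(compute_gamma0(exp(-1)), 5)
  expect_equal(compute_gamma0(1), 0)           # fully-efficient limit
  expect_error(compute_gamma0(0), "r_star")
  expect_error(compute_gamma0(1.2), "r_star")
})

test_that("truncated-normal draws match analytic moments in both regimes", {
  set.seed(101)
  n <- 2e5
  # easy regime: most mass already positive
  x <- rtruncnorm_lower0(n, mean = 0.5, sd = 1)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - .tn_mean(0.5, 1)), 4 * sqrt(.tn_var(0.5, 1) / n))
  expect_equal(var(x), .tn_var(0.5, 1), tolerance = 0.03)
  # tail regime: naive rejection would practically never accept
  y <- rtruncnorm_lower0(n, mean = -6, sd = 1)
  expect_true(all(y >= 0))
  expect_lt(abs(mean(y) - .tn_mean(-6, 1)), 4 * sqrt(.tn_var(-6, 1) / n))
})

test_that("truncated-normal draws match the analytic CDF (KS)", {
  set.seed(102)
  n <- 1e5
  m <- 0.2; s <- 0.4
  x <- rtruncnorm_lower0(n, m, s)
  grid <- sort(x)
  emp <- seq_len(n) / n
  ks <- max(abs(emp - ptruncnorm_lower0(grid, m, s)))
  expect_lt(ks, 0.01)
})

test_that("inefficiency conditional shrinks residuals by tau/(tau+p_u)", {
  set.seed(103)
  tau <- 100; p_u <- 25
  e <- 0.12
  u <- draw_inefficiency(rep(e, 2e5), tau, p_u)
  m <- tau * e / (tau + p_u); s <- sqrt(1 / (tau + p_u))
  expect_lt(abs(mean(u) - .tn_mean(m, s)), 4 * s / sqrt(2e5))
  expect_error(draw_inefficiency(c(0.1, NA), tau, p_u), "non-finite")
  expect_error(draw_inefficiency(0.1, -1, p_u), "positive")
})

test_that("the fixed-coefficient conditional matches the normal-linear posterior", {
  set.seed(104)
  n <- 80; p <- 3; tau <- 50; k <- 1e-6
  Z <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(Z %*% c(1, 0.5, -0.3)) + rnorm(n, 0, sqrt(1 / tau))
  A <- tau * crossprod(Z) + diag(k, p)
  post_mean <- drop(solve(A, tau * crossprod(Z, y)))
  post_cov <- solve(A)
  draws <- t(replicate(2e4, draw_coefficients_fixed(Z, y, tau, k)))
  se <- sqrt(diag(post_cov) / 2e4)
  expect_true(all(abs(colMeans(draws) - post_mean) < 5 * se))
  expect_equal(cov(draws), post_cov, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("a hospital with no rows draws from the population law", {
  set.seed(105)
  q <- 2
  theta_bar <- c(0.4, -0.1)
  omega <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  d <- t(replicate(2e4, draw_coefficients_hospital(
    matrix(numeric(0), 0, q), numeric(0), tau = 10, theta_bar,
    solve(omega))))
  expect_true(all(abs(colMeans(d) - theta_bar) <
                    5 * sqrt(diag(omega) / 2e4)))
  expect_equal(cov(d), omega, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("the hospital conditional blends data and population precision", {
  set.seed(106)
  q <- 2; tau <- 100
  Z_i <- cbind(rnorm(6), rnorm(6))
  theta_true <- c(0.5, 0.2)
  y_i <- drop(Z_i %*% theta_true) + rnorm(6, 0, 0.1)
  theta_bar <- c(0, 0)
  omega_inv <- diag(1 / 0.04, q)
  A <- tau * crossprod(Z_i) + omega_inv
  mu <- drop(solve(A, tau * crossprod(Z_i, y_i) + omega_inv %*% theta_bar))
  d <- t(replicate(1e4, draw_coefficients_hospital(Z_i, y_i, tau,
                                                   theta_bar, omega_inv)))
  expect_true(all(abs(colMeans(d) - mu) < 5 * sqrt(diag(solve(A)) / 1e4)))
  expect_equal(cov(d), solve(A), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("the population-mean conditional averages hospitals with shrinkage", {
  set.seed(107)
  n_h <- 50; q <- 2; k <- 1e-6
  theta_mat <- cbind(rnorm(n_h, 0.4, 0.1), rnorm(n_h, -0.2, 0.1))
  omega_inv <- diag(1 / 0.01, q)
  A <- n_h * omega_inv + diag(k, q)
  mu <- drop(solve(A, omega_inv %*% colSums(theta_mat)))
  d <- t(replicate(1e4, draw_hyper_mean(theta_mat, omega_inv, k)))
  expect_true(all(abs(colMeans(d) - mu) < 5 * sqrt(diag(solve(A)) / 1e4)))
  expect_equal(cov(d), solve(A), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("the covariance conditional has the conjugate inverse-Wishart mean", {
  set.seed(108)
  n_h <- 40; q <- 2
  theta_bar <- c(0.4, -0.2)
  theta_mat <- cbind(rnorm(n_h, theta_bar[1], 0.2),
                     rnorm(n_h, theta_bar[2], 0.3))
  wdf <- q + 2; wscale <- diag(0.001, q)
  dev <- sweep(theta_mat, 2, theta_bar)
  S_post <- wscale + crossprod(dev)
  iw_mean <- S_post / (wdf + n_h - q - 1)
  draws <- replicate(1e4, draw_hyper_cov(theta_mat, theta_bar, wdf, 0.001))
  expect_equal(apply(draws, 1:2, mean), iw_mean, tolerance = 0.05,
               ignore_attr = TRUE)
  # every draw symmetric positive definite
  expect_true(all(apply(draws[, , 1:50], 3, function(m)
    isSymmetric(m) && min(eigen(m, symmetric = TRUE)$values) > 0)))
})

test_that("precision conditionals follow their Gamma laws", {
  set.seed(109)
  v <- rnorm(500, 0, 0.1)
  sh <- 0.001 + 250; rt <- 0.001 + sum(v^2) / 2
  d <- replicate(2e4, draw_noise_precision(v, 0.001, 0.001))
  expect_lt(abs(mean(d) - sh / rt), 5 * sqrt(sh) / rt / sqrt(2e4))
  expect_equal(var(d), sh / rt^2, tolerance = 0.1)

  u <- abs(rnorm(500, 0, 0.2))
  g0 <- compute_gamma0(0.8)
  sh_u <- 5 + 250; rt_u <- g0 + sum(u^2) / 2
  du <- replicate(2e4, draw_ineff_precision(u, 5, g0))
  expect_lt(abs(mean(du) - sh_u / rt_u), 5 * sqrt(sh_u) / rt_u / sqrt(2e4))
  expect_error(draw_ineff_precision(c(-0.1, 0.2), 5, g0), "nonnegative")
})
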