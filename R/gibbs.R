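#' Sample from a normal distribution truncated to the nonnegative half-line
#'
#' Draws from N(mean, sd^2) conditioned on being >= 0, using rejection
#' sampling: plain normal rejection when the truncation point is not far in
#' the upper tail, and Robert's translated-exponential rejection when it
#' is. This avoids the tail underflow of inverse-CDF methods when
#' `mean / sd` is very negative.
#'
#' @param n Number of draws (recycled against `mean` / `sd`).
#' @param mean Mean(s) of the untruncated normal.
#' @param sd Standard deviation(s), positive.
#' @return `n` nonnegative draws.
#' @export
rtruncnorm_lower0 <- function(n, mean, sd) {
  if (any(sd <= 0)) stop("sd must be positive")
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  a <- -mean / sd                      # standardized lower bound
  x <- numeric(n)
  easy <- a < 0.45                     # acceptance of naive rejection >= ~33%
  idx <- which(easy)
  while (length(idx)) {
    z <- stats::rnorm(length(idx))
    ok <- z >= a[idx]
    x[idx[ok]] <- z[ok]
    idx <- idx[!ok]
  }
  idx <- which(!easy)
  while (length(idx)) {
    ai <- a[idx]
    lam <- (ai + sqrt(ai^2 + 4)) / 2   # optimal exponential rate
    z <- ai + stats::rexp(length(idx)) / lam
    ok <- stats::runif(length(idx)) <= exp(-(z - lam)^2 / 2)
    x[idx[ok]] <- z[ok]
    idx <- idx[!ok]
  }
  mean + sd * x
}

# CDF of the same truncated normal; analytic companion used in tests.
#' Cumulative distribution of a lower-truncated normal
#'
#' CDF at `q` of N(mean, sd^2) truncated to `[0, Inf)`.
#' @param q Quantile(s).
#' @param mean,sd Parameters of the untruncated normal.
#' @return CDF value(s).
#' @export
ptruncnorm_lower0 <- function(q, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  ifelse(q < 0, 0, (stats::pnorm(q, mean, sd) - p0) / (1 - p0))
}

#' Draw inefficiency terms given residuals
#'
#' Full conditional of the half-normal inefficiency u under the composed
#' error e = v + u: with noise precision `tau` and inefficiency precision
#' `p_u`, u | e is N(tau * e / (tau + p_u), 1 / (tau + p_u)) truncated to
#' `[0, Inf)`. Vectorized over residuals.
#'
#' @param e Residuals y - frontier (one per hospital-year cell).
#' @param tau Noise precision (positive scalar).
#' @param p_u Inefficiency precision (positive scalar).
#' @return Nonnegative draws, one per residual.
#' @export
draw_inefficiency <- function(e, tau, p_u) {
  if (!all(is.finite(e))) stop("non-finite residuals")
  if (tau <= 0 || p_u <= 0) stop("precisions must be positive")
  prec <- tau + p_u
  rtruncnorm_lower0(length(e), mean = tau * e / prec, sd = sqrt(1 / prec))
}

# Draw from MVN with precision matrix P (via its Cholesky factor R,
# P = R'R) and mean solve(P, b): R^{-1} (R^{-T} b + z), z ~ N(0, I),
# i.e. two triangular solves per draw.
.mvn_prec_draw <- function(R, b) {
  backsolve(R, backsolve(R, b, transpose = TRUE) + stats::rnorm(length(b)))
}

.chol_safe <- function(A) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R))
    stop("conditional precision matrix is not positive definite; ",
         "check for collinear regressors or degenerate priors")
  R
}

#' Draw the common coefficient vector (fixed-coefficient model)
#'
#' Conjugate normal-linear update: with independent N(0, 1/k) priors on
#' each coefficient (k = `theta_precision`) and noise precision `tau`, the
#' conditional is MVN with precision `tau * Z'Z + k * I` and mean solving
#' that precision against `tau * Z'y_adj`.
#'
#' @param Z Design matrix (n x p).
#' @param y_adj Response net of inefficiency, y - u.
#' @param tau Noise precision.
#' @param theta_precision Prior precision (scalar).
#' @return One draw of the p coefficient vector.
#' @export
draw_coefficients_fixed <- function(Z, y_adj, tau, theta_precision) {
  p <- ncol(Z)
  A <- tau * crossprod(Z) + diag(theta_precision, p)
  b <- tau * crossprod(Z, y_adj)
  drop(.mvn_prec_draw(.chol_safe(A), b))
}

#' Draw one hospital's coefficient vector (random-coefficient model)
#'
#' Conditional given the population mean `theta_bar` and inverse
#' covariance `omega_inv`: MVN with precision `tau * Z_i'Z_i + omega_inv`
#' and mean solving that precision against
#' `tau * Z_i'y_adj_i + omega_inv %*% theta_bar`. A hospital with zero
#' rows draws from the population MVN(theta_bar, omega) exactly.
#'
#' @param Z_i Hospital design matrix (T_i x q; T_i may be 0).
#' @param y_adj_i Hospital response net of inefficiency (and of any common
#'   intercept).
#' @param tau Noise precision.
#' @param theta_bar Population mean (length q).
#' @param omega_inv Population precision (q x q, symmetric PD).
#' @return One draw of the hospital's q coefficient vector.
#' @export
draw_coefficients_hospital <- function(Z_i, y_adj_i, tau, theta_bar,
                                       omega_inv) {
  q <- length(theta_bar)
  if (is.null(Z_i) || nrow(Z_i) == 0L) {
    A <- omega_inv
    b <- omega_inv %*% theta_bar
  } else {
    A <- tau * crossprod(Z_i) + omega_inv
    b <- tau * crossprod(Z_i, y_adj_i) + omega_inv %*% theta_bar
  }
  drop(.mvn_prec_draw(.chol_safe(A), b))
}

#' Draw the population mean of the random coefficients
#'
#' Conditional under a diffuse N(0, 1/k) prior on each component:
#' MVN with precision `n * omega_inv + k * I` and matching mean.
#'
#' @param theta_mat Matrix of hospital coefficient draws (n_hospitals x q).
#' @param omega_inv Population precision (q x q).
#' @param theta_precision Prior precision k.
#' @return One draw of the q-vector population mean.
#' @export
draw_hyper_mean <- function(theta_mat, omega_inv, theta_precision) {
  n <- nrow(theta_mat); q <- ncol(theta_mat)
  if (n < 1L) stop("need at least one hospital")
  A <- n * omega_inv + diag(theta_precision, q)
  b <- omega_inv %*% colSums(theta_mat)
  drop(.mvn_prec_draw(.chol_safe(A), b))
}

#' Draw the population covariance of the random coefficients
#'
#' Conjugate inverse-Wishart update: posterior df = prior df + n, posterior
#' scale = prior scale + scatter of the hospital coefficients about
#' `theta_bar`. Sampled by drawing the precision from the corresponding
#' Wishart and inverting.
#'
#' @param theta_mat Hospital coefficients (n x q).
#' @param theta_bar Population mean (length q).
#' @param wishart_df Prior degrees of freedom (>= q for a proper prior).
#' @param wishart_scale Prior scale matrix (q x q) or scalar c for c * I.
#' @return One q x q covariance draw (symmetric positive definite).
#' @export
draw_hyper_cov <- function(theta_mat, theta_bar, wishart_df, wishart_scale) {
  n <- nrow(theta_mat); q <- ncol(theta_mat)
  if (!is.matrix(wishart_scale)) wishart_scale <- diag(wishart_scale, q)
  dev <- sweep(theta_mat, 2L, theta_bar)
  S <- wishart_scale + crossprod(dev)
  df_post <- wishart_df + n
  Sinv <- chol2inv(.chol_safe(S))
  W <- stats::rWishart(1L, df = df_post, Sigma = Sinv)[, , 1L]
  omega <- chol2inv(.chol_safe(W))
  (omega + t(omega)) / 2
}

#' Draw the noise precision
#'
#' Conjugate Gamma update for the precision of the two-sided error v:
#' shape `tau_shape + N/2`, rate `tau_rate + sum(v^2)/2`.
#'
#' @param v Noise residuals y - frontier - u.
#' @param tau_shape,tau_rate Gamma prior parameters.
#' @return One positive precision draw.
#' @export
draw_noise_precision <- function(v, tau_shape, tau_rate) {
  if (!all(is.finite(v))) stop("non-finite residuals")
  stats::rgamma(1L, shape = tau_shape + length(v) / 2,
                rate = tau_rate + sum(v^2) / 2)
}

#' Draw the inefficiency precision
#'
#' Conjugate Gamma update for the precision of the half-normal
#' inefficiency: shape `ineff_shape + N/2`, rate `gamma0 + sum(u^2)/2`.
#'
#' @param u Current inefficiency draws (all >= 0).
#' @param ineff_shape Gamma prior shape.
#' @param gamma0 Gamma prior rate (see [compute_gamma0()]).
#' @return One positive precision draw.
#' @export
draw_ineff_precision <- function(u, ineff_shape, gamma0) {
  if (any(u < 0)) stop("inefficiency draws must be nonnegative")
  stats::rgamma(1L, shape = ineff_shape + length(u) / 2,
                rate = gamma0 + sum(u^2) / 2)
}

# Method-of-moments initialization shared by both chains.
.init_state <- function(Z, y) {
  p <- ncol(Z)
  A <- crossprod(Z) + diag(1e-8 * max(1, sum(diag(crossprod(Z))) / p), p)
  theta <- drop(solve(A, crossprod(Z, y)))
  r <- y - drop(Z %*% theta)
  u <- pmax(r, 0)
  v <- r - u
  tau <- 1 / max(stats::var(v), 1e-6)
  p_u <- 1 / max(mean(u^2), 1e-6)
  list(theta = theta, u = u, tau = tau, p_u = p_u)
}

.check_finite_state <- function(iter, ...) {
  vals <- unlist(list(...))
  if (!all(is.finite(vals)))
    stop(sprintf("sampler diverged (non-finite state) at iteration %d", iter))
}

#' Fit the fixed-coefficient (homogeneous) cost frontier
#'
#' Gibbs sampler for the translog frontier with one common coefficient
#' vector: y_it = z_it' theta + v_it + u_it, v two-sided noise, u
#' half-normal inefficiency entering costs with a positive sign (so
#' efficiency is exp(-u)). Each sweep cycles the inefficiency draws, the
#' coefficient block, the noise precision and the inefficiency precision,
#' all from conjugate full conditionals.
#'
#' @param mf A [model_frame()] (or a list with `y`, `Z`, `hospital_id`,
#'   `year`, `layout`).
#' @param priors A [prior_spec()].
#' @param cfg An [mcmc_config()].
#' @param inefficiency `"halfnormal"` (default) or `"none"`; with
#'   `"none"` the model is a plain Bayesian regression frontier (u fixed
#'   at 0, inefficiency precision not sampled).
#' @param fix_tau Optional known noise precision; when supplied, tau is
#'   held fixed instead of sampled.
#' @param verbose Print progress every `verbose` iterations (0 = quiet).
#' @return An object of class `sfa_fit` with retained draws: `theta`
#'   (n_keep x p), `tau`, `p_u`, `u` (n_keep x n_cells), and metadata
#'   (`layout`, `cells`, `priors`, `cfg`, `model = "fixed"`).
#' @export
run_fixed_chain <- function(mf, priors = prior_spec(), cfg = mcmc_config(),
                            inefficiency = c("halfnormal", "none"),
                            fix_tau = NULL, verbose = 0L) {
  inefficiency <- match.arg(inefficiency)
  Z <- mf$Z; y <- mf$y
  n <- length(y); p <- ncol(Z)
  if (n < p && priors$theta_precision < 1e-4)
    warning("fewer rows than parameters with a near-flat prior; ",
            "posterior is barely identified")
  set.seed(cfg$seed)

  st <- .init_state(Z, y)
  theta <- st$theta; u <- st$u; tau <- st$tau; p_u <- st$p_u
  if (inefficiency == "none") { u <- numeric(n); p_u <- NA_real_ }
  if (!is.null(fix_tau)) tau <- fix_tau

  ZtZ <- crossprod(Z)
  keep <- cfg$n_keep
  out_theta <- matrix(NA_real_, keep, p, dimnames = list(NULL, colnames(Z)))
  out_tau <- numeric(keep); out_pu <- numeric(keep)
  out_u <- matrix(NA_real_, keep, n)
  k <- 0L
  for (it in seq_len(cfg$n_iter)) {
    fit <- drop(Z %*% theta)
    if (inefficiency == "halfnormal")
      u <- draw_inefficiency(y - fit, tau, p_u)
    y_adj <- y - u
    A <- tau * ZtZ + diag(priors$theta_precision, p)
    theta <- drop(.mvn_prec_draw(.chol_safe(A), tau * crossprod(Z, y_adj)))
    v <- y_adj - drop(Z %*% theta)
    if (is.null(fix_tau))
      tau <- draw_noise_precision(v, priors$tau_shape, priors$tau_rate)
    if (inefficiency == "halfnormal")
      p_u <- draw_ineff_precision(u, priors$ineff_shape, priors$gamma0)
    .check_finite_state(it, theta, tau, if (is.na(p_u)) 1 else p_u, u)
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      k <- k + 1L
      out_theta[k, ] <- theta; out_tau[k] <- tau; out_pu[k] <- p_u
      out_u[k, ] <- u
    }
    if (verbose > 0L && it %% verbose == 0L)
      message(sprintf("iteration %d / %d", it, cfg$n_iter))
  }
  structure(list(
    model = "fixed", theta = out_theta, tau = out_tau, p_u = out_pu,
    u = out_u,
    cells = data.frame(hospital_id = mf$hospital_id, year = mf$year,
                       stringsAsFactors = FALSE),
    layout = mf$layout, priors = priors, cfg = cfg
  ), class = "sfa_fit")
}

#' Fit the random-coefficient (heterogeneous) cost frontier
#'
#' Hierarchical Gibbs sampler: each hospital has its own slope vector
#' theta_i ~ MVN(theta_bar, Omega) over all translog terms except the
#' intercept, which is common to all hospitals; Omega carries an
#' inverse-Wishart prior, theta_bar a diffuse normal prior. The composed
#' error is as in [run_fixed_chain()]. Each sweep cycles: inefficiency
#' draws, per-hospital slopes, the common intercept, the population mean,
#' the population covariance, the noise precision and the inefficiency
#' precision.
#'
#' @inheritParams run_fixed_chain
#' @return An `sfa_fit` with draws `beta0` (n_keep), `theta_bar`
#'   (n_keep x q), `omega_diag` (n_keep x q), `tau`, `p_u`, `u`
#'   (n_keep x n_cells), posterior-mean hospital slopes `theta_i_mean`
#'   (n_hospitals x q), and metadata (`model = "random"`).
#' @export
run_random_chain <- function(mf, priors = prior_spec(), cfg = mcmc_config(),
                             verbose = 0L) {
  Z <- mf$Z; y <- mf$y; hosp <- mf$hospital
  n <- length(y); p <- ncol(Z)
  n_h <- length(unique(hosp))
  if (n_h < 2L) stop("the hierarchical model needs at least 2 hospitals")
  q <- p - 1L                       # slopes; intercept is common
  slope_names <- colnames(Z)[-1L]
  set.seed(cfg$seed)

  wdf <- if (is.null(priors$wishart_df)) q + 2 else priors$wishart_df
  if (wdf < q) stop("wishart_df must be at least the slope dimension")
  wscale <- priors$wishart_scale
  if (!is.matrix(wscale)) wscale <- diag(wscale, q)

  st <- .init_state(Z, y)
  beta0 <- st$theta[1L]
  theta_bar <- st$theta[-1L]
  u <- st$u; tau <- st$tau; p_u <- st$p_u

  # per-hospital caches (data fixed over the chain)
  Xs <- vector("list", n_h); XtX <- vector("list", n_h)
  Xty <- vector("list", n_h); Xt1 <- vector("list", n_h)
  rows_of <- split(seq_len(n), hosp)
  for (i in seq_len(n_h)) {
    X <- Z[rows_of[[i]], -1L, drop = FALSE]
    Xs[[i]] <- X; XtX[[i]] <- crossprod(X)
    Xty[[i]] <- crossprod(X, y[rows_of[[i]]]); Xt1[[i]] <- colSums(X)
  }

  # initialize hospital slopes at ridge fits shrunk toward the pooled
  # estimate, and omega at their scatter, so the chain starts in a
  # regime where heterogeneity (if any) is visible rather than collapsed
  theta_i <- matrix(NA_real_, n_h, q)
  ridge <- max(1, mean(vapply(XtX, function(M) sum(diag(M)), 1)) / q)
  for (i in seq_len(n_h)) {
    A0 <- XtX[[i]] + diag(ridge, q)
    theta_i[i, ] <- solve(A0, Xty[[i]] - beta0 * Xt1[[i]] +
                            ridge * theta_bar)
  }
  dev0 <- sweep(theta_i, 2L, colMeans(theta_i))
  omega <- crossprod(dev0) / max(n_h - 1L, 1L) + diag(1e-6, q)

  keep <- cfg$n_keep
  out_b0 <- numeric(keep); out_tau <- numeric(keep); out_pu <- numeric(keep)
  out_tb <- matrix(NA_real_, keep, q, dimnames = list(NULL, slope_names))
  out_od <- matrix(NA_real_, keep, q, dimnames = list(NULL, slope_names))
  out_u <- matrix(NA_real_, keep, n)
  ti_sum <- matrix(0, n_h, q)
  k <- 0L
  fit_slopes <- numeric(n)
  for (i in seq_len(n_h))
    fit_slopes[rows_of[[i]]] <- drop(Xs[[i]] %*% theta_i[i, ])

  for (it in seq_len(cfg$n_iter)) {
    # 1. inefficiency
    u <- draw_inefficiency(y - beta0 - fit_slopes, tau, p_u)
    # 2. per-hospital slopes
    omega_inv <- chol2inv(.chol_safe(omega))
    ob <- omega_inv %*% theta_bar
    for (i in seq_len(n_h)) {
      ri <- rows_of[[i]]
      b <- tau * (Xty[[i]] - crossprod(Xs[[i]], u[ri]) - beta0 * Xt1[[i]]) + ob
      R <- chol(tau * XtX[[i]] + omega_inv)
      theta_i[i, ] <- backsolve(R, backsolve(R, b, transpose = TRUE) +
                                  stats::rnorm(q))
      fit_slopes[ri] <- drop(Xs[[i]] %*% theta_i[i, ])
    }
    # 3. common intercept
    r0 <- y - u - fit_slopes
    prec0 <- tau * n + priors$theta_precision
    beta0 <- stats::rnorm(1L, mean = tau * sum(r0) / prec0,
                          sd = sqrt(1 / prec0))
    # 4. population mean
    theta_bar <- draw_hyper_mean(theta_i, omega_inv, priors$theta_precision)
    # 5. population covariance
    omega <- draw_hyper_cov(theta_i, theta_bar, wdf, wscale)
    # 6. noise precision
    v <- y - beta0 - fit_slopes - u
    tau <- draw_noise_precision(v, priors$tau_shape, priors$tau_rate)
    # 7. inefficiency precision
    p_u <- draw_ineff_precision(u, priors$ineff_shape, priors$gamma0)
    .check_finite_state(it, beta0, theta_bar, tau, p_u, u)
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      k <- k + 1L
      out_b0[k] <- beta0; out_tb[k, ] <- theta_bar
      out_od[k, ] <- diag(omega)
      out_tau[k] <- tau; out_pu[k] <- p_u; out_u[k, ] <- u
      ti_sum <- ti_sum + theta_i
    }
    if (verbose > 0L && it %% verbose == 0L)
      message(sprintf("iteration %d / %d", it, cfg$n_iter))
  }
  structure(list(
    model = "random", beta0 = out_b0, theta_bar = out_tb,
    omega_diag = out_od, tau = out_tau, p_u = out_pu, u = out_u,
    theta_i_mean = ti_sum / k,
    cells = data.frame(hospital_id = mf$hospital_id, year = mf$year,
                       stringsAsFactors = FALSE),
    layout = mf$layout, priors = priors, cfg = cfg
  ), class = "sfa_fit")
}

#' @export
print.sfa_fit <- function(x, ...) {
  cat(sprintf("%s-coefficient frontier fit: %d retained draws, %d cells\n",
              x$model, length(x$tau), nrow(x$cells)))
  cat(sprintf("  posterior mean tau = %.3f, inefficiency precision = %.3f\n",
              mean(x$tau), mean(x$p_u)))
  eff <- mean(exp(-x$u)) * 100
  cat(sprintf("  mean cost efficiency = %.2f%%\n", eff))
  invisible(x)
}

#' Extract named parameter draws from a fit
#'
#' Returns a draw matrix (iterations x parameters) using the translog
#' naming (beta0, beta1, ..., rho52) plus `tau` and `p_u`; for the random
#' model the slope columns are the population means.
#'
#' @param fit An `sfa_fit`.
#' @return Numeric matrix of retained draws.
#' @export
parameter_draws <- function(fit) {
  stopifnot(inherits(fit, "sfa_fit"))
  if (fit$model == "fixed")
    cbind(fit$theta, tau = fit$tau, p_u = fit$p_u)
  else
    cbind(beta0 = fit$beta0, fit$theta_bar, tau = fit$tau, p_u = fit$p_u)
}
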