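#' Moment-match a lognormal to a target mean and standard deviation
#'
#' Returns log-scale parameters such that a lognormal has exactly the
#' requested mean and sd: `mu = ln(mean^2 / sqrt(mean^2 + sd^2))`,
#' `sigma^2 = ln(1 + sd^2 / mean^2)`.
#'
#' @param mean Target mean (positive).
#' @param sd Target standard deviation (positive; 0 allowed as the
#'   degenerate limit).
#' @return List with `meanlog`, `sdlog`.
#' @export
calibrate_lognormal <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd < 0)
    stop("mean must be positive and sd nonnegative")
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Mean efficiency implied by a half-normal inefficiency scale
#'
#' Closed form for E[exp(-u)] with u ~ N+(0, sigma_u^2):
#' `2 * exp(sigma_u^2 / 2) * pnorm(-sigma_u)`; equals 1 at sigma_u = 0.
#'
#' @param sigma_u Nonnegative inefficiency scale.
#' @return Mean efficiency in (0, 1].
#' @export
true_mean_efficiency <- function(sigma_u) {
  if (any(sigma_u < 0)) stop("sigma_u must be nonnegative")
  2 * exp(sigma_u^2 / 2) * stats::pnorm(-sigma_u)
}

# Study-scale marginal moment targets (means and sds of the hospital-year
# marginals): outputs are case-mix-weighted discharges, external
# consultations, emergencies, surgical interventions; prices are materials,
# capital and labour unit costs; cost is in thousands of euros.
.default_output_moments <- function() {
  m <- rbind(c(13317.88, 12069.50),
             c(267501.95, 239723.45),
             c(76574.57, 61087.84),
             c(12079.46, 10811.56),
             c(6.64, 0.34))           # satisfaction: generated uniform
  dimnames(m) <- list(paste0("x", 1:5), c("mean", "sd"))
  m
}
.default_price_moments <- function() {
  m <- rbind(c(166241.38, 66460.98),
             c(5850.74, 8205.62),
             c(55855.47, 9883.40))
  dimnames(m) <- list(paste0("w", 1:3), c("mean", "sd"))
  m
}

# Default first-order elasticities: weighted discharges dominate hospital
# cost; materials and capital price shares 0.30 / 0.10 (labour 0.60
# implied by homogeneity). Second-order terms zero.
.default_slopes <- function(layout) {
  J <- layout$n_outputs; S <- layout$n_prices
  theta <- stats::setNames(numeric(layout$p), layout$names)
  bx <- if (J == 5L) c(0.45, 0.12, 0.08, 0.12, 0.03) else rep(0.8 / J, J)
  dw <- if (S == 2L) c(0.30, 0.10) else rep(0.4 / S, S)
  theta[paste0("beta", seq_len(J))] <- bx
  theta[paste0("delta", seq_len(S))] <- dw
  theta
}

# E[X^a] for the generator's marginal laws (lognormal; uniform for the
# satisfaction output), used to calibrate the intercept analytically.
.power_moment_lognormal <- function(a, mean, sd) {
  p <- calibrate_lognormal(mean, sd)
  exp(a * p$meanlog + a^2 * p$sdlog^2 / 2)
}
.power_moment_uniform <- function(a, lo, hi) {
  if (abs(a) < 1e-12) return(1)
  if (abs(a + 1) < 1e-12) return(log(hi / lo) / (hi - lo))
  (hi^(a + 1) - lo^(a + 1)) / ((a + 1) * (hi - lo))
}

#' Calibrate the frontier intercept to a target mean cost
#'
#' With first-order-only coefficients and independent marginals, expected
#' cost factorizes as exp(beta0) times power moments of each output and
#' price plus the noise and inefficiency factors; the intercept matching a
#' target mean cost then has a closed form. Only exact when all
#' second-order coefficients are zero (the generator default).
#'
#' @param theta Coefficient vector over `layout` with zero second-order
#'   terms.
#' @param layout A [translog_layout()].
#' @param target_mean_cost Target E[cost].
#' @param output_moments J x 2 matrix (mean, sd).
#' @param price_moments (S+1) x 2 matrix (mean, sd); last row is the
#'   numeraire (labour).
#' @param satisfaction_bounds Bounds of the uniform satisfaction score, or
#'   `NULL` when no output is a bounded score.
#' @param satisfaction_index Which output is the bounded score (`NA` for
#'   none).
#' @param tau Noise precision (Inf for no noise).
#' @param sigma_u Half-normal inefficiency scale.
#' @return The calibrated intercept beta0.
#' @export
calibrate_intercept <- function(theta, layout, target_mean_cost,
                                output_moments, price_moments,
                                satisfaction_bounds = NULL,
                                satisfaction_index = NA_integer_,
                                tau = Inf, sigma_u = 0) {
  J <- layout$n_outputs; S <- layout$n_prices
  second <- layout$terms$type %in% c("xx", "ww", "xw")
  if (any(abs(theta[second]) > 1e-12))
    stop("intercept calibration requires zero second-order coefficients")
  lf <- 0
  for (j in seq_len(J)) {
    a <- theta[[paste0("beta", j)]]
    lf <- lf + if (!is.na(satisfaction_index) && j == satisfaction_index)
      log(.power_moment_uniform(a, satisfaction_bounds[1], satisfaction_bounds[2]))
    else
      log(.power_moment_lognormal(a, output_moments[j, 1], output_moments[j, 2]))
  }
  dsum <- 0
  for (s in seq_len(S)) {
    a <- theta[[paste0("delta", s)]]
    dsum <- dsum + a
    lf <- lf + log(.power_moment_lognormal(a, price_moments[s, 1],
                                           price_moments[s, 2]))
  }
  lf <- lf + log(.power_moment_lognormal(1 - dsum, price_moments[S + 1, 1],
                                         price_moments[S + 1, 2]))
  if (is.finite(tau)) lf <- lf + 1 / (2 * tau)
  if (sigma_u > 0)
    lf <- lf + sigma_u^2 / 2 + stats::pnorm(sigma_u, log.p = TRUE) + log(2)
  log(target_mean_cost) - lf
}

#' Configuration of the synthetic hospital-panel generator
#'
#' Defaults emulate the study panel: 278 hospitals over 2016-2019, the
#' full 5-output / 2-normalized-price translog layout, marginal moments of
#' outputs and prices matching the descriptive statistics of the study
#' sample, satisfaction uniform on its observed range (6.00-7.45), noise
#' precision 100 (v sd 0.1), half-normal inefficiency scale 0.18 (true
#' mean efficiency about 87%, the level estimated for the study's
#' heterogeneous model), heterogeneity on the first-order slopes with sd
#' `slope_sd` (default 0.05), and an intercept calibrated so expected cost
#' matches the study's 138,776.69 thousand euros.
#'
#' @param n_hospitals,n_years Panel dimensions (defaults 278 x 4).
#' @param years Calendar years (default 2016:2019).
#' @param layout A [translog_layout()] (reduced layouts are first-class
#'   for fast validation runs).
#' @param theta_bar Population-mean coefficients; `NULL` for the default
#'   first-order vector with calibrated intercept.
#' @param omega Slope covariance (q x q, q = p - 1), a scalar variance for
#'   an isotropic first-order-slope matrix, or 0 for a fixed-coefficient
#'   world; `NULL` uses `slope_sd^2` on the first-order slopes.
#' @param slope_sd Default heterogeneity sd on first-order slopes.
#' @param tau_true Noise precision (Inf = noiseless).
#' @param sigma_u_true Half-normal inefficiency scale (0 = fully
#'   efficient).
#' @param output_moments,price_moments Moment targets; `NULL` for the
#'   study defaults (rows are recycled/truncated to the layout dimension,
#'   the last price row always the numeraire labour price).
#' @param satisfaction_bounds Bounds of the uniform satisfaction score.
#' @param target_mean_cost Target expected cost (thousands).
#' @param within_sd_frac Fraction of each variable's total log-sd that is
#'   year-to-year variation within a hospital (default 0.15); the
#'   remainder is a persistent hospital level, reflecting the stability of
#'   hospital scale and local prices over a short panel. Marginal moments
#'   are preserved. Set to 1 for fully independent cells.
#' @param size_factor_sd Sd of an optional common log-size factor inducing
#'   positive correlation across outputs within a hospital (0 = off;
#'   marginal output sds are preserved by shrinking the idiosyncratic
#'   part).
#' @param center Express the generative coefficients in the centered
#'   translog parameterization (logs measured from their population
#'   means, default `TRUE`) — the same approximation point
#'   [model_frame()] uses, so estimated coefficients are directly
#'   comparable to the generative ones.
#' @param seed RNG seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_hospitals = 278L, n_years = 4L,
                             years = NULL, layout = translog_layout(),
                             theta_bar = NULL, omega = NULL,
                             slope_sd = 0.05, tau_true = 100,
                             sigma_u_true = 0.18,
                             output_moments = NULL, price_moments = NULL,
                             satisfaction_bounds = c(6.00, 7.45),
                             target_mean_cost = 138776.69,
                             within_sd_frac = 0.15,
                             size_factor_sd = 0, center = TRUE, seed = 1L) {
  if (within_sd_frac <= 0 || within_sd_frac > 1)
    stop("within_sd_frac must lie in (0, 1]")
  J <- layout$n_outputs; S <- layout$n_prices
  if (is.null(years)) years <- 2016L + seq_len(n_years) - 1L
  if (length(years) != n_years) stop("years length must equal n_years")
  if (is.null(output_moments)) {
    om <- .default_output_moments()
    output_moments <- om[seq_len(min(J, nrow(om))), , drop = FALSE]
    if (J > nrow(om)) stop("no default moments beyond 5 outputs")
  }
  if (is.null(price_moments)) {
    pm <- .default_price_moments()
    if (S + 1L > nrow(pm)) stop("no default moments beyond 3 prices")
    price_moments <- pm[c(seq_len(S), nrow(pm)), , drop = FALSE]
  }
  if (any(output_moments[, 1] <= 0) || any(price_moments[, 1] <= 0))
    stop("moment targets must be positive")
  satisfaction_index <- if (J == 5L) 5L else NA_integer_

  q <- layout$p - 1L
  if (is.null(omega)) omega <- slope_sd^2
  if (!is.matrix(omega)) {
    v <- stats::setNames(numeric(q), layout$names[-1L])
    first <- layout$terms$type[-1L] %in% c("x", "w")
    v[first] <- as.numeric(omega)
    omega <- diag(v, q)
    dimnames(omega) <- list(layout$names[-1L], layout$names[-1L])
  }
  if (nrow(omega) != q) stop("omega dimension must be layout p - 1")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("omega must be positive semidefinite")

  # population log-scale centers of outputs and price ratios
  centers <- numeric(J + S)
  for (j in seq_len(J)) {
    centers[j] <- if (!is.na(satisfaction_index) && j == satisfaction_index) {
      lo <- satisfaction_bounds[1]; hi <- satisfaction_bounds[2]
      (hi * (log(hi) - 1) - lo * (log(lo) - 1)) / (hi - lo)   # E[ln U]
    } else calibrate_lognormal(output_moments[j, 1], output_moments[j, 2])$meanlog
  }
  mw <- vapply(seq_len(S + 1L), function(s)
    calibrate_lognormal(price_moments[s, 1], price_moments[s, 2])$meanlog,
    numeric(1))
  centers[J + seq_len(S)] <- mw[seq_len(S)] - mw[S + 1L]
  if (!center) centers <- numeric(J + S)

  if (is.null(theta_bar)) {
    theta_bar <- .default_slopes(layout)
    b0 <- calibrate_intercept(theta_bar, layout, target_mean_cost,
      output_moments, price_moments, satisfaction_bounds, satisfaction_index,
      tau_true, sigma_u_true)
    # shift to the centered parameterization
    theta_bar[1L] <- b0 +
      sum(theta_bar[paste0("beta", seq_len(J))] * centers[seq_len(J)]) +
      sum(theta_bar[paste0("delta", seq_len(S))] * centers[J + seq_len(S)])
  }
  if (length(theta_bar) != layout$p) stop("theta_bar length must be layout p")

  structure(list(
    n_hospitals = as.integer(n_hospitals), n_years = as.integer(n_years),
    years = as.integer(years), layout = layout,
    theta_bar = theta_bar, omega = omega,
    tau_true = tau_true, sigma_u_true = sigma_u_true,
    output_moments = output_moments, price_moments = price_moments,
    satisfaction_bounds = satisfaction_bounds,
    satisfaction_index = satisfaction_index,
    within_sd_frac = within_sd_frac,
    size_factor_sd = size_factor_sd, centers = centers,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# MVN sampler tolerant of positive-semidefinite covariance.
.rmvnorm_psd <- function(n, mean, sigma) {
  q <- length(mean)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), q)
  t(mean + L %*% matrix(stats::rnorm(n * q), q, n))
}

#' Generate a synthetic hospital-year panel with known ground truth
#'
#' Simulates the hierarchical cost-frontier data-generating process:
#' hospital slopes theta_i ~ MVN(theta_bar, Omega) around a common
#' intercept; outputs and prices drawn from lognormals moment-matched to
#' the configured targets (satisfaction uniform on its bounds); noise
#' v ~ N(0, 1/tau); inefficiency u ~ N+(0, sigma_u^2); and cost assembled
#' as `C = w_labour * exp(z'theta_i + v + u)`. Omega = 0 yields the
#' fixed-coefficient special case. Fully reproducible under the configured
#' seed.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_panel`: `panel` (a `hospital_panel`
#'   data frame readable by [to_model_rows()]) and `truth` (theta_bar,
#'   omega, per-hospital slopes, per-cell u, v, y, tau, sigma_u, layout
#'   dimensions, seed).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  lay <- config$layout
  J <- lay$n_outputs; S <- lay$n_prices
  n_h <- config$n_hospitals; n_t <- config$n_years
  n <- n_h * n_t
  hosp <- rep(seq_len(n_h), each = n_t)
  year <- rep(config$years, times = n_h)

  # hospital slopes around the common intercept
  q <- lay$p - 1L
  slopes_i <- .rmvnorm_psd(n_h, config$theta_bar[-1L], config$omega)

  sf <- if (config$size_factor_sd > 0)
    rep(stats::rnorm(n_h, 0, config$size_factor_sd), each = n_t) else 0

  # persistent hospital level + year-to-year variation, marginals preserved
  f <- config$within_sd_frac
  draw_persistent_log <- function(sdlog, extra_between = 0) {
    v_within <- (sdlog * f)^2
    v_between <- max(sdlog^2 - v_within - extra_between^2, 0)
    rep(stats::rnorm(n_h, 0, sqrt(v_between)), each = n_t) +
      stats::rnorm(n, 0, sqrt(v_within))
  }
  X <- matrix(NA_real_, n, J)
  for (j in seq_len(J)) {
    if (!is.na(config$satisfaction_index) && j == config$satisfaction_index) {
      X[, j] <- stats::runif(n, config$satisfaction_bounds[1],
                             config$satisfaction_bounds[2])
    } else {
      p <- calibrate_lognormal(config$output_moments[j, 1],
                               config$output_moments[j, 2])
      X[, j] <- exp(p$meanlog + sf +
                      draw_persistent_log(p$sdlog, config$size_factor_sd))
    }
  }
  W <- matrix(NA_real_, n, S + 1L)
  for (s in seq_len(S + 1L)) {
    p <- calibrate_lognormal(config$price_moments[s, 1],
                             config$price_moments[s, 2])
    W[, s] <- exp(p$meanlog + draw_persistent_log(p$sdlog))
  }

  logx <- sweep(log(X), 2L, config$centers[seq_len(J)])
  logw <- sweep(log(W[, seq_len(S), drop = FALSE]) - log(W[, S + 1L]),
                2L, config$centers[J + seq_len(S)])
  Z <- build_design_matrix(lay, logx, logw)
  frontier <- Z[, 1L] * config$theta_bar[1L] +
    rowSums(Z[, -1L, drop = FALSE] * slopes_i[hosp, , drop = FALSE])

  u <- if (config$sigma_u_true > 0)
    config$sigma_u_true * abs(stats::rnorm(n)) else numeric(n)
  v <- if (is.finite(config$tau_true))
    stats::rnorm(n, 0, sqrt(1 / config$tau_true)) else numeric(n)
  y <- frontier + v + u
  cost <- W[, S + 1L] * exp(y)

  panel <- data.frame(hospital_id = sprintf("H%03d", hosp), year = year,
                      cost = cost, stringsAsFactors = FALSE)
  for (j in seq_len(J)) panel[[paste0("x", j)]] <- X[, j]
  for (s in seq_len(S + 1L)) panel[[paste0("w", s)]] <- W[, s]
  panel <- as_hospital_panel(panel, n_outputs = J, n_raw_prices = S + 1L)

  structure(list(
    panel = panel,
    truth = list(theta_bar = config$theta_bar, omega = config$omega,
                 slopes_i = slopes_i, u = u, v = v, y = y,
                 frontier = frontier, centers = config$centers,
                 tau = config$tau_true, sigma_u = config$sigma_u_true,
                 n_outputs = J, n_prices = S, seed = config$seed)
  ), class = "synthetic_panel")
}

#' Write a synthetic panel and its ground-truth sidecar
#'
#' @param sp A `synthetic_panel`.
#' @param path CSV path for the panel (the dialect [read_panel()] reads).
#' @param truth_path Optional JSON path for the generative truth.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(sp, path, truth_path = NULL) {
  stopifnot(inherits(sp, "synthetic_panel"))
  utils::write.csv(as.data.frame(sp$panel), path, row.names = FALSE)
  if (!is.null(truth_path)) {
    tr <- sp$truth
    tr$slopes_i <- unname(apply(tr$slopes_i, 1L, as.numeric, simplify = FALSE))
    tr$omega <- unname(apply(tr$omega, 1L, as.numeric, simplify = FALSE))
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
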