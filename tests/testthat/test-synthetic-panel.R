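test_that("lognormal calibration reproduces the target moments exactly", {
  p <- calibrate_lognormal(1, 1)
  expect_equal(p$meanlog, -log(2) / 2)
  expect_equal(p$sdlog, sqrt(log(2)))
  for (tgt in list(c(13317.88, 12069.50), c(55855.47, 9883.40))) {
    q <- calibrate_lognormal(tgt[1], tgt[2])
    expect_equal(exp(q$meanlog + q$sdlog^2 / 2), tgt[1])
    expect_equal(sqrt((exp(q$sdlog^2) - 1) * exp(2 * q$meanlog + q$sdlog^2)),
                 tgt[2])
  }
  expect_equal(calibrate_lognormal(5, 0)$sdlog, 0)  # degenerate limit
  expect_error(calibrate_lognormal(-1, 1), "positive")
})

test_that("closed-form mean efficiency matches its Monte Carlo value", {
  expect_equal(true_mean_efficiency(0), 1)
  expect_equal(true_mean_efficiency(0.18), 0.871152, tolerance = 1e-6)
  expect_equal(true_mean_efficiency(0.3), 0.799351, tolerance = 1e-6)
  # decreasing in sigma_u
  s <- seq(0, 1, 0.1)
  expect_true(all(diff(true_mean_efficiency(s)) < 0))
  set.seed(61)
  u <- 0.25 * abs(rnorm(2e5))
  mc <- mean(exp(-u))
  expect_lt(abs(mc - true_mean_efficiency(0.25)),
            4 * sd(exp(-u)) / sqrt(2e5))
})

test_that("the calibrated intercept hits the target mean cost analytically", {
  lay <- translog_layout(2, 1)
  cfg <- generator_config(n_hospitals = 4000, n_years = 1, layout = lay,
    omega = 0, tau_true = 100, sigma_u_true = 0.2, within_sd_frac = 1,
    center = FALSE, seed = 62)
  sp <- generate_panel(cfg)
  expect_equal(mean(sp$panel$cost), 138776.69, tolerance = 0.1)
  expect_error(calibrate_intercept(
    stats::setNames(rep(0.1, lay$p), lay$names), lay, 1000,
    cfg$output_moments, cfg$price_moments), "second-order")
})

test_that("generated panels are reproducible and satisfy their own frontier", {
  sw <- small_world(seed = 63, n_hospitals = 15)
  sw2 <- small_world(seed = 63, n_hospitals = 15)
  expect_identical(sw$sp$panel$cost, sw2$sp$panel$cost)

  sp <- sw$sp
  rows <- to_model_rows(sp$panel)
  # the recorded log normalized cost is reproduced from the panel file
  expect_equal(rows$y, sp$truth$y, tolerance = 1e-12)
  # and decomposes exactly into frontier + noise + inefficiency
  expect_equal(sp$truth$y, sp$truth$frontier + sp$truth$v + sp$truth$u)
  expect_true(all(sp$truth$u >= 0))

  # rebuilding the design at the generator's centers reproduces the
  # frontier from the stored hospital slopes
  mf <- model_frame(rows, translog_layout(2, 1), center = sp$truth$centers)
  hosp <- rep(seq_len(15), each = 4)
  fr <- mf$Z[, 1] * sp$truth$theta_bar[1] +
    rowSums(mf$Z[, -1, drop = FALSE] * sp$truth$slopes_i[hosp, , drop = FALSE])
  expect_equal(fr, sp$truth$frontier, tolerance = 1e-10)
})

test_that("generated marginals emulate the study's descriptive statistics", {
  cfg <- generator_config(seed = 64)        # full 278 x 4 study defaults
  sp <- generate_panel(cfg)
  p <- sp$panel
  expect_equal(nrow(p), 278 * 4)
  expect_equal(sort(unique(p$year)), 2016:2019)
  # output and price means within 10% of the Table-style targets
  tgt_x <- c(13317.88, 267501.95, 76574.57, 12079.46)
  for (j in 1:4)
    expect_lt(abs(mean(p[[paste0("x", j)]]) / tgt_x[j] - 1), 0.10)
  tgt_w <- c(166241.38, 5850.74, 55855.47)
  for (s in 1:3)
    expect_lt(abs(mean(p[[paste0("w", s)]]) / tgt_w[s] - 1), 0.15)
  # satisfaction stays inside its observed range
  expect_true(all(p$x5 >= 6.00 & p$x5 <= 7.45))
  # mean cost near the study's 138.8 million (heavy-tailed, generous band)
  expect_lt(abs(mean(p$cost) / 138776.69 - 1), 0.25)
  # the panel passes its own validation
  expect_true(validate_panel(p)$pass)
})

test_that("persistence splits log variance without changing marginals", {
  # within_sd_frac = 0.15: year-to-year variation within a hospital is a
  # small share of the total; marginal spread is preserved
  lay <- translog_layout(2, 1)
  base <- generator_config(n_hospitals = 400, n_years = 4, layout = lay,
    omega = 0, sigma_u_true = 0, tau_true = Inf, seed = 65)
  iid <- generator_config(n_hospitals = 400, n_years = 4, layout = lay,
    omega = 0, sigma_u_true = 0, tau_true = Inf, within_sd_frac = 1,
    seed = 65)
  lp <- log(generate_panel(base)$panel$x1)
  li <- log(generate_panel(iid)$panel$x1)
  expect_equal(sd(lp), sd(li), tolerance = 0.1)       # marginals agree
  wi_p <- mean(tapply(lp, rep(1:400, each = 4), sd))
  wi_i <- mean(tapply(li, rep(1:400, each = 4), sd))
  expect_lt(wi_p, 0.3 * wi_i)   # within-hospital variation much smaller
})

test_that("omega = 0 collapses to identical hospital slopes", {
  lay <- translog_layout(2, 1)
  cfg <- generator_config(n_hospitals = 10, n_years = 2, layout = lay,
                          omega = 0, seed = 66)
  sp <- generate_panel(cfg)
  expect_equal(max(apply(sp$truth$slopes_i, 2, sd)), 0)
  cfg2 <- generator_config(n_hospitals = 10, n_years = 2, layout = lay,
                           slope_sd = 0.3, seed = 66)
  sp2 <- generate_panel(cfg2)
  expect_gt(max(apply(sp2$truth$slopes_i, 2, sd)), 0.05)
})

test_that("the truth sidecar serializes alongside the panel", {
  sw <- small_world(seed = 67, n_hospitals = 5)
  f <- tempfile(fileext = ".csv"); ft <- tempfile(fileext = ".json")
  write_panel(sw$sp, f, ft)
  tr <- jsonlite::fromJSON(ft)
  expect_equal(tr$sigma_u, 0.3)
  expect_equal(tr$tau, 100)
  expect_equal(length(tr$u), 20)
  unlink(c(f, ft))
})
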