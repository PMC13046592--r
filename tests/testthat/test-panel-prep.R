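test_that("deflation rescales nominal values by the index ratio", {
  expect_equal(deflate_monetary(100, 80, 100), 125)
  expect_equal(deflate_monetary(c(50, 100), 104.2, 100),
               c(50, 100) * 100 / 104.2)
  # base-year values are unchanged
  expect_equal(deflate_monetary(138776.69, 100, 100), 138776.69)
  expect_error(deflate_monetary(100, 0, 100), "positive")
  expect_error(deflate_monetary(100, 100, -1), "positive")
})

test_that("deflating a mean annual cost at a realistic CPI matches hand arithmetic", {
  # 138776.69 * 100 / 104.2, computed independently
  expect_equal(deflate_monetary(138776.69, 104.2, 100), 133183.0038387716,
               tolerance = 1e-12)
})

test_that("deflation then logging equals logging then adding the log-deflator", {
  x <- c(138776.69, 50, 0.3)
  idx <- 104.2; base <- 100
  expect_equal(log(deflate_monetary(x, idx, base)),
               log(x) + log(base / idx))
})

test_that("case-mix weighting scales discharges by the DRG weight", {
  expect_equal(case_mix_adjust(1000, 1.2), 1200)
  expect_equal(case_mix_adjust(0, 2), 0)
  expect_error(case_mix_adjust(-1, 1), "nonnegative")
  expect_error(case_mix_adjust(10, 0), "positive")
})

test_that("a clean panel validates and an unbalanced one only draws notes", {
  p <- tiny_panel()
  v <- validate_panel(p)
  expect_true(v$pass)
  expect_equal(nrow(v$issues), 0L)

  p2 <- tiny_panel()[-2L, ]            # hospital A loses 2017
  p2 <- as_hospital_panel(p2, 2L, 2L)
  v2 <- validate_panel(p2)
  expect_true(v2$pass)                 # unbalanced is accepted
  expect_true(any(v2$issues$severity == "note" &
                  v2$issues$hospital_id == "A"))
})

test_that("validation rejects duplicate keys, nonpositive values and NAs", {
  p <- tiny_panel()
  dup <- as_hospital_panel(rbind(p, p[1L, ]), 2L, 2L)
  expect_false(validate_panel(dup)$pass)

  bad <- tiny_panel(); bad$cost[1] <- -5
  expect_false(validate_panel(as_hospital_panel(bad, 2L, 2L))$pass)

  bad <- tiny_panel(); bad$w2[2] <- 0
  expect_false(validate_panel(as_hospital_panel(bad, 2L, 2L))$pass)

  bad <- tiny_panel(); bad$x1[3] <- 0  # log undefined
  expect_false(validate_panel(as_hospital_panel(bad, 2L, 2L))$pass)

  bad <- tiny_panel(); bad$x2[4] <- NA
  expect_false(validate_panel(as_hospital_panel(bad, 2L, 2L))$pass)
})

test_that("model rows impose linear homogeneity by price normalization", {
  p <- tiny_panel()
  rows <- to_model_rows(p)
  expect_equal(rows$y, log(p$cost) - log(p$w2))
  expect_equal(rows$logw1, log(p$w1) - log(p$w2))
  expect_equal(rows$logx1, log(p$x1))

  # scaling all raw prices by lambda scales cost by lambda and leaves
  # every regressor and the normalized response's frontier relation intact
  lam <- 3.7
  p3 <- p; p3$w1 <- lam * p$w1; p3$w2 <- lam * p$w2; p3$cost <- lam * p$cost
  rows3 <- to_model_rows(as_hospital_panel(p3, 2L, 2L))
  expect_equal(rows3$y, rows$y)
  expect_equal(rows3$logw1, rows$logw1)
})

test_that("invalid panels are rejected with hospital-year context", {
  bad <- tiny_panel(); bad$cost[2] <- -1
  expect_error(to_model_rows(as_hospital_panel(bad, 2L, 2L)),
               "A/2017.*nonpositive cost")
})

test_that("the estimation frame centers logs at sample means by default", {
  rows <- to_model_rows(tiny_panel())
  mf <- model_frame(rows)
  expect_equal(mf$centers,
               c(mean(rows$logx1), mean(rows$logx2), mean(rows$logw1)),
               ignore_attr = TRUE)
  # centered first-order columns average to zero
  expect_equal(mean(mf$Z[, "beta1"]), 0)
  expect_equal(mean(mf$Z[, "delta1"]), 0)

  mf0 <- model_frame(rows, center = FALSE)
  expect_equal(mf0$centers, numeric(3))
  expect_equal(mf0$Z[, "beta1"], rows$logx1, ignore_attr = TRUE)

  mfc <- model_frame(rows, center = c(1, 2, 0.5))
  expect_equal(mfc$Z[, "beta1"], rows$logx1 - 1, ignore_attr = TRUE)
})

test_that("centering reparameterizes the frontier without changing fit", {
  # a frontier expressed in raw logs has an exactly equivalent centered
  # form: same fitted values once the intercept absorbs the shift
  rows <- to_model_rows(tiny_panel())
  mf0 <- model_frame(rows, center = FALSE)
  mf1 <- model_frame(rows)
  theta0 <- runif(ncol(mf0$Z), -0.5, 0.5)
  fit0 <- drop(mf0$Z %*% theta0)
  # refit on the centered design by least squares: fitted values agree
  theta1 <- qr.solve(mf1$Z, fit0)
  expect_equal(drop(mf1$Z %*% theta1), fit0, tolerance = 1e-8)
})

test_that("panel CSV round-trips through write and read", {
  sw <- small_world(seed = 7, n_hospitals = 5)
  f <- tempfile(fileext = ".csv")
  write_panel(sw$sp, f)
  back <- read_panel(f, n_outputs = 2L, n_raw_prices = 2L)
  expect_equal(nrow(back), nrow(sw$sp$panel))
  expect_equal(back$cost, sw$sp$panel$cost, tolerance = 1e-12)
  unlink(f)
})
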