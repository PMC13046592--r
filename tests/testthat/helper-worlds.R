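# Shared fixture builders for the test suite.

# A tiny hand-written valid panel (2 hospitals x 2 years, 2 outputs,
# 2 raw prices).
tiny_panel <- function() {
  df <- data.frame(
    hospital_id = c("A", "A", "B", "B"),
    year = c(2016L, 2017L, 2016L, 2017L),
    cost = c(1000, 1100, 2000, 2100),
    x1 = c(10, 11, 20, 21),
    x2 = c(5, 6, 7, 8),
    w1 = c(2, 2.1, 2.2, 2.3),
    w2 = c(4, 4.1, 4.2, 4.3),
    stringsAsFactors = FALSE)
  as_hospital_panel(df, n_outputs = 2L, n_raw_prices = 2L)
}

# A reduced synthetic world used by chain smoke tests: small enough to
# fit in seconds, large enough for the samplers to be well behaved.
small_world <- function(seed = 42, slope_sd = 0.05, sigma_u = 0.3,
                        tau = 100, n_hospitals = 30, within_sd_frac = 1) {
  lay <- translog_layout(2, 1)
  cfg <- generator_config(n_hospitals = n_hospitals, n_years = 4,
    layout = lay, slope_sd = slope_sd, sigma_u_true = sigma_u,
    tau_true = tau, within_sd_frac = within_sd_frac, seed = seed)
  sp <- generate_panel(cfg)
  list(config = cfg, sp = sp,
       mf = model_frame(to_model_rows(sp$panel), lay))
}

# Minimal model-frame-like list around an arbitrary design matrix, for
# exercising the fixed chain outside the translog pipeline.
raw_frame <- function(Z, y) {
  n <- nrow(Z)
  list(y = y, Z = Z, hospital = rep(1L, n),
       hospital_id = rep("H1", n), year = rep(2016L, n), layout = NULL)
}
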