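# Generator: configuration validation, determinism, degenerate cases,
# cadence and latent-time calibration, artifact injection.

test_that("configuration objects validate their fields by name", {
  expect_error(dist_spec("weibull", shape = -1, scale = 10), "shape")
  expect_error(dist_spec("uniform", min = 5, max = 2), "max")
  expect_error(dist_spec("weibull", shape = 1), "scale")
  expect_error(dist_spec("weibull", shape = 1, scale = 2, cure = 1.5),
               "cure")
  expect_error(gap_lognormal(0, 1, 2), "median")
  expect_error(gap_lognormal(5, 8, 2), "q25")
  expect_error(variable_spec("x", grid_step_h = 5), "grid_step_h")
  expect_error(variable_spec("x", lo = 2, hi = 1), "lo")
  expect_error(signature_spec(10, onset_lag_h = 0), "onset_lag_h")
  expect_error(signature_spec(10, onset_lag_h = 80), "onset_lag_h")
  expect_error(signature_spec(10, noise_sd = -1), "noise_sd")
  base <- marker_recovery_config(10)
  expect_error(
    sim_config(n_patients = 0, event_time_dist = base$event_time_dist,
               death_time_dist = base$death_time_dist,
               discharge_time_dist = base$discharge_time_dist,
               variable_specs = base$variable_specs,
               signatures = base$signatures,
               sampling_gaps = base$sampling_gaps),
    "n_patients")
  expect_error(
    sim_config(n_patients = 5, event_time_dist = base$event_time_dist,
               death_time_dist = base$death_time_dist,
               discharge_time_dist = base$discharge_time_dist,
               variable_specs = base$variable_specs,
               signatures = base$signatures,
               sampling_gaps = list(), artifact_rate = 2),
    "sampling_gaps|artifact_rate")
})

test_that("gap spec matches the median/IQR parameterization", {
  g <- gap_lognormal(5.4, 2.3, 8.3)
  expect_equal(g$meanlog, log(5.4))
  expect_equal(g$sdlog, log(8.3 / 2.3) / (2 * qnorm(0.75)))
})

test_that("identical (config, seed) reproduces the cohort exactly", {
  cfg <- default_sim_config(n_patients = 40, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$patients, b$cohort$patients)
  expect_identical(a$cohort$measurements, b$cohort$measurements)
  expect_identical(a$cohort$procedures, b$cohort$procedures)
  expect_equal(tibble::as_tibble(a$truth), tibble::as_tibble(b$truth))
  # a different seed changes the draws
  c2 <- simulate_cohort(default_sim_config(n_patients = 40, seed = 12))
  expect_false(identical(a$cohort$measurements, c2$cohort$measurements))
})

test_that("noiseless signature-free series are constant at baseline", {
  cfg <- sim_config(
    n_patients = 1, horizon_h = 192,
    event_time_dist = dist_spec("uniform", min = 80, max = 188),
    death_time_dist = dist_spec("none"),
    discharge_time_dist = dist_spec("none"),
    variable_specs = list(variable_spec("marker")),
    signatures = list(marker = signature_spec(10, baseline_sd = 0,
                                              net_change = 0,
                                              noise_sd = 0)),
    sampling_gaps = list(marker = gap_lognormal(2, 1.5, 3)),
    seed = 3
  )
  sim <- simulate_cohort(cfg)
  expect_true(nrow(sim$cohort$measurements) > 10)
  expect_true(all(sim$cohort$measurements$value == 10))
})

test_that("noiseless measurements follow the flat-then-ramp signature", {
  cfg <- marker_recovery_config(15, "none", net_change = 2, seed = 9)
  cfg$signatures$marker <- signature_spec(10, baseline_sd = 0,
                                          onset_lag_h = 72,
                                          net_change = 2, noise_sd = 0)
  sim <- simulate_cohort(cfg)
  m <- sim$cohort$measurements
  tr <- sim$truth
  t_star <- tr$T_star_h[match(m$patient_id, tr$patient_id)]
  frac <- pmin(pmax((m$time_h - (t_star - 72)) / 72, 0), 1)
  expect_equal(m$value, 10 + 2 * frac, tolerance = 1e-12)
  # the net accumulated from T*-72 to T* is exactly the configured change
  expect_equal(
    (10 + 2 * pmin(pmax((tr$T_star_h - (tr$T_star_h - 72)) / 72, 0), 1)) -
      (10 + 2 * 0),
    rep(2, nrow(tr)))
})

test_that("sampling cadence reproduces the configured median gap", {
  sim <- simulate_cohort(default_sim_config(n_patients = 500, seed = 21))
  g <- summarize_gaps(sim$cohort$measurements)
  glu <- g[g$variable == "glucose", ]
  expect_lt(abs(glu$median_h - 5.4), 0.5)
})

test_that("latent event times follow the configured distribution", {
  cfg <- marker_recovery_config(5000, "none", seed = 31)
  cfg$event_time_dist <- dist_spec("exponential", rate = 1 / 100)
  et <- simulate_event_times(cfg)
  p_true <- 1 - exp(-72 / 100)
  p_emp <- mean(et$T_star_h <= 72)
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / 5000))
})

test_that("degenerate competing distributions give all-event or all-censored", {
  cfg <- marker_recovery_config(200, "none", seed = 5)
  et <- simulate_event_times(cfg) # death and discharge never occur
  expect_true(all(et$status[et$T_star_h <= 192] == 1))
  cfg2 <- cfg
  cfg2$event_time_dist <- dist_spec("none")
  et2 <- simulate_event_times(cfg2)
  expect_true(all(et2$status == 0))
  expect_true(all(et2$X_h == 192))
})

test_that("observed event proportions match numerically integrated truth", {
  cfg <- marker_recovery_config(5000, "none", seed = 41)
  cfg$event_time_dist <- dist_spec("weibull", shape = 1.3, scale = 120)
  cfg$death_time_dist <- dist_spec("exponential", rate = 1 / 300)
  cfg$discharge_time_dist <- dist_spec("uniform", min = 24, max = 400)
  et <- simulate_event_times(cfg)
  f_e <- function(t) dweibull(t, 1.3, 120)
  s_d <- function(t) exp(-t / 300)
  s_c <- function(t) 1 - punif(t, 24, 400)
  p_true <- integrate(function(t) f_e(t) * s_d(t) * s_c(t), 0, 192)$value
  p_emp <- mean(et$status == 1)
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / 5000))
})

test_that("artifact injection honours its rate and guarantees", {
  m <- simulate_cohort(default_sim_config(n_patients = 60,
                                          seed = 8))$cohort$measurements
  m <- m[m$variable %in% c("glucose", "sodium", "wbc"), ]
  expect_identical(inject_artifacts(m, 0, seed = 1)$value, m$value)
  one <- m[m$patient_id == m$patient_id[1] & m$variable == "glucose", ]
  one <- head(one, 10)
  allinj <- inject_artifacts(one, 1, seed = 2)
  expect_true(all(allinj$injected))
  # count at rate 0.05 lies in the binomial 99% interval
  big <- m[rep(seq_len(nrow(m)), length.out = 10000), ]
  big$time_h <- seq_len(nrow(big)) # keep rows distinct in time
  inj <- inject_artifacts(big, 0.05, seed = 3)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(sum(inj$injected), bounds[1])
  expect_lte(sum(inj$injected), bounds[2])
})
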