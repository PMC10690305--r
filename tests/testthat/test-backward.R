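# Event-aligned backward estimation: alignment, weights, quantiles,
# trajectories, scatters.

hourly_const <- function(id, hours, value, variable = "m") {
  tibble::tibble(patient_id = id, variable = variable, hour = hours,
                 value = value, observed = TRUE)
}

rec1 <- function(id, x, status = 1L) {
  tibble::tibble(patient_id = id, outcome = "mls5", X_h = x,
                 status = status, censor_reason = "none")
}

test_that("alignment indexes hours backward from the outcome", {
  al <- align_backward(hourly_const("P1", 0:10, 7), rec1("P1", 10), "m",
                       s_max = 15)
  expect_equal(unname(al$values[1, 1:11]), rep(7, 11))
  expect_true(all(is.na(al$values[1, 12:16]))) # before admission
  # an affine series aligns to Y(X) - s
  h <- hourly_const("P2", 0:50, 0:50)
  al2 <- align_backward(h, rec1("P2", 50), "m", s_max = 20)
  expect_equal(unname(al2$values[1, ]), 50 - (0:20))
  # no cases: empty matrix, all-missing estimates
  al3 <- align_backward(h, rec1("P2", 50, status = 0L), "m")
  expect_equal(nrow(al3$values), 0)
  est3 <- backward_estimate(al3)
  expect_true(all(est3$masked))
  expect_true(all(is.na(est3$mean)))
})

test_that("a case with no series yields an all-missing row", {
  h <- hourly_const("P1", 0:10, 7)
  recs <- dplyr::bind_rows(rec1("P1", 10), rec1("P9", 20))
  al <- align_backward(h, recs, "m", s_max = 5)
  expect_equal(nrow(al$values), 2)
  expect_true(all(is.na(al$values["P9", ])))
})

test_that("IPCW weights reduce to 1/n without censoring and follow
          1/G(X-) with it", {
  recs <- dplyr::bind_rows(rec1("a", 10), rec1("b", 50), rec1("c", 30))
  w <- ipcw_weights(recs, censoring_km(recs))
  expect_equal(w$weight, rep(1 / 3, 3))
  # one censoring event at 20 halves G for the later case:
  # raw weights (1, 2), normalized (1/3, 2/3)
  recs2 <- dplyr::bind_rows(rec1("a", 10), rec1("b", 20, status = 0L),
                            rec1("c", 30))
  G <- censoring_km(recs2)
  expect_equal(G_left(G, c(10, 30)), c(1, 0.5))
  w2 <- ipcw_weights(recs2, G)
  expect_equal(w2$weight, c(1 / 3, 0, 2 / 3))
  # a single case is fully weighted regardless of G
  recs3 <- dplyr::bind_rows(rec1("a", 30), rec1("b", 20, status = 0L))
  expect_equal(ipcw_weights(recs3, censoring_km(recs3))$weight, c(1, 0))
  # positivity violation is an error naming the patient (a KM fitted to
  # the records themselves can never reach 0 before a case, so feed a
  # degenerate censoring survival directly)
  G0 <- structure(list(time = 5, surv = 0, death = "censoring"),
                  class = "censoring_km")
  expect_error(ipcw_weights(rec1("b", 20), G0), "b")
})

test_that("weighted quantiles invert the weighted CDF left-continuously", {
  expect_equal(weighted_quantile(c(1, 2, 3), probs = 0.5), 2)
  expect_equal(weighted_quantile(c(1, 3), c(0.5, 0.5), 0.5), 1)
  expect_equal(weighted_quantile(c(1, 3), c(0.4, 0.6), 0.5), 3)
  expect_equal(weighted_quantile(numeric(), numeric(), 0.5), NA_real_)
  expect_error(weighted_quantile(c(1, 2), c(-1, 1), 0.5), ">= 0")
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(20)
    w <- runif(20)
    q <- weighted_quantile(x, w)
    expect_true(q[1] <= q[2] && q[2] <= q[3])
    # equal weights reduce to the sort-based empirical quantile
    expect_equal(weighted_quantile(x, rep(1, 20), c(0.25, 0.5, 0.75)),
                 c(oracle_quantile(x, 0.25), oracle_quantile(x, 0.5),
                   oracle_quantile(x, 0.75)))
  }
})

test_that("backward means average available cases with renormalized
          weights", {
  h <- dplyr::bind_rows(hourly_const("P1", 0:30, 10),
                        hourly_const("P2", 0:40, 12))
  recs <- dplyr::bind_rows(rec1("P1", 30), rec1("P2", 40))
  est <- backward_estimate(align_backward(h, recs, "m", s_max = 40),
                           min_n = 1)
  expect_equal(est$mean[est$lag_h == 24], 11)
  # P1's series spans only 30h: beyond lag 30 only P2 contributes
  expect_equal(est$mean[est$lag_h == 35], 12)
  expect_equal(est$n_eff[est$lag_h == 35], 1)
  # constant cohort: constant trajectory
  expect_true(all(est$q50[est$lag_h <= 30] == 10))
})

test_that("lags with fewer than min_n contributing cases are masked, not
          zero", {
  h <- dplyr::bind_rows(hourly_const("P1", 0:30, 10),
                        hourly_const("P2", 0:40, 12))
  recs <- dplyr::bind_rows(rec1("P1", 30), rec1("P2", 40))
  est <- backward_estimate(align_backward(h, recs, "m", s_max = 40),
                           min_n = 2)
  expect_true(all(est$masked[est$lag_h > 30]))
  expect_true(all(is.na(est$mean[est$masked])))
  expect_true(all(is.na(est$q50[est$masked])))
  expect_false(any(est$masked[est$lag_h <= 30]))
  expect_true(all(est$q25 <= est$q50 & est$q50 <= est$q75, na.rm = TRUE))
})

test_that("without censoring the weighted estimator equals brute-force
          case-only statistics at every lag", {
  cfg <- marker_recovery_config(40, "none", net_change = 1, seed = 17)
  sim <- simulate_cohort(cfg)
  rec <- records_from_truth(sim$truth)
  h <- hourly_series(sim$cohort$measurements, cfg$variable_specs, rec)
  w <- ipcw_weights(rec, censoring_km(rec))
  est <- backward_estimate(align_backward(h, rec, "marker"), w, min_n = 1)
  orc <- oracle_backward(h, rec, "marker")
  defined <- !est$masked
  expect_equal(est$n_eff, orc$n)
  expect_equal(est$mean[defined], orc$mean[defined], tolerance = 1e-12)
  expect_equal(est$q25[defined], orc$q25[defined], tolerance = 1e-12)
  expect_equal(est$q50[defined], orc$q50[defined], tolerance = 1e-12)
  expect_equal(est$q75[defined], orc$q75[defined], tolerance = 1e-12)
})

test_that("backward scatter collects raw pre-outcome measurements", {
  m <- tibble::tibble(
    patient_id = c("A", "A", "A", "B"),
    variable = "wbc",
    time_h = c(5, 60, 65, 10), value = c(1, 2, 3, 4)
  )
  recs <- dplyr::bind_rows(rec1("A", 65), rec1("B", 100, status = 0L))
  bs <- backward_scatter(m, recs, "wbc")
  expect_equal(sort(bs$lag_h), c(0, 5, 60)) # at-event lag 0; B excluded
  bs2 <- backward_scatter(m, recs, "wbc", window_h = 50)
  expect_equal(sort(bs2$lag_h), c(0, 5)) # the 60h-lag point drops
})

test_that("forward scatter keeps all pre-outcome, pre-horizon rows", {
  m <- tibble::tibble(
    patient_id = c("A", "A", "B", "B"),
    variable = "wbc",
    time_h = c(5, 80, 10, 200), value = 1:4
  )
  recs <- dplyr::bind_rows(rec1("A", 65), rec1("B", 150, status = 0L))
  fs <- forward_scatter(m, recs)
  expect_equal(nrow(fs), sum(m$time_h <= c(65, 65, 150, 150) &
                               m$time_h <= 192))
  expect_false(80 %in% fs$time_h) # after A's outcome
  expect_false(200 %in% fs$time_h) # after the horizon
  fs2 <- forward_scatter(m[1, ])
  expect_equal(nrow(fs2), 1)
})
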