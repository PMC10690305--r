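# Erroneous-measurement flagging, agreement metrics, cadence summaries,
# availability.

test_that("the Z rule flags at |Z| >= 3 inclusively", {
  # 17 zeros plus -3 and +3: pooled mean is exactly 0 and the sample SD is
  # exactly 1, so the extremes sit exactly on the boundary
  m <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:19), variable = "wbc",
    time_h = 0, value = c(rep(0, 17), -3, 3)
  )
  f <- flag_outliers(m)
  expect_equal(f$z_score[18:19], c(-3, 3))
  expect_equal(f$flagged, c(rep(FALSE, 17), TRUE, TRUE))
})

test_that("the 25%-change rule compares to the preceding value inclusively", {
  filler <- tibble::tibble(
    patient_id = sprintf("F%02d", 1:4), variable = "wbc",
    time_h = 0, value = c(2, 6, 18, 22) # widen the cohort SD
  )
  seq_patient <- function(vals) {
    dplyr::bind_rows(
      tibble::tibble(patient_id = "A", variable = "wbc",
                     time_h = seq_along(vals), value = vals),
      filler
    )
  }
  f <- flag_outliers(seq_patient(c(10, 10, 14)))
  expect_equal(f$rel_change[1:3], c(NA, 0, 0.4))
  expect_equal(f$flagged[1:3], c(FALSE, FALSE, TRUE))
  f2 <- flag_outliers(seq_patient(c(10, 12)))
  expect_false(any(f2$flagged)) # 20% change: below the rule
  f3 <- flag_outliers(seq_patient(c(10, 12.5)))
  expect_true(f3$flagged[2]) # exactly 25%: inclusive
})

test_that("degenerate inputs behave: constant cohort, zero SD, zero
          preceding value", {
  m <- tibble::tibble(patient_id = c("A", "A", "B"), variable = "na",
                      time_h = c(0, 1, 0), value = 7)
  expect_warning(f <- flag_outliers(m), "zero or undefined")
  expect_false(any(f$flagged))
  m2 <- tibble::tibble(patient_id = "A", variable = "x",
                       time_h = c(0, 1, 2), value = c(5, 0, 4))
  f2 <- suppressWarnings(flag_outliers(m2))
  expect_true(is.na(f2$rel_change[3])) # preceding value 0: undefined
})

test_that("radiographic variables are exempt from the 25%-change rule", {
  specs <- list(
    mls = variable_spec("mls", grid_step_h = 12, lo = 0, hi = 30,
                        radiographic = TRUE),
    wbc = variable_spec("wbc", grid_step_h = 24, lo = 0.5, hi = 60)
  )
  m <- tibble::tibble(
    patient_id = "A",
    variable = rep(c("mls", "wbc"), each = 3),
    time_h = rep(c(0, 10, 20), 2),
    value = c(1, 2, 4, 10, 10.5, 14) # both series have > 25% jumps
  )
  f <- flag_outliers(m, specs)
  expect_false(any(f$flagged[f$variable == "mls"]))
  expect_true(any(f$flagged[f$variable == "wbc"]))
})

test_that("flagging is invariant to row order", {
  sim <- simulate_cohort(default_sim_config(n_patients = 20, seed = 13))
  m <- inject_artifacts(sim$cohort$measurements, 0.05, seed = 1)
  f1 <- flag_outliers(m)
  set.seed(2)
  perm <- sample(nrow(m))
  f2 <- flag_outliers(m[perm, ])
  expect_equal(f1$flagged[perm], f2$flagged)
  expect_equal(f1$z_score[perm], f2$z_score)
})

test_that("the drop policy removes exactly the flagged rows", {
  m <- tibble::tibble(
    patient_id = "A", variable = "wbc", time_h = 1:5,
    value = c(10, 10, 14, 14, 14)
  )
  f <- flag_outliers(m)
  expect_equal(sum(f$flagged), 1)
  kept <- apply_flag_policy(m, f, "drop_flagged")
  expect_equal(nrow(kept), 4)
  expect_equal(attr(kept, "removed_n"), 1)
  expect_equal(attr(kept, "removed_fraction"), 1 / 5)
  expect_false(any(kept$time_h == 3))
  # flag_only leaves values untouched
  ann <- apply_flag_policy(m, f, "flag_only")
  expect_equal(ann$value, m$value)
  expect_equal(sum(ann$flagged), 1)
  # no flags: identity
  f0 <- f
  f0$flagged <- FALSE
  expect_equal(nrow(apply_flag_policy(m, f0, "drop_flagged")), 5)
})

test_that("agreement metrics match hand arithmetic", {
  expect_equal(percent_agreement(c("A", "A", "B", "C"),
                                 c("A", "B", "B", "C")), 75)
  expect_equal(percent_agreement(letters[1:3], letters[1:3]), 100)
  expect_equal(mean_abs_error(c(1, 2), c(1.2, 1.6)), 0.3)
  expect_equal(mean_abs_error(c(1, 2), c(1, 2)), 0)
  expect_error(percent_agreement(1:3, 1:2), "equal length")
  expect_error(mean_abs_error(1:3, 1:2), "equal length")
})

test_that("gap summaries pool within-patient gaps and honour the
          pre-outcome restriction", {
  m <- tibble::tibble(
    patient_id = c("A", "A", "A", "B", "B"),
    variable = "glucose",
    time_h = c(0, 2, 10, 0, 4), value = 1
  )
  g <- summarize_gaps(m)
  expect_equal(g$n_gaps, 3) # gaps 2, 8, 4
  expect_equal(g$median_h, 4)
  single <- summarize_gaps(m[1, ])
  expect_equal(nrow(single), 0)
  m2 <- tibble::tibble(patient_id = "A", variable = "x",
                       time_h = c(0, 6, 12), value = 1)
  expect_equal(summarize_gaps(m2)$median_h, 6)
  # restriction: for a case with outcome at 9h the gap ending at 10h drops
  rec <- tibble::tibble(patient_id = c("A", "B"), X_h = c(9, 100),
                        status = c(1L, 0L), censor_reason = "none")
  gr <- summarize_gaps(m, rec)
  expect_equal(gr$n_gaps, 2) # gaps 2 (A) and 4 (B, censored keeps all)
})

test_that("availability matrix uses half-open bins", {
  m <- tibble::tibble(patient_id = "P1", variable = "wbc", time_h = 3,
                      value = 10)
  a <- availability_matrix(m, grid_step_h = 2, horizon_h = 8)
  expect_equal(as.vector(a), c(FALSE, TRUE, FALSE, FALSE))
  empty <- availability_matrix(m[0, ], grid_step_h = 2, horizon_h = 8,
                               patient_ids = "P1")
  expect_false(any(empty))
  m2 <- tibble::tibble(patient_id = "P1", variable = "wbc",
                       time_h = c(0, 23.9), value = 1)
  a2 <- availability_matrix(m2, grid_step_h = 24, horizon_h = 24)
  expect_equal(dim(a2), c(1L, 1L))
  expect_true(a2[1, 1])
})
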