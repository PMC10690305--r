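# Independent brute-force oracles and small fixture builders.  These
# deliberately re-derive quantities from first principles (explicit
# risk-set products, sort-based quantiles, nested loops) so they share no
# code path with the package implementation.

# Product-limit estimator of cause-specific cumulative incidence by direct
# multiplication of risk-set fractions, processing tied times together.
oracle_aj <- function(time, status) {
  ut <- sort(unique(time))
  S <- 1
  cif1 <- cif2 <- 0
  out <- data.frame(time = ut, cif1 = NA_real_, cif2 = NA_real_,
                    surv = NA_real_)
  for (k in seq_along(ut)) {
    t <- ut[k]
    n_at <- sum(time >= t)
    d1 <- sum(time == t & status == 1)
    d2 <- sum(time == t & status == 2)
    cif1 <- cif1 + S * d1 / n_at
    cif2 <- cif2 + S * d2 / n_at
    S <- S * (1 - (d1 + d2) / n_at)
    out$cif1[k] <- cif1
    out$cif2[k] <- cif2
    out$surv[k] <- S
  }
  out
}

# Kaplan-Meier survival by explicit product over event times.
oracle_km <- function(time, is_event) {
  ut <- sort(unique(time))
  S <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (k in seq_along(ut)) {
    t <- ut[k]
    n_at <- sum(time >= t)
    d <- sum(time == t & is_event)
    S <- S * (1 - d / n_at)
    out$surv[k] <- S
  }
  out
}

# Smallest value whose empirical CDF reaches q (sort-based; matches the
# left-continuous inverse-CDF definition for equal weights).
oracle_quantile <- function(x, q) {
  x <- sort(x)
  x[ceiling(q * length(x) - 1e-9)]
}

# Unweighted case-only backward statistics by nested loops over cases and
# lags, looking values up directly in per-patient slices of the hourly
# table.
oracle_backward <- function(hourly, records, variable, s_max = 72) {
  cases <- records[records$status == 1, , drop = FALSE]
  hv <- hourly[hourly$variable == variable, , drop = FALSE]
  by_pat <- split(hv[, c("hour", "value")], hv$patient_id)
  res <- data.frame(lag_h = 0:s_max, n = 0L, mean = NA_real_,
                    q25 = NA_real_, q50 = NA_real_, q75 = NA_real_)
  for (s in 0:s_max) {
    vals <- c()
    for (i in seq_len(nrow(cases))) {
      df <- by_pat[[cases$patient_id[i]]]
      if (is.null(df)) next
      h <- floor(cases$X_h[i]) - s
      row <- which(df$hour == h)
      if (length(row) == 1 && !is.na(df$value[row])) {
        vals <- c(vals, df$value[row])
      }
    }
    res$n[s + 1] <- length(vals)
    if (length(vals)) {
      res$mean[s + 1] <- mean(vals)
      res$q25[s + 1] <- oracle_quantile(vals, 0.25)
      res$q50[s + 1] <- oracle_quantile(vals, 0.5)
      res$q75[s + 1] <- oracle_quantile(vals, 0.75)
    }
  }
  res
}

# Six-patient toy cohort exercising every adjudication branch:
#   P1 crossing before anything else        -> event at 40
#   P2 crossing after surgery               -> censored at 30 (precedence)
#   P3 death before any crossing            -> death at 20
#   P4 no crossing, discharged at 100       -> censored at 100 (discharge)
#   P5 no crossing, discharged after 192    -> censored at 192 (horizon)
#   P6 crossing after the 192 h horizon     -> censored at 192 (horizon)
toy_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = paste0("P", 1:6),
    death_h = c(NA, NA, 20, NA, NA, NA),
    discharge_h = c(120, 150, NA, 100, 250, 250)
  )
  measurements <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3", "P4", "P4", "P5", "P6", "P6"),
    variable = "mls",
    time_h = c(10, 40, 40, 10, 10, 50, 10, 100, 200),
    value = c(2, 6, 6, 2, 2, 3, 2, 3, 6)
  )
  procedures <- tibble::tibble(patient_id = "P2", procedure = "dhc",
                               time_h = 30)
  cohort(patients, measurements, procedures)
}

# Event records built from simulated latent truth (the generator's
# observed state for the latent crossing).
records_from_truth <- function(truth) {
  tibble::tibble(patient_id = truth$patient_id, outcome = "latent",
                 X_h = truth$X_h, status = truth$status,
                 censor_reason = truth$censor_reason)
}

# One signature-recovery replicate: simulate, regularize, weight, align,
# estimate; returns the fitted backward mean trajectory.
recovery_estimate <- function(seed, censoring, net_change,
                              n_patients = 600) {
  cfg <- marker_recovery_config(n_patients, censoring,
                                net_change = net_change, seed = seed)
  sim <- simulate_cohort(cfg)
  rec <- records_from_truth(sim$truth)
  h <- hourly_series(sim$cohort$measurements, cfg$variable_specs, rec)
  w <- ipcw_weights(rec, censoring_km(rec))
  backward_estimate(align_backward(h, rec, "marker"), w)
}
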