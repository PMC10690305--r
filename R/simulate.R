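# Synthetic cohort generator: joint longitudinal-survival simulation.

# Irregular measurement times on (0, end]: first time ~ U(0, min(median gap,
# end)), then i.i.d. log-normal gaps.  Returns numeric(0) when end <= 0.
draw_irregular_times <- function(end, gap, first_max = gap$median) {
  if (!is.finite(end) || end <= 0) return(numeric(0))
  t0 <- runif(1, 0, min(first_max, end))
  times <- t0
  block <- max(8L, ceiling((end - t0) / gap$median * 1.5))
  while (times[length(times)] <= end) {
    g <- rlnorm(block, gap$meanlog, gap$sdlog)
    times <- c(times, times[length(times)] + cumsum(g))
  }
  times[times <= end]
}

# Latent marker value: baseline + linear ramp accumulating `net` over the
# `onset` hours before t_star, plateauing at baseline + net afterwards.
latent_marker <- function(t, baseline, t_star, onset, net) {
  if (net == 0 || !is.finite(t_star)) return(rep(baseline, length(t)))
  frac <- pmin(pmax((t - (t_star - onset)) / onset, 0), 1)
  baseline + net * frac
}

# Internal: draw latent event/death/discharge times and the observed
# (X, status) state for n patients.  Assumes the RNG is already seeded.
draw_event_times <- function(config) {
  n <- config$n_patients
  t_star <- draw_times(config$event_time_dist, n)
  death <- draw_times(config$death_time_dist, n)
  discharge <- draw_times(config$discharge_time_dist, n)
  h <- config$horizon_h
  # observed state = argmin of (T*, D, C, horizon); ties: event > death >
  # censoring.
  tm <- rbind(t_star, death, discharge, rep(h, n))
  j <- apply(tm, 2, which.min)
  x <- tm[cbind(j, seq_len(n))]
  status <- c(1L, 2L, 0L, 0L)[j]
  reason <- c("none", "none", "discharge", "horizon")[j]
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    T_star_h = t_star, death_h = death, discharge_h = discharge,
    X_h = x, status = status, censor_reason = reason
  )
}

#' Draw latent event, death and discharge times
#'
#' Draws independent latent times for the severity-threshold crossing
#' (`T_star_h`), death and discharge for every patient, and reports the
#' observed state: `X_h` is the minimum of the three times and the horizon,
#' `status` is 1 when the crossing comes first, 2 for death, 0 for
#' censoring (with `censor_reason` `"discharge"` or `"horizon"`).  Ties are
#' resolved event > death > censoring.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per patient: `patient_id`, `T_star_h`,
#'   `death_h`, `discharge_h`, `X_h`, `status`, `censor_reason`.  The
#'   `(X_h, status)` columns form a valid event-record table for the
#'   latent crossing outcome.
#' @examples
#' cfg <- marker_recovery_config(n_patients = 20, seed = 1)
#' simulate_event_times(cfg)
#' @export
simulate_event_times <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  draw_event_times(config)
}

#' Simulate a synthetic stroke cohort with known ground truth
#'
#' Generates a full cohort with the joint longitudinal-survival structure
#' the backward-looking analysis assumes.  Each patient receives latent
#' crossing/death/discharge times; irregularly sampled laboratory and vital
#' sign measurements over `[0, min(death, discharge, horizon)]` whose
#' latent mean follows the patient baseline plus the configured pre-event
#' signature ramp anchored at the latent crossing time; radiographic scan
#' series (midline shift and pineal gland shift) as monotone latent
#' processes plus reading noise, with a scan triggered at each latent
#' threshold crossing (imaging prompted by deterioration); and surgical
#' decompression for a configured fraction of patients with an observed
#' crossing, at an exponential delay after it.
#'
#' Identical `(config, seed)` yields an identical cohort.
#'
#' @param config A [sim_config()].
#' @return A list of class `backtraj_sim` with elements
#'   \describe{
#'     \item{cohort}{a [cohort()] object (patients, measurements,
#'       procedures);}
#'     \item{truth}{a tibble of generator ground truth per patient: latent
#'       times, observed latent state, and realized per-variable baselines.}
#'   }
#' @examples
#' sim <- simulate_cohort(default_sim_config(n_patients = 30, seed = 2))
#' sim$cohort
#' head(sim$truth)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  et <- draw_event_times(config)
  end_follow <- pmin(et$death_h, et$discharge_h, config$horizon_h)

  vnames <- names(config$variable_specs)
  radio <- vnames[vapply(config$variable_specs, `[[`, TRUE, "radiographic")]
  markers <- setdiff(vnames, radio)

  # patient-level baselines for every marker with a signature
  baselines <- lapply(markers, function(v) {
    sg <- config$signatures[[v]]
    if (is.null(sg)) return(rep(NA_real_, n))
    rnorm(n, sg$baseline_mean, sg$baseline_sd)
  })
  names(baselines) <- markers

  has_vitals <- rep(TRUE, n)
  if (length(config$vitals_variables)) {
    has_vitals <- runif(n) < config$vitals_fraction
  }

  age <- as.numeric(round(pmin(pmax(rnorm(n, 69, 15), 18), 100)))
  female <- as.numeric(runif(n) < 0.49)

  pid <- et$patient_id
  meas <- vector("list", length(markers) + 2L)
  k <- 0L
  for (v in markers) {
    sg <- config$signatures[[v]]
    gap <- config$sampling_gaps[[v]]
    spec <- config$variable_specs[[v]]
    src <- if (v %in% config$vitals_variables) "vital" else "lab"
    who <- if (v %in% config$vitals_variables) which(has_vitals) else
      seq_len(n)
    rows <- lapply(who, function(i) {
      tt <- draw_irregular_times(end_follow[i], gap)
      if (!length(tt)) return(NULL)
      mu <- if (is.null(sg)) 0 else
        latent_marker(tt, baselines[[v]][i], et$T_star_h[i],
                      sg$onset_lag_h, sg$net_change)
      val <- mu + if (is.null(sg) || sg$noise_sd == 0) 0 else
        rnorm(length(tt), 0, sg$noise_sd)
      val <- pmin(pmax(val, spec$lo), spec$hi)
      list(pid = rep(pid[i], length(tt)), t = tt, v = val)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) {
      k <- k + 1L
      meas[[k]] <- tibble::tibble(
        patient_id = unlist(lapply(rows, `[[`, "pid")),
        variable = v,
        time_h = unlist(lapply(rows, `[[`, "t")),
        value = unlist(lapply(rows, `[[`, "v")),
        source = src
      )
    }
  }

  mls0 <- NULL
  if (length(radio)) {
    mls0 <- runif(n, config$mls_baseline_range[1],
                  config$mls_baseline_range[2])
    slope <- (5 - mls0) / et$T_star_h # latent MLS crosses 5 mm at T*
    pgs_cross <- et$T_star_h * (4 / config$pgs_ratio - mls0) / (5 - mls0)
    scans <- lapply(seq_len(n), function(i) {
      tt <- draw_irregular_times(end_follow[i], config$imaging_gap,
                                 first_max = 2)
      trig <- c(et$T_star_h[i], pgs_cross[i])
      tt <- sort(unique(c(tt, trig[trig <= end_follow[i]])))
      if (!length(tt)) return(NULL)
      lat <- mls0[i] + slope[i] * tt
      list(pid = rep(pid[i], length(tt)), t = tt, lat = lat)
    })
    scans <- scans[!vapply(scans, is.null, TRUE)]
    sc_pid <- unlist(lapply(scans, `[[`, "pid"))
    sc_t <- unlist(lapply(scans, `[[`, "t"))
    sc_lat <- unlist(lapply(scans, `[[`, "lat"))
    if ("mls" %in% radio) {
      k <- k + 1L
      meas[[k]] <- tibble::tibble(
        patient_id = sc_pid, variable = "mls", time_h = sc_t,
        value = pmax(sc_lat + rnorm(length(sc_lat), 0,
                                    config$scan_noise_sd), 0),
        source = "imaging"
      )
    }
    if ("pgs" %in% radio) {
      k <- k + 1L
      meas[[k]] <- tibble::tibble(
        patient_id = sc_pid, variable = "pgs", time_h = sc_t,
        value = pmax(config$pgs_ratio * sc_lat +
                       rnorm(length(sc_lat), 0, config$scan_noise_sd), 0),
        source = "imaging"
      )
    }
  }

  measurements <- dplyr::bind_rows(meas[seq_len(k)])
  measurements <- measurements[order(measurements$patient_id,
                                     measurements$variable,
                                     measurements$time_h), , drop = FALSE]

  # surgical decompression: a fraction of patients with an observed
  # crossing, at an exponential delay, while still in hospital and alive
  procedures <- tibble::tibble(patient_id = character(),
                               procedure = character(),
                               time_h = numeric())
  if (config$dhc_fraction > 0) {
    eligible <- which(et$T_star_h <= end_follow)
    pick <- eligible[runif(length(eligible)) < config$dhc_fraction]
    if (length(pick)) {
      dhc_t <- et$T_star_h[pick] + rexp(length(pick),
                                        1 / config$dhc_delay_mean_h)
      keep <- dhc_t < pmin(et$death_h[pick], et$discharge_h[pick])
      procedures <- tibble::tibble(
        patient_id = pid[pick[keep]],
        procedure = "dhc",
        time_h = dhc_t[keep]
      )
    }
  }

  if (config$artifact_rate > 0) {
    measurements <- inject_artifacts(measurements, config$artifact_rate)
  }

  patients <- tibble::tibble(
    patient_id = pid,
    age = age, female = female,
    death_h = ifelse(et$death_h < et$discharge_h, et$death_h, NA_real_),
    discharge_h = ifelse(et$discharge_h <= et$death_h, et$discharge_h,
                         NA_real_),
    vitals_monitored = as.numeric(has_vitals)
  )

  truth <- et
  for (v in markers) {
    if (!is.null(config$signatures[[v]])) {
      truth[[paste0("baseline_", v)]] <- baselines[[v]]
    }
  }
  if (!is.null(mls0)) truth$mls_baseline_mm <- mls0
  attr(truth, "config") <- config

  structure(
    list(cohort = cohort(patients, measurements, procedures), truth = truth),
    class = "backtraj_sim"
  )
}

#' @export
print.backtraj_sim <- function(x, ...) {
  cat("<backtraj_sim>\n")
  print(x$cohort)
  cat("truth:", nrow(x$truth), "patients,",
      sum(x$truth$status == 1), "latent crossings observed\n")
  invisible(x)
}

#' Inject erroneous spike artifacts into a measurement table
#'
#' Replaces a random subset of measurement values with implausible spikes
#' that are guaranteed to trip the erroneous-measurement flagging rules:
#' a row with a preceding same-variable value within the patient is set to
#' 1.5x the (current) preceding value (a 50% jump, beyond the 25%-change
#' rule); a row with no usable preceding value is set to the variable's
#' cohort mean plus six cohort standard deviations (beyond the |Z| >= 3
#' rule even after the injection itself inflates the cohort SD).  Rows are
#' processed in patient/time order so consecutive injections still jump.
#'
#' @param measurements Measurement tibble (`patient_id`, `variable`,
#'   `time_h`, `value`, ...).
#' @param rate Per-measurement injection probability in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The measurement tibble in the original row order with values
#'   replaced for injected rows and a logical `injected` truth column.
#' @examples
#' m <- tibble::tibble(patient_id = "P1", variable = "wbc",
#'                     time_h = 0:9, value = rep(10, 10))
#' inject_artifacts(m, rate = 1, seed = 1)$value
#' @export
inject_artifacts <- function(measurements, rate, seed = NULL) {
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- measurements
  m$injected <- FALSE
  if (rate == 0 || nrow(m) == 0) return(m)
  stats <- tapply(m$value, m$variable, function(v) {
    c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  })
  ord <- order(m$patient_id, m$variable, m$time_h)
  sel <- runif(nrow(m)) < rate
  grp <- paste(m$patient_id[ord], m$variable[ord], sep = "\r")
  val <- m$value
  inj <- logical(nrow(m))
  prev_grp <- ""
  prev_val <- NA_real_
  for (idx in seq_along(ord)) {
    i <- ord[idx]
    g <- grp[idx]
    if (g != prev_grp) prev_val <- NA_real_
    if (sel[i]) {
      st <- stats[[m$variable[i]]]
      if (!is.na(prev_val) && prev_val != 0) {
        val[i] <- 1.5 * prev_val
      } else {
        s <- if (is.na(st["sd"]) || st["sd"] == 0) abs(st["mean"]) + 1 else
          st["sd"]
        val[i] <- st["mean"] + 6 * s
      }
      inj[i] <- TRUE
    }
    prev_val <- val[i]
    prev_grp <- g
  }
  m$value <- val
  m$injected <- inj
  m
}
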