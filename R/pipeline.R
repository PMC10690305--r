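# End-to-end pipeline driver: simulate/read -> clean -> adjudicate ->
# regularize -> incidence -> backward -> figures, with a JSON-lines run log.

#' Pipeline configuration
#'
#' @param simulate A [sim_config()] used to generate the cohort, or `NULL`
#'   when reading from `input_dir`.
#' @param input_dir Directory with cohort CSVs (see [read_cohort()]);
#'   ignored when `simulate` is given.
#' @param variable_specs Named list of [variable_spec()]s; defaults to the
#'   simulation config's specs.
#' @param outcomes Outcomes to analyse, subset of
#'   `c("mls5", "pgs4", "dhc")`.
#' @param variables Marker variables for backward trajectories; default:
#'   all non-radiographic variables, plus midline shift as an exposure for
#'   the pineal-gland-shift outcome.
#' @param horizon_h Follow-up horizon (default 192 h).
#' @param window_h Backward look-back window (default 72 h).
#' @param flag_policy `"flag_only"` (default) or `"drop_flagged"`.
#' @param min_n Minimum contributing cases per lag (default 5).
#' @param death_in_G Censoring convention for the weight denominator, see
#'   [censoring_km()].
#' @param cif_times Hours at which cumulative incidences are tabulated.
#' @param figures Logical: also render figures (default `TRUE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = default_sim_config(),
                            input_dir = NULL,
                            variable_specs = NULL,
                            outcomes = c("mls5", "pgs4", "dhc"),
                            variables = NULL,
                            horizon_h = 192,
                            window_h = 72,
                            flag_policy = "flag_only",
                            min_n = 5,
                            death_in_G = "censoring",
                            cif_times = c(24, 48, 72),
                            figures = TRUE) {
  if (!is.null(input_dir) && missing(simulate)) simulate <- NULL
  if (is.null(simulate) && is.null(input_dir)) {
    stop("pipeline_config: need either `simulate` or `input_dir`",
         call. = FALSE)
  }
  if (!all(outcomes %in% c("mls5", "pgs4", "dhc"))) {
    stop("pipeline_config: `outcomes` must be a subset of mls5, pgs4, dhc",
         call. = FALSE)
  }
  if (is.null(variable_specs)) {
    if (is.null(simulate)) {
      stop("pipeline_config: `variable_specs` is required with `input_dir`",
           call. = FALSE)
    }
    variable_specs <- simulate$variable_specs
  }
  if (!is.null(variables)) {
    bad <- setdiff(variables, names(variable_specs))
    if (length(bad)) {
      stop("pipeline_config: no variable_spec for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(simulate = simulate, input_dir = input_dir,
         variable_specs = variable_specs, outcomes = outcomes,
         variables = variables, horizon_h = horizon_h,
         window_h = window_h, flag_policy = flag_policy, min_n = min_n,
         death_in_G = death_in_G, cif_times = cif_times,
         figures = figures),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Supports the scalar settings of [pipeline_config()] plus a `simulate`
#' block with `n_patients` and `seed` (expanded through
#' [default_sim_config()]) or an `input_dir`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim <- default_sim_config(
      n_patients = y$simulate$n_patients %||% 635,
      seed = y$simulate$seed %||% 1L
    )
  }
  args <- y[setdiff(names(y), c("simulate", "input_dir"))]
  args$simulate <- sim
  args$input_dir <- y$input_dir
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full trajectory pipeline
#'
#' Executes, in order: cohort simulation (or CSV input), erroneous-value
#' flagging, outcome adjudication, cadence summaries, per-outcome
#' regularization to hourly series, Aalen-Johansen cumulative incidence,
#' backward-looking trajectory estimation for every (outcome, variable)
#' pair, and figure rendering.  All tables are written as CSV under
#' `outdir` and a JSON-lines run log (`run_log.jsonl`) records versions,
#' the seed, the settings in force and row counts at every stage.
#' Identical configuration and seed reproduce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the cohort, event records, CIF and
#'   backward estimates, and the paths written.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.jsonl")
  unlink(log_path)
  log_line <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  log_line("start", r_version = R.version.string,
           package = as.character(packageVersion("backtraj")),
           horizon_h = config$horizon_h, window_h = config$window_h,
           flag_policy = config$flag_policy, min_n = config$min_n,
           death_in_G = config$death_in_G,
           seed = if (!is.null(config$simulate)) config$simulate$seed else
             NA)

  # -- cohort ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate)
    ch <- sim$cohort
    truth <- sim$truth
    write_cohort(ch, outdir)
    readr::write_csv(truth, file.path(outdir, "truth.csv"),
                     progress = FALSE)
  } else {
    ch <- read_cohort(config$input_dir)
  }
  log_line("cohort", patients = nrow(ch$patients),
           measurements = nrow(ch$measurements),
           procedures = nrow(ch$procedures))

  # -- cleaning -------------------------------------------------------------
  flags <- flag_outliers(ch$measurements, config$variable_specs)
  readr::write_csv(flags, file.path(outdir, "flags.csv"), progress = FALSE)
  meas <- apply_flag_policy(ch$measurements, flags, config$flag_policy)
  log_line("clean", policy = config$flag_policy,
           flagged = sum(flags$flagged), kept = nrow(meas))

  # -- adjudication ---------------------------------------------------------
  records <- lapply(config$outcomes, function(oc) {
    adjudicate_outcomes(ch, oc, horizon_h = config$horizon_h)
  })
  names(records) <- config$outcomes
  events <- dplyr::bind_rows(records)
  readr::write_csv(events, file.path(outdir, "events.csv"),
                   progress = FALSE)
  for (oc in config$outcomes) {
    log_line("adjudicate", outcome = oc,
             events = sum(records[[oc]]$status == 1),
             deaths = sum(records[[oc]]$status == 2),
             censored = sum(records[[oc]]$status == 0))
  }

  # -- cadence summaries ----------------------------------------------------
  gaps <- dplyr::bind_rows(
    dplyr::mutate(summarize_gaps(meas), restriction = "none"),
    if (config$outcomes[1] %in% names(records)) {
      dplyr::mutate(summarize_gaps(meas, records[[config$outcomes[1]]]),
                    restriction = paste0("pre_", config$outcomes[1]))
    }
  )
  readr::write_csv(gaps, file.path(outdir, "gaps.csv"), progress = FALSE)

  # -- hourly series (follow-up truncation only; backward estimation below
  # re-truncates per outcome) ----------------------------------------------
  hourly_all <- hourly_series(meas, config$variable_specs)
  readr::write_csv(hourly_all, file.path(outdir, "hourly.csv"),
                   progress = FALSE)
  log_line("regularize", hourly_rows = nrow(hourly_all))

  # -- incidence + backward -------------------------------------------------
  nonradio <- names(config$variable_specs)[
    !vapply(config$variable_specs, `[[`, TRUE, "radiographic")]
  base_vars <- config$variables %||%
    intersect(nonradio, unique(meas$variable))
  cif_rows <- list()
  cif_tab_rows <- list()
  back_rows <- list()
  estimates <- list()
  cifs <- list()
  for (oc in config$outcomes) {
    rec <- records[[oc]]
    aj <- aalen_johansen(rec)
    cifs[[oc]] <- aj
    cif_rows[[oc]] <- dplyr::mutate(aj$steps, outcome = oc,
                                    .before = 1)
    cif_tab_rows[[oc]] <- dplyr::mutate(
      cif_at(aj, config$cif_times), outcome = oc, .before = 1)
    vars <- base_vars
    if (oc == "pgs4" && "mls" %in% unique(meas$variable) &&
        is.null(config$variables)) {
      vars <- c(vars, "mls") # midline shift as exposure for this outcome
    }
    hourly_oc <- hourly_series(meas[meas$variable %in% vars, , drop = FALSE],
                               config$variable_specs, records = rec)
    G <- censoring_km(rec, death = config$death_in_G)
    w <- ipcw_weights(rec, G)
    for (v in vars) {
      al <- align_backward(hourly_oc, rec, v, s_max = config$window_h)
      est <- backward_estimate(al, w, min_n = config$min_n)
      estimates[[paste(oc, v, sep = ".")]] <- est
      back_rows[[paste(oc, v, sep = ".")]] <-
        dplyr::mutate(tibble::as_tibble(est), outcome = oc, variable = v,
                      .before = 1)
    }
    log_line("backward", outcome = oc, cases = sum(rec$status == 1),
             variables = length(vars))
  }
  readr::write_csv(dplyr::bind_rows(cif_rows),
                   file.path(outdir, "cif.csv"), progress = FALSE)
  readr::write_csv(dplyr::bind_rows(cif_tab_rows),
                   file.path(outdir, "cif_at.csv"), progress = FALSE)
  backward <- dplyr::bind_rows(back_rows)
  readr::write_csv(backward, file.path(outdir, "backward.csv"),
                   progress = FALSE)

  # -- figures --------------------------------------------------------------
  fig_paths <- character()
  if (isTRUE(config$figures)) {
    figdir <- file.path(outdir, "figures")
    if (!dir.exists(figdir)) dir.create(figdir)
    save_fig <- function(p, name) {
      path <- file.path(figdir, paste0(name, ".png"))
      grDevices::png(path, width = 1600, height = 1200, res = 150)
      print(p)
      grDevices::dev.off()
      fig_paths <<- c(fig_paths, path)
    }
    for (oc in config$outcomes) {
      keys <- grep(paste0("^", oc, "\\."), names(estimates), value = TRUE)
      ests <- estimates[keys]
      names(ests) <- sub("^[^.]*\\.", "", keys)
      save_fig(plot_backward_bands(
        ests, title = paste("backward trajectories before", oc)),
        paste0("backward_", oc))
    }
    fs <- forward_scatter(meas, records[[config$outcomes[1]]],
                          config$horizon_h)
    save_fig(plot_forward_scatter(fs, "forward-looking scatter"),
             "forward_scatter")
    bs <- backward_scatter(meas, records[[config$outcomes[1]]],
                           window_h = config$window_h)
    save_fig(plot_backward_scatter(
      bs, paste("measurements before", config$outcomes[1])),
      "backward_scatter")
    first_var <- base_vars[1]
    av <- availability_matrix(
      meas[meas$variable == first_var, , drop = FALSE],
      grid_step_h = config$variable_specs[[first_var]]$grid_step_h,
      horizon_h = config$horizon_h,
      patient_ids = ch$patients$patient_id)
    save_fig(plot_availability(av, paste("availability:", first_var)),
             "availability")
    case_ids <- events$patient_id[events$status == 1]
    if (length(case_ids)) {
      save_fig(plot_individual(ch, case_ids[1], records = events),
               "individual")
    }
    log_line("figures", n = length(fig_paths))
  }
  log_line("done")
  invisible(list(cohort = ch, truth = truth, records = records,
                 cifs = cifs, estimates = estimates, backward = backward,
                 outdir = outdir, figures = fig_paths))
}
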