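# Erroneous-measurement flagging, rater agreement, cadence summaries.

#' Flag potentially erroneous measurements
#'
#' Applies the two chart-entry error screens used when curating
#' electronic-health-record series: a measurement is flagged when its
#' absolute Z-score is at least 3 (inclusive), standardized against the
#' pooled distribution of that variable across the full cohort, or when it
#' changes by at least 25% (inclusive, in absolute value) from the
#' immediately preceding same-variable measurement within the patient.
#' The 25%-change rule is not applied to radiographic variables (per their
#' [variable_spec()]), whose between-scan changes are legitimately large.
#' A variable with zero pooled SD skips the Z rule with a warning; the
#' first measurement of a patient-variable series, or one whose preceding
#' value is 0, has an undefined relative change and cannot be flagged by
#' that rule.
#'
#' @param measurements Measurement tibble.
#' @param variable_specs Optional named list of [variable_spec()]s, used to
#'   identify radiographic variables.  Without specs all variables are
#'   treated as non-radiographic.
#' @return A flag table aligned to the input rows: `row` (input row
#'   number), `patient_id`, `variable`, `time_h`, `value`, `z_score`,
#'   `rel_change`, `flagged`, `removed` (always `FALSE`; see
#'   [apply_flag_policy()]).
#' @examples
#' m <- tibble::tibble(patient_id = "P1", variable = "wbc",
#'                     time_h = c(0, 10, 20), value = c(10, 10, 14))
#' flag_outliers(m)[, c("value", "rel_change", "flagged")]
#' @export
flag_outliers <- function(measurements, variable_specs = NULL) {
  m <- measurements
  n <- nrow(m)
  out <- tibble::tibble(
    row = seq_len(n),
    patient_id = m$patient_id, variable = m$variable,
    time_h = m$time_h, value = m$value,
    z_score = NA_real_, rel_change = NA_real_,
    flagged = FALSE, removed = FALSE
  )
  if (n == 0) return(out)

  for (v in unique(m$variable)) {
    idx <- which(m$variable == v)
    mu <- mean(m$value[idx], na.rm = TRUE)
    s <- sd(m$value[idx], na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("flag_outliers: zero or undefined cohort SD for '", v,
              "'; Z rule skipped", call. = FALSE)
    } else {
      out$z_score[idx] <- (m$value[idx] - mu) / s
    }
  }

  radio <- character()
  if (!is.null(variable_specs)) {
    radio <- names(variable_specs)[
      vapply(variable_specs, `[[`, TRUE, "radiographic")]
  }
  ord <- order(m$patient_id, m$variable, m$time_h)
  grp <- paste(m$patient_id[ord], m$variable[ord], sep = "\r")
  val <- m$value[ord]
  prev <- c(NA_real_, val[-length(val)])
  prev[c(TRUE, grp[-1] != grp[-length(grp)])] <- NA_real_
  rel <- ifelse(is.na(prev) | prev == 0, NA_real_,
                abs(val - prev) / abs(prev))
  out$rel_change[ord] <- rel
  rel_applies <- !(out$variable %in% radio)

  out$flagged <- (!is.na(out$z_score) & abs(out$z_score) >= 3) |
    (rel_applies & !is.na(out$rel_change) & out$rel_change >= 0.25)
  out
}

#' Apply a policy to flagged measurements
#'
#' `"flag_only"` (the default throughout the package) annotates the
#' measurements and changes no value: flagged points warrant contextual
#' review, not automatic deletion.  `"drop_flagged"` removes exactly the
#' flagged rows and reports how many were removed.
#'
#' @param measurements Measurement tibble.
#' @param flags Flag table from [flag_outliers()] computed on the same
#'   measurements (row-aligned).
#' @param policy `"flag_only"` or `"drop_flagged"`.
#' @return The measurement tibble with a `flagged` column; under
#'   `"drop_flagged"` the flagged rows are removed and the result carries
#'   attributes `removed_n` and `removed_fraction`.
#' @examples
#' m <- tibble::tibble(patient_id = "P1", variable = "wbc",
#'                     time_h = c(0, 10, 20), value = c(10, 10, 14))
#' f <- flag_outliers(m)
#' nrow(apply_flag_policy(m, f, "drop_flagged"))
#' @export
apply_flag_policy <- function(measurements, flags,
                              policy = c("flag_only", "drop_flagged")) {
  policy <- match.arg(policy)
  if (nrow(flags) != nrow(measurements)) {
    stop("apply_flag_policy: `flags` is not aligned to `measurements`",
         call. = FALSE)
  }
  m <- measurements
  m$flagged <- flags$flagged
  if (policy == "flag_only") return(m)
  keep <- !flags$flagged
  out <- m[keep, , drop = FALSE]
  attr(out, "removed_n") <- sum(!keep)
  attr(out, "removed_fraction") <- mean(!keep)
  out
}

#' Inter-rater agreement metrics
#'
#' `percent_agreement()` is the percentage of exact categorical matches
#' between two raters; `mean_abs_error()` is the mean absolute difference
#' between paired continuous readings.
#'
#' @param ratings_a,ratings_b Equal-length categorical vectors.
#' @param values_a,values_b Equal-length numeric vectors.
#' @return A single number: percentage in `[0, 100]`, or mean absolute
#'   error in the readings' units.
#' @examples
#' percent_agreement(c("A", "A", "B", "C"), c("A", "B", "B", "C")) # 75
#' mean_abs_error(c(1, 2), c(1.2, 1.6)) # 0.3
#' @export
percent_agreement <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("percent_agreement: inputs must have equal length", call. = FALSE)
  }
  100 * mean(ratings_a == ratings_b)
}

#' @rdname percent_agreement
#' @export
mean_abs_error <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("mean_abs_error: inputs must have equal length", call. = FALSE)
  }
  mean(abs(values_a - values_b))
}

#' Summarize inter-measurement gaps per variable
#'
#' Pools the gaps between consecutive same-variable measurements within
#' each patient and reports the median and quartiles per variable, the
#' summaries sampling cadences are reported with.  With `records`, only
#' gaps ending strictly before the patient's observed event time contribute
#' for patients whose outcome occurred (censored patients contribute all
#' their gaps, which already end at censoring).
#'
#' @param measurements Measurement tibble.
#' @param records Optional event-record tibble (one outcome) from
#'   [adjudicate_outcomes()] or [simulate_event_times()].
#' @return A tibble with one row per variable: `variable`, `n_gaps`,
#'   `median_h`, `q25_h`, `q75_h`.
#' @examples
#' m <- tibble::tibble(patient_id = "P1", variable = "glucose",
#'                     time_h = c(0, 6, 12), value = 1:3)
#' summarize_gaps(m)
#' @export
summarize_gaps <- function(measurements, records = NULL) {
  m <- measurements[order(measurements$patient_id, measurements$variable,
                          measurements$time_h), , drop = FALSE]
  grp <- paste(m$patient_id, m$variable, sep = "\r")
  same <- c(FALSE, grp[-1] == grp[-length(grp)])
  gap <- c(NA_real_, diff(m$time_h))
  keep <- same
  if (!is.null(records)) {
    x_of <- ifelse(records$status == 1, records$X_h, Inf)
    x_of <- x_of[match(m$patient_id, records$patient_id)]
    x_of[is.na(x_of)] <- Inf
    keep <- keep & m$time_h < x_of
  }
  g <- tibble::tibble(variable = m$variable[keep], gap = gap[keep])
  dplyr::summarise(
    dplyr::group_by(g, .data$variable),
    n_gaps = dplyr::n(),
    median_h = median(.data$gap),
    q25_h = as.numeric(quantile(.data$gap, 0.25)),
    q75_h = as.numeric(quantile(.data$gap, 0.75)),
    .groups = "drop"
  )
}

#' Patient-by-time-bin availability matrix
#'
#' Indicates, for one variable's measurements, which half-open time bins
#' `[k*step, (k+1)*step)` contain at least one measurement for each
#' patient; the machine-readable form of an availability heatmap.
#'
#' @param measurements Measurement tibble (typically pre-filtered to one
#'   variable).
#' @param grid_step_h Bin width in hours.
#' @param horizon_h Last hour covered (default 192); bins partition
#'   `[0, horizon_h)`.
#' @param patient_ids Optional row universe (default: patients present in
#'   `measurements`, sorted).
#' @return A logical matrix, rows named by patient, columns by bin start
#'   hour.
#' @examples
#' m <- tibble::tibble(patient_id = "P1", variable = "wbc",
#'                     time_h = 3, value = 10)
#' availability_matrix(m, grid_step_h = 2, horizon_h = 8)
#' @export
availability_matrix <- function(measurements, grid_step_h,
                                horizon_h = 192, patient_ids = NULL) {
  if (is.null(patient_ids)) {
    patient_ids <- sort(unique(measurements$patient_id))
  }
  starts <- seq(0, horizon_h - grid_step_h, by = grid_step_h)
  mat <- matrix(FALSE, nrow = length(patient_ids), ncol = length(starts),
                dimnames = list(patient_ids, starts))
  m <- measurements[measurements$time_h >= 0 &
                      measurements$time_h < horizon_h, , drop = FALSE]
  if (nrow(m)) {
    i <- match(m$patient_id, patient_ids)
    j <- floor(m$time_h / grid_step_h) + 1L
    ok <- !is.na(i)
    mat[cbind(i[ok], j[ok])] <- TRUE
  }
  mat
}
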