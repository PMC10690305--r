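# Binning to variable-specific grids and hourly interpolation.

# Fast internals operating on sorted time/value vectors --------------------

# One node per non-empty half-open bin [k*step, (k+1)*step), placed at the
# bin's left edge; node value = in-bin mean (continuous) or last value in
# the bin (dichotomous).  `times` must be sorted ascending.
bin_nodes <- function(times, values, step, kind = "continuous") {
  if (!length(times)) {
    return(list(time = numeric(0), value = numeric(0)))
  }
  grp <- floor(times / step)
  lev <- sort(unique(grp))
  f <- factor(grp, levels = lev)
  v <- if (kind == "continuous") {
    as.numeric(tapply(values, f, mean))
  } else {
    as.numeric(tapply(values, f, function(x) x[length(x)]))
  }
  list(time = lev * step, value = v)
}

# Hourly values between the first and last node (no extrapolation).
interp_hours <- function(node_time, node_value, kind = "continuous") {
  k <- length(node_time)
  if (!k) {
    return(list(hour = numeric(0), value = numeric(0),
                observed = logical(0)))
  }
  hours <- seq(ceiling(node_time[1] - 1e-9), floor(node_time[k] + 1e-9))
  if (!length(hours) || hours[length(hours)] < node_time[1]) {
    return(list(hour = numeric(0), value = numeric(0),
                observed = logical(0)))
  }
  if (k == 1L) {
    val <- rep(node_value, length(hours))
  } else if (kind == "continuous") {
    val <- approx(node_time, node_value, xout = hours,
                  method = "linear")$y
  } else {
    # midpoint rule: the value switches at the first hour at or past the
    # midpoint between consecutive nodes
    bounds <- (node_time[-1] + node_time[-k]) / 2
    val <- node_value[findInterval(hours, bounds) + 1L]
  }
  observed <- hours %in% node_time
  list(hour = hours, value = val, observed = observed)
}

#' Bin one patient's measurements to the variable's grid
#'
#' Collapses irregular measurements into one node per non-empty half-open
#' bin `[k*step, (k+1)*step)`, placed at the bin's left edge.  Continuous
#' variables take the in-bin mean; dichotomous variables take the last
#' measurement in the bin.
#'
#' @param measurements Measurement tibble for a single patient (an error
#'   otherwise); only rows matching the spec's variable are used.
#' @param variable_spec A [variable_spec()] providing the grid step and
#'   kind.
#' @return A tibble of nodes: `time_h`, `value`, sorted by time.
#' @examples
#' m <- tibble::tibble(patient_id = "P1", variable = "temperature",
#'                     time_h = c(1, 1.5), value = c(98, 99))
#' bin_to_grid(m, variable_spec("temperature", grid_step_h = 2))
#' @export
bin_to_grid <- function(measurements, variable_spec) {
  m <- measurements[measurements$variable == variable_spec$name &
                      !is.na(measurements$value), , drop = FALSE]
  if (length(unique(m$patient_id)) > 1) {
    stop("bin_to_grid: expected measurements from a single patient",
         call. = FALSE)
  }
  o <- order(m$time_h)
  nodes <- bin_nodes(m$time_h[o], m$value[o], variable_spec$grid_step_h,
                     variable_spec$kind)
  tibble::tibble(time_h = nodes$time, value = nodes$value)
}

#' Interpolate grid nodes to an hourly series
#'
#' Evaluates the series at every integer hour between the first and last
#' node (never beyond: no extrapolation).  Continuous series are piecewise
#' linear between consecutive nodes; dichotomous series switch value at the
#' first hour at or past the midpoint between consecutive nodes with
#' differing values.  Node times are reproduced exactly where they fall on
#' integer hours, and those hours carry `observed = TRUE`.
#'
#' @param nodes Tibble of nodes (`time_h`, `value`) with strictly
#'   increasing times, e.g. from [bin_to_grid()].
#' @param kind `"continuous"` or `"dichotomous"`.
#' @return A tibble: `hour`, `value`, `observed`.
#' @examples
#' interpolate_hourly(tibble::tibble(time_h = c(0, 6), value = c(10, 16)))
#' @export
interpolate_hourly <- function(nodes, kind = c("continuous", "dichotomous")) {
  kind <- match.arg(kind)
  if (nrow(nodes) == 0) {
    stop("interpolate_hourly: need at least one node", call. = FALSE)
  }
  if (is.unsorted(nodes$time_h, strictly = TRUE)) {
    stop("interpolate_hourly: node times must be strictly increasing",
         call. = FALSE)
  }
  r <- interp_hours(nodes$time_h, nodes$value, kind)
  tibble::tibble(hour = r$hour, value = r$value, observed = r$observed)
}

#' Regularize a cohort's measurements into hourly series
#'
#' Runs [bin_to_grid()] and [interpolate_hourly()] for every
#' patient-variable series.  When `records` is supplied (the backward
#' analysis), measurements taken after a patient's observed outcome are
#' excluded before binning, so post-event data never leak into pre-event
#' interpolated values; censored patients are untouched.
#'
#' @param measurements Measurement tibble.
#' @param variable_specs Named list of [variable_spec()]s covering every
#'   variable present.
#' @param records Optional event-record tibble for one outcome.
#' @return A tibble: `patient_id`, `variable`, `hour`, `value`, `observed`.
#' @examples
#' m <- tibble::tibble(patient_id = "P1", variable = "marker",
#'                     time_h = c(0, 6), value = c(10, 16))
#' specs <- list(marker = variable_spec("marker", grid_step_h = 6))
#' hourly_series(m, specs)
#' @export
hourly_series <- function(measurements, variable_specs, records = NULL) {
  m <- measurements[!is.na(measurements$value), , drop = FALSE]
  if (!is.null(records)) {
    x_of <- ifelse(records$status == 1, records$X_h, Inf)
    x_of <- x_of[match(m$patient_id, records$patient_id)]
    x_of[is.na(x_of)] <- Inf
    m <- m[m$time_h <= x_of + 1e-9, , drop = FALSE]
  }
  vars <- unique(m$variable)
  no_spec <- setdiff(vars, names(variable_specs))
  if (length(no_spec)) {
    stop("hourly_series: no variable_spec for: ",
         paste(no_spec, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(vars))
  for (vi in seq_along(vars)) {
    v <- vars[vi]
    spec <- variable_specs[[v]]
    mv <- m[m$variable == v, , drop = FALSE]
    o <- order(mv$patient_id, mv$time_h)
    idx <- split(o, mv$patient_id[o])
    pieces <- lapply(idx, function(i) {
      nd <- bin_nodes(mv$time_h[i], mv$value[i], spec$grid_step_h,
                      spec$kind)
      interp_hours(nd$time, nd$value, spec$kind)
    })
    len <- vapply(pieces, function(p) length(p$hour), 0L)
    out[[vi]] <- tibble::tibble(
      patient_id = rep(names(pieces), len),
      variable = v,
      hour = unlist(lapply(pieces, `[[`, "hour"), use.names = FALSE),
      value = unlist(lapply(pieces, `[[`, "value"), use.names = FALSE),
      observed = unlist(lapply(pieces, `[[`, "observed"),
                        use.names = FALSE)
    )
  }
  dplyr::bind_rows(out)
}
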