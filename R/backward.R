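# Event-aligned backward-looking trajectory estimation.

#' Align hourly series backward from each patient's outcome time
#'
#' Builds the case-by-lag matrix at the heart of the backward-looking
#' analysis: rows are patients whose outcome was observed (`status = 1`),
#' columns are lags `s = 0, 1, ..., s_max` hours before the outcome, and
#' cell `(i, s)` holds the hourly interpolated value at hour
#' `floor(X_i) - s` -- the alignment origin is the last completed hour at
#' or before the outcome, so no cell can index an hour after the event.
#' Cells are missing wherever that hour precedes
#' admission or falls outside the patient's observed series span; the
#' hourly input should be built with the outcome's records (see
#' [hourly_series()]) so series are truncated at the event.
#'
#' @param hourly Hourly series tibble from [hourly_series()].
#' @param records Event-record tibble for one outcome.
#' @param variable Variable to align.
#' @param s_max Maximum lag in hours (default 72).
#' @return An object of class `aligned_matrix`: list with `values` (matrix
#'   cases x lags, `NA` for missing), `patient_id`, `X_h`, `variable`,
#'   `s_max`.
#' @examples
#' h <- tibble::tibble(patient_id = "P1", variable = "marker",
#'                     hour = 0:10, value = 7, observed = TRUE)
#' r <- tibble::tibble(patient_id = "P1", outcome = "mls5", X_h = 10,
#'                     status = 1, censor_reason = "none")
#' align_backward(h, r, "marker", s_max = 12)$values
#' @export
align_backward <- function(hourly, records, variable, s_max = 72) {
  cases <- records[records$status == 1, , drop = FALSE]
  hv <- hourly[hourly$variable == variable, , drop = FALSE]
  lags <- 0:s_max
  mat <- matrix(NA_real_, nrow = nrow(cases), ncol = length(lags),
                dimnames = list(cases$patient_id, paste0("s", lags)))
  if (nrow(cases) && nrow(hv)) {
    idx <- split(seq_len(nrow(hv)), hv$patient_id)
    for (i in seq_len(nrow(cases))) {
      rows <- idx[[cases$patient_id[i]]]
      if (is.null(rows)) next
      need <- floor(cases$X_h[i]) - lags
      mat[i, ] <- hv$value[rows][match(need, hv$hour[rows])]
    }
  }
  structure(list(values = mat, patient_id = cases$patient_id,
                 X_h = cases$X_h, variable = variable, s_max = s_max),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat("<aligned_matrix> ", nrow(x$values), " cases x lags 0..", x$s_max,
      "h for '", x$variable, "' (",
      round(100 * mean(!is.na(x$values))), "% cells observed)\n", sep = "")
  invisible(x)
}

#' Inverse-probability-of-censoring weights for observed cases
#'
#' Weights each observed case by the inverse estimated probability of
#' still being under observation just before its outcome time,
#' `w_i = 1 / G(X_i-)`, then normalizes the case weights to sum to 1.
#' Patients whose outcome was not observed receive weight 0 -- they
#' contribute through the censoring-distribution estimate G, not directly.
#' Without censoring, all case weights reduce to `1 / n_cases`.
#'
#' @param records Event-record tibble for one outcome.
#' @param G A [censoring_km()] fit estimated from the same records;
#'   `NULL` gives equal case weights.
#' @return A tibble aligned to `records`: `patient_id`, `weight`.
#' @examples
#' rec <- tibble::tibble(patient_id = c("a", "b", "c"),
#'                       X_h = c(10, 50, 30), status = c(1, 1, 0))
#' ipcw_weights(rec, censoring_km(rec))
#' @export
ipcw_weights <- function(records, G = NULL) {
  is_case <- records$status == 1
  w <- numeric(nrow(records))
  if (any(is_case)) {
    if (is.null(G)) {
      g <- rep(1, sum(is_case))
    } else {
      g <- G_left(G, records$X_h[is_case])
    }
    if (any(g <= 0)) {
      bad <- records$patient_id[is_case][g <= 0]
      stop("ipcw_weights: censoring survival is 0 at the outcome time of ",
           "patient(s) ", paste(head(bad, 5), collapse = ", "),
           " (positivity violation)", call. = FALSE)
    }
    w[is_case] <- (1 / g) / sum(1 / g)
  }
  tibble::tibble(patient_id = records$patient_id, weight = w)
}

# Resolve a weights argument (NULL, tibble, or named vector) to a numeric
# vector aligned with the aligned matrix's cases.
resolve_weights <- function(aligned, weights) {
  n <- length(aligned$patient_id)
  if (is.null(weights)) {
    return(rep(1 / max(n, 1), n))
  }
  if (is.data.frame(weights)) {
    w <- weights$weight[match(aligned$patient_id, weights$patient_id)]
  } else {
    w <- weights[aligned$patient_id]
  }
  if (anyNA(w)) {
    stop("backward estimation: missing weight for some case(s)",
         call. = FALSE)
  }
  as.numeric(w)
}

#' Weighted quantile (left-continuous inverse CDF)
#'
#' The q-th weighted quantile is the smallest observed value whose
#' cumulative normalized weight reaches q.  With equal weights this is the
#' smallest value `y` with `ecdf(y) >= q`.
#'
#' @param values Numeric vector (`NA`s dropped together with their
#'   weights).
#' @param weights Non-negative weights, not all zero; `NULL` for equal.
#' @param probs Probabilities in `(0, 1]`.
#' @return Numeric vector, one quantile per element of `probs`; `NA` when
#'   no usable values remain.
#' @examples
#' weighted_quantile(c(1, 3), c(0.5, 0.5), 0.5) # 1
#' @export
weighted_quantile <- function(values, weights = NULL,
                              probs = c(0.25, 0.5, 0.75)) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(probs > 0),
            all(probs <= 1))
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]
  weights <- weights[keep]
  if (!length(values)) return(rep(NA_real_, length(probs)))
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weighted_quantile: weights must be >= 0 and not all zero",
         call. = FALSE)
  }
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  vapply(probs, function(q) v[which(cw >= q - 1e-9)[1]], 0)
}

#' Backward-looking trajectory estimates
#'
#' For every lag `s` in `0..s_max` hours before the outcome,
#' `backward_estimate()` renormalizes the case weights over the cases with
#' a non-missing aligned value at that lag and reports the weighted mean
#' and the weighted 25th/50th/75th percentile of the marker, together with
#' the number of contributing cases.  Lags with fewer than `min_n`
#' contributing cases are masked (statistics reported as `NA`, never 0).
#' `backward_mean()` and `backward_quantiles()` return the corresponding
#' subsets.
#'
#' @param aligned An [align_backward()] matrix.
#' @param weights Case weights from [ipcw_weights()] (tibble or named
#'   vector); `NULL` for equal weights.
#' @param min_n Minimum contributing cases per lag before reporting
#'   (default 5).
#' @param lag_step_h Report every `lag_step_h`-th hour (default 1).
#' @return A tibble of class `backward_estimate`: `lag_h`, `n_eff`,
#'   `mean`, `q25`, `q50`, `q75`, `masked`.
#' @examples
#' h <- tibble::tibble(patient_id = "P1", variable = "m", hour = 0:48,
#'                     value = 7, observed = TRUE)
#' r <- tibble::tibble(patient_id = "P1", X_h = 48, status = 1)
#' backward_estimate(align_backward(h, r, "m"), min_n = 1)
#' @export
backward_estimate <- function(aligned, weights = NULL, min_n = 5,
                              lag_step_h = 1) {
  stopifnot(inherits(aligned, "aligned_matrix"))
  w <- resolve_weights(aligned, weights)
  lags <- seq(0, aligned$s_max, by = lag_step_h)
  cols <- lags + 1L
  n_eff <- integer(length(lags))
  mn <- q25 <- q50 <- q75 <- rep(NA_real_, length(lags))
  for (j in seq_along(cols)) {
    y <- aligned$values[, cols[j]]
    avail <- !is.na(y) & w > 0
    n_eff[j] <- sum(!is.na(y))
    if (n_eff[j] == 0 || n_eff[j] < min_n || !any(avail)) next
    wj <- w[avail] / sum(w[avail])
    mn[j] <- sum(wj * y[avail])
    qq <- weighted_quantile(y[avail], wj, c(0.25, 0.5, 0.75))
    q25[j] <- qq[1]; q50[j] <- qq[2]; q75[j] <- qq[3]
  }
  out <- tibble::tibble(lag_h = lags, n_eff = n_eff, mean = mn,
                        q25 = q25, q50 = q50, q75 = q75,
                        masked = is.na(mn))
  class(out) <- c("backward_estimate", class(out))
  out
}

#' @rdname backward_estimate
#' @export
backward_mean <- function(aligned, weights = NULL, min_n = 5) {
  backward_estimate(aligned, weights, min_n)[, c("lag_h", "n_eff", "mean",
                                                 "masked")]
}

#' @rdname backward_estimate
#' @export
backward_quantiles <- function(aligned, weights = NULL, min_n = 5) {
  backward_estimate(aligned, weights, min_n)[, c("lag_h", "n_eff", "q25",
                                                 "q50", "q75", "masked")]
}

#' Raw measurements in the window leading up to each observed outcome
#'
#' The backward-looking scatter: every raw (uninterpolated) measurement
#' taken within `window_h` hours before an observed outcome, with its lag
#' before the outcome.
#'
#' @param measurements Measurement tibble.
#' @param records Event-record tibble for one outcome.
#' @param variable Optional variable filter.
#' @param window_h Look-back window in hours (default 72).
#' @return A tibble: `patient_id`, `variable`, `lag_h`, `value`, `X_h`.
#' @export
backward_scatter <- function(measurements, records, variable = NULL,
                             window_h = 72) {
  m <- measurements
  if (!is.null(variable)) m <- m[m$variable %in% variable, , drop = FALSE]
  cases <- records[records$status == 1, , drop = FALSE]
  x_of <- cases$X_h[match(m$patient_id, cases$patient_id)]
  lag <- x_of - m$time_h
  keep <- !is.na(lag) & lag >= 0 & lag <= window_h
  tibble::tibble(patient_id = m$patient_id[keep],
                 variable = m$variable[keep],
                 lag_h = lag[keep], value = m$value[keep],
                 X_h = x_of[keep])
}

#' Raw measurements from admission for all patients
#'
#' The forward-looking scatter: every measurement before the patient's
#' observed time (outcome, death or censoring) and the horizon.
#'
#' @param measurements Measurement tibble.
#' @param records Optional event-record tibble; without it only the
#'   horizon truncation applies.
#' @param horizon_h Follow-up horizon in hours (default 192).
#' @return A tibble: `patient_id`, `variable`, `time_h`, `value`.
#' @export
forward_scatter <- function(measurements, records = NULL,
                            horizon_h = 192) {
  m <- measurements
  end <- rep(horizon_h, nrow(m))
  if (!is.null(records)) {
    x_of <- records$X_h[match(m$patient_id, records$patient_id)]
    end <- pmin(end, ifelse(is.na(x_of), Inf, x_of))
  }
  keep <- m$time_h <= end
  tibble::tibble(patient_id = m$patient_id[keep],
                 variable = m$variable[keep],
                 time_h = m$time_h[keep], value = m$value[keep])
}
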