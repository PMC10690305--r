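# Cumulative incidence with death as a competing risk, and the
# censoring-distribution Kaplan-Meier used for backward weighting.

#' Aalen-Johansen cumulative incidence with competing death
#'
#' Estimates the cause-specific cumulative incidence functions of the
#' outcome (`status = 1`) and of competing death (`status = 2`) by the
#' Aalen-Johansen product-limit estimator, with the Aalen-type variance and
#' pointwise confidence intervals on the complementary log-log scale
#' (clipped to `[0, 1]`).  Observations at tied times are processed
#' simultaneously against the same risk set.
#'
#' @param records Event-record tibble: `X_h` (> 0) and `status` in
#'   `{0, 1, 2}`; typically from [adjudicate_outcomes()].
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `cif_estimate`: a list with `steps` (tibble
#'   `time`, `cause`, `n_risk`, `cif`, `se`, `ci_lo`, `ci_hi`, one row per
#'   cause per jump or censoring time) and `surv` (tibble `time`, `surv`
#'   with the all-cause event-free survival).  At every time,
#'   `sum(cif over causes) + surv = 1`.
#' @examples
#' rec <- tibble::tibble(X_h = 1:4, status = c(1, 2, 0, 1))
#' aj <- aalen_johansen(rec)
#' cif_at(aj, c(2, 4))
#' @export
aalen_johansen <- function(records, conf_level = 0.95) {
  stopifnot(all(records$status %in% 0:2), all(records$X_h > 0))
  causes <- c("event", "death")
  if (!any(records$status %in% 1:2)) {
    warning("aalen_johansen: no events or deaths; CIF is identically 0",
            call. = FALSE)
    tt <- sort(unique(records$X_h))
    steps <- tibble::tibble(
      time = rep(tt, times = 2),
      cause = rep(causes, each = length(tt)),
      n_risk = rep(vapply(tt, function(t) sum(records$X_h >= t), 0L), 2),
      cif = 0, se = 0, ci_lo = 0, ci_hi = 0
    )
    return(structure(list(steps = steps,
                          surv = tibble::tibble(time = tt, surv = 1),
                          conf_level = conf_level),
                     class = "cif_estimate"))
  }
  st <- factor(records$status, levels = 0:2,
               labels = c("censor", "event", "death"))
  fit <- survival::survfit(survival::Surv(records$X_h, st) ~ 1)
  states <- fit$states
  get_state <- function(mat, s) {
    if (s %in% states) mat[, match(s, states)] else rep(0, length(fit$time))
  }
  n_risk <- if (is.matrix(fit$n.risk)) fit$n.risk[, 1] else fit$n.risk
  z <- qnorm(1 - (1 - conf_level) / 2)
  one_cause <- function(s) {
    p <- get_state(fit$pstate, s)
    se <- get_state(fit$std.err, s)
    # complementary log-log interval, respecting [0, 1]
    lo <- hi <- p
    ok <- p > 0 & p < 1 & se > 0
    w <- se[ok] / (p[ok] * log(p[ok]))
    lo[ok] <- p[ok]^exp(z * w)
    hi[ok] <- p[ok]^exp(-z * w)
    tibble::tibble(time = fit$time, cause = s, n_risk = n_risk,
                   cif = p, se = se,
                   ci_lo = pmin(pmax(pmin(lo, hi), 0), 1),
                   ci_hi = pmin(pmax(pmax(lo, hi), 0), 1))
  }
  steps <- dplyr::bind_rows(lapply(causes, one_cause))
  surv <- tibble::tibble(time = fit$time,
                         surv = get_state(fit$pstate, "(s0)"))
  structure(list(steps = steps, surv = surv, conf_level = conf_level),
            class = "cif_estimate")
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat("<cif_estimate> ", length(unique(x$steps$time)), " time points, ",
      round(100 * x$conf_level), "% CI\n", sep = "")
  last <- x$steps[x$steps$time == max(x$steps$time), ]
  for (i in seq_len(nrow(last))) {
    cat(sprintf("  CIF_%s(%g) = %.4f\n", last$cause[i], last$time[i],
                last$cif[i]))
  }
  invisible(x)
}

#' Evaluate a cumulative incidence function at given times
#'
#' Right-continuous step-function evaluation of a [aalen_johansen()]
#' estimate; times before the first jump give 0, times beyond the last
#' observed time return the last value and are marked `extrapolated`.
#'
#' @param estimate A `cif_estimate`.
#' @param times Evaluation times in hours (>= 0).
#' @param cause `"event"` or `"death"`.
#' @return A tibble: `time`, `cif`, `ci_lo`, `ci_hi`, `extrapolated`.
#' @export
cif_at <- function(estimate, times, cause = "event") {
  stopifnot(inherits(estimate, "cif_estimate"), all(times >= 0))
  s <- estimate$steps[estimate$steps$cause == cause, , drop = FALSE]
  idx <- findInterval(times + 1e-12, s$time)
  pick <- function(col) ifelse(idx == 0, 0, col[pmax(idx, 1)])
  tibble::tibble(
    time = times,
    cif = pick(s$cif),
    ci_lo = pick(s$ci_lo),
    ci_hi = pick(s$ci_hi),
    extrapolated = times > max(s$time)
  )
}

#' Kaplan-Meier estimate of the censoring-time survival
#'
#' Estimates the survival function G(t) of the censoring time by
#' Kaplan-Meier with the roles reversed: censoring is the "event" and
#' outcomes are censored observations.  By the package's default
#' convention, death is pooled with discharge/horizon censoring (the
#' longitudinal record ends at death just as it does at discharge), so the
#' downstream weighted estimand conditions on surviving to the outcome;
#' `death = "competing"` instead treats only `status = 0` as censoring.
#'
#' @param records Event-record tibble (`X_h`, `status`).
#' @param death `"censoring"` (default) or `"competing"`.
#' @return An object of class `censoring_km` with the step function
#'   `time`/`surv`; evaluate with [G_at()] / [G_left()].
#' @examples
#' rec <- tibble::tibble(X_h = 1:4, status = c(1, 2, 0, 1))
#' G <- censoring_km(rec)
#' G_left(G, 4)
#' @export
censoring_km <- function(records, death = c("censoring", "competing")) {
  death <- match.arg(death)
  is_cens <- records$status == 0 |
    (death == "censoring" & records$status == 2)
  fit <- survival::survfit(survival::Surv(records$X_h, is_cens) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, death = death),
            class = "censoring_km")
}

#' Evaluate the censoring survival and its left limit
#'
#' `G_at()` returns the right-continuous value G(t); `G_left()` the left
#' limit G(t-), the probability of remaining uncensored just before `t`,
#' which is what inverse-probability-of-censoring weights use.
#'
#' @param G A `censoring_km` object.
#' @param t Numeric vector of times.
#' @return Numeric vector of survival probabilities.
#' @export
G_at <- function(G, t) {
  idx <- findInterval(t, G$time)
  ifelse(idx == 0, 1, G$surv[pmax(idx, 1)])
}

#' @rdname G_at
#' @export
G_left <- function(G, t) {
  idx <- findInterval(t, G$time, left.open = TRUE)
  ifelse(idx == 0, 1, G$surv[pmax(idx, 1)])
}

#' @export
print.censoring_km <- function(x, ...) {
  cat("<censoring_km> death treated as ", x$death, "; G(",
      max(x$time), ") = ", signif(min(x$surv), 4), "\n", sep = "")
  invisible(x)
}
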