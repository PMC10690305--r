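# Outcome adjudication: one event record per patient per outcome.

#' Adjudicate mass-effect outcomes for every patient
#'
#' Produces one event record per patient for the requested outcome:
#' \describe{
#'   \item{`"mls5"`}{first scan with midline shift >= 5 mm (inclusive);}
#'   \item{`"pgs4"`}{first scan with pineal gland shift > 4 mm (strict);}
#'   \item{`"dhc"`}{decompressive hemicraniectomy.}
#' }
#' The event time is the qualifying scan's timestamp (or the procedure
#' time).  Death before the event is a competing event (`status = 2`);
#' otherwise the patient is censored (`status = 0`) at the earliest of
#' surgery (for radiographic outcomes whose first crossing would fall after
#' it; `censor_reason = "dhc_precedence"`), discharge, or the follow-up
#' horizon.  A crossing and a competing time at the same timestamp resolve
#' in favour of the event.  Crossings after the horizon are censored at the
#' horizon.
#'
#' @param cohort A [cohort()] object.
#' @param outcome One of `"mls5"`, `"pgs4"`, `"dhc"`.
#' @param horizon_h Follow-up horizon in hours (default 192).
#' @param mls_threshold_mm,pgs_threshold_mm Radiographic thresholds
#'   (defaults 5 and 4 mm; midline shift is compared inclusively, pineal
#'   gland shift strictly).
#' @return A tibble with one row per patient: `patient_id`, `outcome`,
#'   `X_h` (observed time, `0 < X_h <= horizon_h`), `status` (1 event,
#'   2 death, 0 censored) and `censor_reason` (`"none"`, `"dhc_precedence"`,
#'   `"discharge"`, `"horizon"`).
#' @examples
#' p <- tibble::tibble(patient_id = "P1", death_h = NA, discharge_h = 100)
#' m <- tibble::tibble(patient_id = "P1", variable = "mls",
#'                     time_h = c(10, 40), value = c(2, 6))
#' adjudicate_outcomes(cohort(p, m), "mls5")
#' @export
adjudicate_outcomes <- function(cohort, outcome = c("mls5", "pgs4", "dhc"),
                                horizon_h = 192,
                                mls_threshold_mm = 5,
                                pgs_threshold_mm = 4) {
  stopifnot(inherits(cohort, "cohort"))
  outcome <- match.arg(outcome)
  p <- cohort$patients
  n <- nrow(p)
  m <- cohort$measurements
  pr <- cohort$procedures

  dhc_t <- rep(NA_real_, n)
  if (nrow(pr)) {
    d <- pr[tolower(pr$procedure) == "dhc", , drop = FALSE]
    if (nrow(d)) {
      first <- tapply(d$time_h, d$patient_id, min)
      dhc_t[match(names(first), p$patient_id)] <- as.numeric(first)
    }
  }
  bad <- which(!is.na(dhc_t) & !is.na(p$death_h) & dhc_t > p$death_h + 1e-8)
  if (length(bad)) {
    stop("adjudicate_outcomes: DHC recorded after death for patient(s) ",
         paste(head(p$patient_id[bad], 5), collapse = ", "), call. = FALSE)
  }

  first_crossing <- function(var, threshold, strict) {
    s <- m[m$variable == var, , drop = FALSE]
    n_missing <- sum(is.na(s$value))
    if (n_missing > 0) {
      warning("adjudicate_outcomes: skipped ", n_missing, " ", var,
              " scan(s) with missing value", call. = FALSE)
      s <- s[!is.na(s$value), , drop = FALSE]
    }
    hit <- if (strict) s$value > threshold else s$value >= threshold
    s <- s[hit, , drop = FALSE]
    out <- rep(NA_real_, n)
    if (nrow(s)) {
      first <- tapply(s$time_h, s$patient_id, min)
      out[match(names(first), p$patient_id)] <- as.numeric(first)
    }
    out
  }

  death <- ifelse(is.na(p$death_h), Inf, p$death_h)
  discharge <- ifelse(is.na(p$discharge_h), Inf, p$discharge_h)

  if (outcome == "dhc") {
    ev <- ifelse(is.na(dhc_t), Inf, dhc_t)
    cand <- rbind(ev, death, discharge, rep(horizon_h, n))
    status_of <- c(1L, 2L, 0L, 0L)
    reason_of <- c("none", "none", "discharge", "horizon")
  } else {
    ev <- if (outcome == "mls5") {
      first_crossing("mls", mls_threshold_mm, strict = FALSE)
    } else {
      first_crossing("pgs", pgs_threshold_mm, strict = TRUE)
    }
    ev <- ifelse(is.na(ev), Inf, ev)
    dhc_c <- ifelse(is.na(dhc_t), Inf, dhc_t)
    # surgery strictly before the first crossing censors it; the rbind
    # order encodes tie priority event > death > dhc > discharge > horizon
    cand <- rbind(ev, death, dhc_c, discharge, rep(horizon_h, n))
    status_of <- c(1L, 2L, 0L, 0L, 0L)
    reason_of <- c("none", "none", "dhc_precedence", "discharge", "horizon")
  }

  j <- apply(cand, 2, which.min)
  x <- cand[cbind(j, seq_len(n))]
  tibble::tibble(
    patient_id = p$patient_id,
    outcome = outcome,
    X_h = x,
    status = status_of[j],
    censor_reason = reason_of[j]
  )
}
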