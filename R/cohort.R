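# Tidy cohort data model and CSV input/output.

required_cols <- list(
  patients = c("patient_id", "death_h", "discharge_h"),
  measurements = c("patient_id", "variable", "time_h", "value"),
  procedures = c("patient_id", "procedure", "time_h")
)

#' Construct and validate a cohort
#'
#' A cohort links three tidy tables: `patients` (one row per patient with
#' nullable death and discharge times in hours from admission plus any
#' baseline covariates), `measurements` (long table of repeated laboratory,
#' vital-sign and radiographic values), and `procedures` (currently
#' decompressive hemicraniectomy times).  Construction validates the schema
#' and the cross-table invariants and fails with row-level diagnostics.
#'
#' @param patients,measurements,procedures Data frames; `procedures` may be
#'   omitted.
#' @return An object of class `cohort` (a named list of the three tibbles).
#' @examples
#' p <- tibble::tibble(patient_id = "P1", death_h = NA, discharge_h = 100)
#' m <- tibble::tibble(patient_id = "P1", variable = "wbc",
#'                     time_h = c(0, 24), value = c(9.5, 10.2))
#' cohort(p, m)
#' @export
cohort <- function(patients, measurements, procedures = NULL) {
  if (is.null(procedures)) {
    procedures <- tibble::tibble(patient_id = character(),
                                 procedure = character(),
                                 time_h = numeric())
  }
  x <- list(patients = tibble::as_tibble(patients),
            measurements = tibble::as_tibble(measurements),
            procedures = tibble::as_tibble(procedures))
  validate_cohort(x)
  structure(x, class = "cohort")
}

# Collects all invariant violations and reports them with row indices.
validate_cohort <- function(x) {
  problems <- character()
  note <- function(tbl, rows, what) {
    if (!length(rows)) return()
    shown <- paste(head(rows, 5), collapse = ", ")
    more <- if (length(rows) > 5) sprintf(" (+%d more)", length(rows) - 5)
      else ""
    problems <<- c(problems,
                   sprintf("%s: %s at row(s) %s%s", tbl, what, shown, more))
  }
  for (tbl in names(required_cols)) {
    miss <- setdiff(required_cols[[tbl]], names(x[[tbl]]))
    if (length(miss)) {
      problems <- c(problems, sprintf("%s: missing column(s) %s", tbl,
                                      paste(miss, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  p <- x$patients; m <- x$measurements; pr <- x$procedures
  note("patients", which(duplicated(p$patient_id)), "duplicated patient_id")
  note("patients", which(!is.na(p$death_h) & p$death_h <= 0),
       "death_h must be > 0")
  note("patients", which(!is.na(p$discharge_h) & p$discharge_h <= 0),
       "discharge_h must be > 0")
  note("measurements", which(!(m$patient_id %in% p$patient_id)),
       "unknown patient_id")
  note("measurements", which(!is.finite(m$time_h) | m$time_h < 0),
       "time_h must be finite and >= 0")
  end <- pmin(ifelse(is.na(p$death_h), Inf, p$death_h),
              ifelse(is.na(p$discharge_h), Inf, p$discharge_h))
  end_of <- end[match(m$patient_id, p$patient_id)]
  note("measurements",
       which(is.finite(m$time_h) & m$time_h > end_of + 1e-8),
       "measurement after death/discharge")
  note("procedures", which(!(pr$patient_id %in% p$patient_id)),
       "unknown patient_id")
  note("procedures", which(!is.finite(pr$time_h) | pr$time_h < 0),
       "time_h must be finite and >= 0")
  death_of <- p$death_h[match(pr$patient_id, p$patient_id)]
  note("procedures", which(!is.na(death_of) & pr$time_h > death_of + 1e-8),
       "procedure after death")
  if (length(problems)) {
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$patients), " patients, ",
      nrow(x$measurements), " measurements (",
      length(unique(x$measurements$variable)), " variables), ",
      nrow(x$procedures), " procedures\n", sep = "")
  invisible(x)
}

#' Read / write a cohort as CSV files
#'
#' `write_cohort()` writes `patients.csv`, `measurements.csv` and
#' `procedures.csv` (lowercase snake_case headers, decimal hours from
#' admission, empty fields for missing values) into `dir`; `read_cohort()`
#' reads them back and validates.  The pair round-trips: reading a written
#' cohort reproduces its tables.
#'
#' @param dir Directory containing (or to receive) the CSV files.
#' @param cohort A [cohort()] object.
#' @return `read_cohort()` returns a [cohort()]; `write_cohort()` returns
#'   the directory path, invisibly.
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("patients.csv", "measurements.csv")) {
    if (!file.exists(path(f))) {
      stop("read_cohort: missing file ", path(f), call. = FALSE)
    }
  }
  rd <- function(f, types) {
    readr::read_csv(path(f), col_types = types, progress = FALSE)
  }
  patients <- rd("patients.csv", readr::cols(
    patient_id = readr::col_character(),
    death_h = readr::col_double(),
    discharge_h = readr::col_double(),
    .default = readr::col_guess()
  ))
  measurements <- rd("measurements.csv", readr::cols(
    patient_id = readr::col_character(),
    variable = readr::col_character(),
    time_h = readr::col_double(),
    value = readr::col_double(),
    .default = readr::col_guess()
  ))
  procedures <- if (file.exists(path("procedures.csv"))) {
    rd("procedures.csv", readr::cols(
      patient_id = readr::col_character(),
      procedure = readr::col_character(),
      time_h = readr::col_double()
    ))
  } else NULL
  cohort(patients, measurements, procedures)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$procedures, file.path(dir, "procedures.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Midline shift from lateral and medial boundary readings
#'
#' The analysed midline shift is the arithmetic mean of the lateral- and
#' medial-boundary displacements read from the same scan.
#'
#' @param lateral_mm,medial_mm Non-negative displacements in mm (vectorized;
#'   `NA` propagates).
#' @return Numeric vector of midline shift in mm.
#' @examples
#' compute_mls(4, 6) # 5
#' @export
compute_mls <- function(lateral_mm, medial_mm) {
  if (length(lateral_mm) != length(medial_mm)) {
    stop("compute_mls: inputs must have equal length", call. = FALSE)
  }
  if (any(lateral_mm < 0, na.rm = TRUE) || any(medial_mm < 0, na.rm = TRUE)) {
    stop("compute_mls: boundary displacements must be >= 0", call. = FALSE)
  }
  (lateral_mm + medial_mm) / 2
}

#' Baseline value of a variable around the time origin
#'
#' Returns the measurement closest in time to the origin within the
#' admission window (by default 8 hours before to 36 hours after), or `NA`
#' when no measurement falls in the window.  Ties in distance resolve to
#' the earlier measurement.
#'
#' @param measurements Measurement tibble.
#' @param variable Variable name.
#' @param origin_h Time origin in hours (default 0 = admission).
#' @param window_before_h,window_after_h Window bounds in hours.
#' @return A length-1 numeric value (possibly `NA`).
#' @examples
#' m <- tibble::tibble(patient_id = "P1", variable = "glucose",
#'                     time_h = c(5, 30), value = c(140, 180))
#' baseline_value(m, "glucose") # 140
#' @export
baseline_value <- function(measurements, variable, origin_h = 0,
                           window_before_h = 8, window_after_h = 36) {
  m <- measurements[measurements$variable == variable &
                      !is.na(measurements$value), , drop = FALSE]
  lo <- origin_h - window_before_h
  hi <- origin_h + window_after_h
  m <- m[m$time_h >= lo & m$time_h <= hi, , drop = FALSE]
  if (nrow(m) == 0) return(NA_real_)
  d <- abs(m$time_h - origin_h)
  cand <- which(d == min(d))
  m$value[cand[which.min(m$time_h[cand])]]
}
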