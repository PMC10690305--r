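# Static figure builders.  All functions return ggplot objects; the
# pipeline driver saves them to files.

#' Individual forward-looking trajectory panel
#'
#' One panel per variable showing a single patient's raw measurements from
#' admission, with vertical markers at the adjudicated outcome times,
#' surgery, and death where present.
#'
#' @param cohort A [cohort()] object.
#' @param patient_id Patient to plot (error if unknown).
#' @param variables Variables to include (default: all the patient has).
#' @param records Optional event-record tibble(s) (rows for several
#'   outcomes may be concatenated) used to draw outcome markers.
#' @return A ggplot object.
#' @export
plot_individual <- function(cohort, patient_id, variables = NULL,
                            records = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (!patient_id %in% cohort$patients$patient_id) {
    stop("plot_individual: unknown patient '", patient_id, "'",
         call. = FALSE)
  }
  m <- cohort$measurements[cohort$measurements$patient_id == patient_id, ,
                           drop = FALSE]
  if (!is.null(variables)) m <- m[m$variable %in% variables, , drop = FALSE]
  marks <- tibble::tibble(time_h = numeric(), label = character())
  if (!is.null(records)) {
    r <- records[records$patient_id == patient_id & records$status == 1, ,
                 drop = FALSE]
    if (nrow(r)) {
      marks <- dplyr::bind_rows(marks,
        tibble::tibble(time_h = r$X_h, label = r$outcome))
    }
  }
  pr <- cohort$procedures[cohort$procedures$patient_id == patient_id, ,
                          drop = FALSE]
  if (nrow(pr)) {
    marks <- dplyr::bind_rows(marks,
      tibble::tibble(time_h = pr$time_h, label = pr$procedure))
  }
  d <- cohort$patients$death_h[cohort$patients$patient_id == patient_id]
  if (!is.na(d)) {
    marks <- dplyr::bind_rows(marks,
      tibble::tibble(time_h = d, label = "death"))
  }
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "hours from admission", y = NULL,
                  title = paste("Patient", patient_id)) +
    ggplot2::theme_minimal()
  if (nrow(m)) {
    p <- p + ggplot2::geom_line(alpha = 0.5) + ggplot2::geom_point(size = 1)
  } else {
    p <- p + ggplot2::annotate("text", x = 0, y = 0,
                               label = "no longitudinal data")
  }
  if (nrow(marks)) {
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$time_h, colour = .data$label),
      linetype = "dashed")
  }
  p
}

#' Backward-looking trajectory bands
#'
#' Median line with interquartile band and mean overlay against the lag
#' before the outcome; the event sits at the right edge (lag 0) so time
#' flows left to right.  Masked lags are blank.
#'
#' @param estimates A [backward_estimate()] tibble, or a named list of
#'   them (names become facet labels).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_backward_bands <- function(estimates, title = NULL) {
  if (inherits(estimates, "backward_estimate")) {
    estimates <- list(trajectory = estimates)
  }
  d <- dplyr::bind_rows(lapply(estimates, tibble::as_tibble),
                        .id = "panel")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q50), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "black",
                       linetype = "dashed") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "hours before outcome", y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Forward- and backward-looking scatter plots
#'
#' @param scatter Output of [forward_scatter()] or [backward_scatter()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_forward_scatter <- function(scatter, title = NULL) {
  ggplot2::ggplot(scatter,
                  ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "hours from admission", y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @rdname plot_forward_scatter
#' @export
plot_backward_scatter <- function(scatter, title = NULL) {
  ggplot2::ggplot(scatter,
                  ggplot2::aes(x = .data$lag_h, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "hours before outcome", y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Availability heatmap
#'
#' @param mat Logical matrix from [availability_matrix()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_availability <- function(mat, title = NULL) {
  d <- tibble::tibble(
    patient_id = rep(rownames(mat), ncol(mat)),
    bin_start_h = rep(as.numeric(colnames(mat)), each = nrow(mat)),
    present = as.vector(mat)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_start_h,
                                  y = .data$patient_id,
                                  fill = .data$present)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "hours from admission", y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
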