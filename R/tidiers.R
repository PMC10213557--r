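#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stage model
#'
#' One row per cluster (stage): its mean central-cell volume and organ
#' count; for WSS-curve models, one row per candidate k with its WSS and
#' normalized curvature.
#'
#' @param x a `stage_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.stage_model <- function(x, ...) {
  if (!is.null(x$assignments)) {
    tibble::tibble(
      stage = seq_len(x$k),
      mean_volume_um3 = x$means,
      n_organs = vapply(seq_len(x$k), function(m)
        sum(x$assignments == m), integer(1)))
  } else {
    x$wss
  }
}

#' Glance at a stage model
#' @param x a `stage_model`.
#' @param ... unused.
#' @return one-row tibble: k (or suggested k), WSS, scale, confidence flag.
#' @export
glance.stage_model <- function(x, ...) {
  if (!is.null(x$assignments)) {
    tibble::tibble(k = x$k, n_organs = sum(x$assignments > 0),
                   n_stage0 = sum(x$assignments == 0),
                   log_scale = x$log_scale)
  } else {
    tibble::tibble(k = NA_integer_, suggested_k = x$suggested_k,
                   low_confidence = x$low_confidence,
                   log_scale = x$log_scale)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stage model
#'
#' WSS elbow curve (for [wss_curve_and_elbow()] results) or the central-cell
#' volume strip colored by assigned stage (for [assign_stages()] results,
#' with `values` supplied).
#'
#' @param object a `stage_model`.
#' @param values the clustered volumes (needed for assignment plots).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stage_model <- function(object, values = NULL, ...) {
  if (is.null(object$assignments)) {
    ggplot2::ggplot(object$wss, ggplot2::aes(x = .data$k, y = .data$wss)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = object$suggested_k,
                          linetype = "dashed", color = "grey40") +
      ggplot2::labs(x = "number of clusters k",
                    y = "total within-cluster sum of squares",
                    title = sprintf("Elbow curve (suggested k = %d%s)",
                                    object$suggested_k,
                                    if (isTRUE(object$low_confidence))
                                      ", low confidence" else "")) +
      ggplot2::theme_minimal()
  } else {
    if (is.null(values))
      stop("supply `values` to plot a fitted stage assignment")
    df <- tibble::tibble(volume = values,
                         stage = factor(object$assignments))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$volume,
                                     color = .data$stage)) +
      ggplot2::geom_jitter(width = 0.15, height = 0) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "assigned stage",
                    y = expression(paste("central L2 cell volume (",
                                         mu * m^3, ")"))) +
      ggplot2::theme_minimal()
  }
}

#' Line chart of mean descriptor by cell class along stages
#'
#' The per-class developmental trajectory plot: group means with SEM error
#' bars, one line per cell class.
#'
#' @param cell_table a staged cell table.
#' @param descriptor descriptor column to plot.
#' @param classes contact classes to include.
#' @return a ggplot.
#' @export
plot_class_trajectories <- function(cell_table, descriptor = "volume_um3",
                                    classes = c("central_L2", "central_L3",
                                                "contact1", "contact2")) {
  gs <- group_summary(cell_table, descriptor = descriptor)
  gs <- gs[gs$class %in% classes, ]
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$stage, y = .data$mean,
                                   color = .data$class,
                                   group = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.1) +
    ggplot2::labs(x = "developmental stage", y = descriptor,
                  color = "cell class") +
    ggplot2::theme_minimal()
}

#' Density/histogram comparison of division-call continuity angles
#'
#' @param calls a [detect_recent_divisions()] table.
#' @param threshold continuity threshold to mark.
#' @return a ggplot.
#' @export
plot_continuity_angles <- function(calls, threshold = 160) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$continuity_angle_deg,
                               fill = .data$is_recent)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "junction wall angle (degrees)", fill = "recent") +
    ggplot2::theme_minimal()
}
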