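#' Plot trajectories
#'
#' Paths of every track in arena coordinates, colored by track identity,
#' with the y axis flipped so "up" in the tank is up on the page.
#'
#' @param tracks track tibble.
#' @return a ggplot object.
#' @export
plot_tracks <- function(tracks) {
  ggplot2::ggplot(tracks, ggplot2::aes(.data$x_px, .data$y_px,
                                       group = .data$track_id,
                                       color = factor(.data$track_id))) +
    ggplot2::geom_path(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px, down)", title = "Trajectories")
}

#' @export
autoplot.km_fit <- function(object, ...) {
  d <- object$curve
  d0 <- bind_rows(tibble(time = 0, surv = 1), d[, c("time", "surv")])
  ggplot2::ggplot(d0, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        color = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival S(t)",
                  title = "Kaplan-Meier lifespan curve",
                  subtitle = paste0("median = ",
                                    format(object$median_days), " days"))
}

#' @export
autoplot.clock_model <- function(object, ...) {
  ggplot2::ggplot(object$cv_predictions,
                  ggplot2::aes(.data$age_days, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "red") +
    ggplot2::labs(x = "chronological age (days)",
                  y = "predicted age (days)",
                  title = "Phenotypic clock, held-out predictions")
}

#' @export
autoplot.phenotypic_age <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$condition, .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "phenotypic - chronological age (days)",
                  title = "Phenotypic age deltas by condition")
}

#' Plot a feature correlation matrix
#'
#' @param m correlation matrix from [correlation_matrix()].
#' @return a ggplot tile plot.
#' @export
plot_correlation <- function(m) {
  d <- as.data.frame(as.table(m))
  names(d) <- c("f1", "f2", "r")
  ggplot2::ggplot(d, ggplot2::aes(.data$f1, .data$f2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Feature correlation matrix")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
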