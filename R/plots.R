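#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an SmO2 trace
#'
#' Trace over time, optionally shading rest phases of a schedule.
#'
#' @param object An [smo2_trace()].
#' @param schedule Optional `stage_schedule` for phase shading.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot smo2_trace
#' @export
autoplot.smo2_trace <- function(object, schedule = NULL, ...) {
  m <- trace_meta(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$smo2_pct))
  if (!is.null(schedule)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(schedule),
      ggplot2::aes(xmin = .data$work_end_s, xmax = .data$rest_end_s),
      ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line(colour = "#2166ac", na.rm = TRUE) +
    ggplot2::labs(x = "Time (s)", y = "SmO2 (%)",
                  title = sprintf("%s trial %s, %s", m$participant_id,
                                  m$trial, m$site)) +
    ggplot2::theme_minimal()
}

#' Plot half-recovery time by workload and muscle site
#'
#' @param bouts Output of [extract_bouts()] (OK bouts are shown).
#' @return A ggplot of HRT distributions per target workload, faceted by
#'   site.
#' @export
plot_hrt <- function(bouts) {
  d <- bouts[bouts$status == "OK", ]
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$target_pct), .data$hrt_s)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~site, nrow = 1) +
    ggplot2::labs(x = "Target workload (% Wpeak)",
                  y = "Half-recovery time (s)") +
    ggplot2::theme_minimal()
}

#' Plot a monoexponential fit against its data
#'
#' @param object A `monoexp_fit` carrying its fitted segment.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot monoexp_fit
#' @export
autoplot.monoexp_fit <- function(object, ...) {
  if (is.null(object$data)) stop("fit carries no data", call. = FALSE)
  d <- object$data
  grid <- data.frame(t = seq(min(d$t), max(d$t), length.out = 200))
  grid$y <- object$y0 + object$amp *
    (1 - exp(-pmax(grid$t - object$delay_s, 0) / object$tau_s))
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#b2182b") +
    ggplot2::labs(x = "Time from end of work (s)", y = "SmO2 (%)",
                  subtitle = sprintf("tau = %.1f s, delay = %.1f s, pseudo-R2 = %.3f",
                                     object$tau_s, object$delay_s,
                                     object$pseudo_r2)) +
    ggplot2::theme_minimal()
}
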