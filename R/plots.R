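#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a baseflow separation
#'
#' Total flow with the slow-flow component shaded underneath; the gap
#' between the lines is quickflow.
#'
#' @param object a [separate_baseflow()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.baseflow_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$slowflow), fill = "steelblue",
                       alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$flow), linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = expression(Q ~ (m^3 ~ s^-1)),
                  title = "Flow separation: slow flow (shaded) under total flow") +
    ggplot2::theme_minimal()
}

#' Plot extracted events over the hydrograph
#'
#' The diagnostic time-series view: rainfall (inverted, top), measured flow
#' and quickflow, with each surviving event window shaded.
#'
#' @param base a [separate_baseflow()] result.
#' @param rain the matching rain series.
#' @param events the [extract_events()] table for the same site.
#' @return A ggplot.
#' @export
plot_event_extraction <- function(base, rain, events) {
  df <- tibble::as_tibble(base)
  scale_r <- max(df$flow, na.rm = TRUE) /
    max(c(rain$value, 1e-9), na.rm = TRUE) / 3
  keep <- !events$excluded & !events$unpaired
  win <- tibble::as_tibble(events[keep, c("start", "end")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp)) +
    ggplot2::geom_rect(
      data = win,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.25
    ) +
    ggplot2::geom_col(
      data = tibble::tibble(timestamp = rain$timestamp, rain = rain$value),
      ggplot2::aes(y = .data$rain * scale_r),
      width = 900, fill = "grey40"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$flow), linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$quickflow), colour = "firebrick",
                       linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = expression(Q ~ (m^3 ~ s^-1)),
                  title = "Event windows over the hydrograph",
                  subtitle = "grey: rainfall (scaled); red: quickflow; shaded: events") +
    ggplot2::theme_minimal()
}

#' Plot estimated marginal means
#'
#' Point-and-interval display of the equal-weight marginal means, split by
#' beaver period and any season/site factors present.
#'
#' @param object a [marginal_means()] table.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.marginal_means <- function(object, ...) {
  df <- tibble::as_tibble(object)
  facet_vars <- intersect(c("season", "site"), names(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beaver, y = .data$emmean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$emmean - .data$se,
      ymax = .data$emmean + .data$se
    )) +
    ggplot2::labs(
      x = "beaver", y = expression(peak ~ Q ~ (m^3 ~ s^-1)),
      title = "Estimated marginal mean peak flow (+/- SE)"
    ) +
    ggplot2::theme_minimal()
  if (length(facet_vars)) {
    p <- p + ggplot2::facet_wrap(facet_vars)
  }
  p
}

#' Plot a fitted peak-flow GLM
#'
#' Observed peak flow against event rainfall with the model's fitted lines
#' per beaver level (other factors at their reference levels).
#'
#' @param object a [fit_peakflow_glm()] object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.peakflow_glm <- function(object, ...) {
  ev <- object$data
  grid <- tidyr::expand_grid(
    rain_mm = seq(min(ev$rain_mm), max(ev$rain_mm), length.out = 50),
    beaver = factor(levels(ev$beaver), levels = levels(ev$beaver))
  )
  for (f in intersect(c("season", "site"), names(ev))) {
    grid[[f]] <- factor(levels(factor(ev[[f]]))[1],
                        levels = levels(factor(ev[[f]])))
  }
  grid$fit <- predict(object$fit, newdata = grid, type = "response")
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$rain_mm, y = .data$peak_q,
                                   colour = .data$beaver)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(
      x = "total event rainfall (mm)", y = expression(peak ~ Q ~ (m^3 ~ s^-1)),
      title = sprintf("Gamma identity GLM (%s)", object$kind)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rating curve with its gaugings
#'
#' @param object a [fit_rating_curve()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rating_curve <- function(object, ...) {
  rng <- object$stage_range
  grid <- tibble::tibble(stage = seq(rng[1], rng[2], length.out = 200))
  grid$discharge <- predict(object, grid$stage)
  obs <- tibble::tibble(
    stage = object$fit$model$h,
    discharge = object$fit$model$q
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$stage, y = .data$discharge)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = obs, size = 1, alpha = 0.6) +
    ggplot2::labs(x = "stage (m)", y = expression(Q ~ (m^3 ~ s^-1)),
                  title = "Stage-discharge rating") +
    ggplot2::theme_minimal()
}
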