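#' Channel geometry for Manning's equation
#'
#' Describes the cross-section of the gauged structure (typically a smooth
#' lined culvert or channel). Stage is measured as depth above the invert
#' (lowest point) of the section, so 0 means dry.
#'
#' @param shape `"rectangular"`, `"circular"` or `"trapezoidal"`.
#' @param width bottom width in metres (rectangular, trapezoidal).
#' @param diameter pipe diameter in metres (circular).
#' @param side_slope horizontal run per unit rise of the banks
#'   (trapezoidal; 0 gives a rectangle).
#' @param slope channel bed slope S (dimensionless rise/run), > 0.
#' @param n Manning roughness (s m^-1/3); 0.015 suits a smooth lined culvert.
#' @param K unit constant, 1 for metric inputs.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(shape = c("rectangular", "circular", "trapezoidal"),
                             width = NULL, diameter = NULL, side_slope = NULL,
                             slope, n = 0.015, K = 1) {
  shape <- match.arg(shape)
  chk_pos <- function(v, nm) {
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  chk_pos(slope, "slope")
  chk_pos(n, "n")
  chk_pos(K, "K")
  switch(shape,
    rectangular = chk_pos(width, "width"),
    circular = chk_pos(diameter, "diameter"),
    trapezoidal = {
      chk_pos(width, "width")
      if (is.null(side_slope) || side_slope < 0) {
        abort("`side_slope` must be >= 0 for a trapezoidal section.")
      }
    }
  )
  structure(
    list(shape = shape, width = width, diameter = diameter,
         side_slope = side_slope, slope = slope, n = n, K = K),
    class = "channel_geometry"
  )
}

# flow area and wetted perimeter at a given depth above the invert
section_geometry <- function(geom, depth) {
  switch(geom$shape,
    rectangular = list(A = geom$width * depth,
                       P = geom$width + 2 * depth),
    trapezoidal = list(A = (geom$width + geom$side_slope * depth) * depth,
                       P = geom$width + 2 * depth * sqrt(1 + geom$side_slope^2)),
    circular = {
      D <- geom$diameter
      theta <- 2 * acos(pmin(1, pmax(-1, 1 - 2 * depth / D)))
      list(A = D^2 / 8 * (theta - sin(theta)), P = D * theta / 2)
    }
  )
}

#' Discharge from stage via Manning's equation
#'
#' Computes `Q = K * A * R^0.667 * S^0.5 / n`, where `A` is the flow area,
#' `R = A / P` the hydraulic radius (`P` the wetted perimeter), `S` the bed
#' slope and `n` the Manning roughness. The exponent on `R` is 0.667, the
#' conventional three-decimal form of 2/3.
#'
#' @param geom a [channel_geometry()].
#' @param depth water depth above the invert, metres; may be a vector.
#' @return Discharge in m3/s, same length as `depth`; 0 at zero depth.
#' @export
#' @examples
#' cg <- channel_geometry("rectangular", width = 2, slope = 0.01, n = 0.015)
#' manning_discharge(cg, 0.5)  # about 3.204 m3/s
manning_discharge <- function(geom, depth) {
  if (!inherits(geom, "channel_geometry")) {
    abort("`geom` must be a channel_geometry.")
  }
  if (any(!is.finite(depth)) || any(depth < 0)) {
    abort("`depth` must be finite and >= 0.")
  }
  if (geom$shape == "circular" && any(depth > geom$diameter)) {
    abort("depth exceeds the pipe diameter: closed conduit is overfull.")
  }
  sg <- section_geometry(geom, depth)
  R <- ifelse(sg$P > 0, sg$A / sg$P, 0)
  Q <- geom$K * sg$A * R^0.667 * sqrt(geom$slope) / geom$n
  Q[depth == 0] <- 0
  Q
}

#' Fit a piecewise-spline stage-discharge rating curve
#'
#' Fits discharge against stage with a piecewise cubic regression spline
#' (least squares on the supplied gaugings). The fitted mapping must be
#' non-decreasing over the gauged stage range; if the fit is not, it is
#' refitted with progressively fewer interior knots (down to a straight
#' line), so the returned rating is always invertible.
#'
#' @param pairs data frame with columns `stage_m` and `discharge_m3s`.
#' @param knots number of interior knots to attempt (placed at stage
#'   quantiles).
#' @return An object of class `rating_curve` with the fitted model, the
#'   valid stage range and residual diagnostics.
#' @export
fit_rating_curve <- function(pairs, knots = 3) {
  if (!is.data.frame(pairs) || !all(c("stage_m", "discharge_m3s") %in% names(pairs))) {
    abort("`pairs` must have columns `stage_m` and `discharge_m3s`.")
  }
  pairs <- pairs[complete.cases(pairs[c("stage_m", "discharge_m3s")]), ]
  h <- pairs$stage_m
  q <- pairs$discharge_m3s
  if (any(h < 0)) abort("stages must be non-negative.")
  if (length(unique(h)) < 2) abort("degenerate rating: all gaugings at one stage.")
  if (nrow(pairs) < 2 * max(knots, 1)) {
    abort(sprintf("need at least %d gaugings for %d knots.", 2 * knots, knots))
  }
  rng <- range(h)
  grid <- seq(rng[1], rng[2], length.out = 512)
  for (k in rev(seq_len(knots + 1)) - 1) {   # knots, knots-1, ..., 0
    fit <- if (k > 0) {
      kn <- unname(quantile(h, probs = seq_len(k) / (k + 1)))
      stats::lm(q ~ splines::bs(h, knots = kn, degree = 3,
                                Boundary.knots = rng))
    } else {
      stats::lm(q ~ h)
    }
    pred <- unname(predict(fit, newdata = data.frame(h = grid)))
    if (all(diff(pred) >= -1e-10)) break
  }
  structure(
    list(
      fit = fit, knots_used = k, stage_range = rng,
      residuals = unname(stats::residuals(fit)),
      sigma = stats::sigma(fit), n = length(h)
    ),
    class = "rating_curve"
  )
}

#' @export
print.rating_curve <- function(x, ...) {
  cat(sprintf(
    "<rating_curve> %d gaugings, %d interior knots, stage %.3f-%.3f m, sigma %.4g\n",
    x$n, x$knots_used, x$stage_range[1], x$stage_range[2], x$sigma
  ))
  invisible(x)
}

#' Predict discharge from stage with a fitted rating curve
#'
#' @param object a [fit_rating_curve()] result.
#' @param stage numeric vector of stages (m).
#' @param ... unused.
#' @return Discharge in m3/s; `NA` outside the fitted stage range
#'   (extrapolation is flagged, never silent).
#' @export
predict.rating_curve <- function(object, stage, ...) {
  out <- rep(NA_real_, length(stage))
  ok <- !is.na(stage) &
    stage >= object$stage_range[1] & stage <= object$stage_range[2]
  if (any(ok)) {
    out[ok] <- pmax(0, unname(predict(object$fit,
                                      newdata = data.frame(h = stage[ok]))))
  }
  out
}

#' Convert a stage series to discharge
#'
#' Applies a rating (either a [rating_curve] or a [channel_geometry] for
#' Manning conversion) element-wise to a regular stage series. Samples
#' outside a rating curve's gauged range are masked in the output gap mask
#' rather than extrapolated.
#'
#' @param stage a [regular_series()] of quantity `"stage"`.
#' @param rating a `rating_curve` or `channel_geometry`.
#' @return A flow [regular_series()] on the same timestamps.
#' @export
apply_rating <- function(stage, rating) {
  assert_series(stage, "stage")
  v <- stage$value
  q <- rep(NA_real_, length(v))
  ok <- !stage$gap
  if (inherits(rating, "rating_curve")) {
    q[ok] <- predict(rating, v[ok])
  } else if (inherits(rating, "channel_geometry")) {
    q[ok] <- manning_discharge(rating, v[ok])
  } else {
    abort("`rating` must be a rating_curve or channel_geometry.")
  }
  regular_series(stage$timestamp, q,
    gap = stage$gap | is.na(q),
    quantity = "flow", step_min = series_step_min(stage)
  )
}

#' @export
tidy.rating_curve <- function(x, ...) {
  tibble::tibble(
    term = names(coef(x$fit)),
    estimate = unname(coef(x$fit))
  )
}

#' @export
glance.rating_curve <- function(x, ...) {
  tibble::tibble(
    n = x$n, knots = x$knots_used, sigma = x$sigma,
    stage_min = x$stage_range[1], stage_max = x$stage_range[2],
    r.squared = summary(x$fit)$r.squared
  )
}
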