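#' Regular hydrological time series
#'
#' A `regular_series` is a tibble with columns `timestamp` (POSIXct, UTC),
#' `value` and `gap` (logical mask for missing bins), constrained to a
#' strictly regular time step. It is the common currency of the pipeline:
#' rainfall is stored as depth per step (mm) and flow as a rate (m3/s).
#'
#' @param timestamp POSIXct vector (UTC), strictly increasing at a constant
#'   step.
#' @param value numeric vector, same length; non-negative at unmasked samples.
#' @param gap logical mask; `TRUE` marks bins with no usable data. Defaults
#'   to `is.na(value)`.
#' @param quantity `"rain"` or `"flow"`.
#' @param units unit string, e.g. `"mm/15min"` or `"m3/s"`.
#' @param step_min step length in minutes.
#'
#' @return A tibble of class `regular_series`.
#' @export
regular_series <- function(timestamp, value, gap = NULL,
                           quantity = c("flow", "rain", "stage"),
                           units = NULL, step_min = 15) {
  quantity <- match.arg(quantity)
  if (is.null(units)) {
    units <- switch(quantity,
      rain = sprintf("mm/%dmin", step_min),
      flow = "m3/s", stage = "m"
    )
  }
  if (length(timestamp) != length(value)) {
    abort("`timestamp` and `value` must have the same length.")
  }
  if (length(timestamp) == 0) abort("empty series.")
  if (is.null(gap)) gap <- is.na(value)
  gap <- gap | is.na(value)
  ts <- as.POSIXct(timestamp, tz = "UTC")
  if (length(ts) > 1) {
    d <- as.numeric(diff(ts), units = "mins")
    if (any(abs(d - step_min) > 1e-6)) {
      abort(sprintf("timestamps must advance by exactly %g minutes.", step_min))
    }
  }
  if (any(value[!gap] < 0, na.rm = TRUE)) {
    abort("unmasked values must be non-negative.")
  }
  out <- tibble::tibble(timestamp = ts, value = as.numeric(value), gap = gap)
  out$value[out$gap] <- NA_real_
  structure(out,
    class = c("regular_series", class(out)),
    quantity = quantity, units = units, step_min = step_min
  )
}

series_quantity <- function(x) attr(x, "quantity")
series_units <- function(x) attr(x, "units")
series_step_min <- function(x) attr(x, "step_min")

assert_series <- function(x, quantity = NULL, arg = deparse(substitute(x))) {
  if (!inherits(x, "regular_series")) {
    abort(sprintf("`%s` must be a regular_series (see `regularize()`).", arg))
  }
  if (!is.null(quantity) && !identical(series_quantity(x), quantity)) {
    abort(sprintf(
      "`%s` must carry quantity '%s', got '%s' (unit mismatch).",
      arg, quantity, series_quantity(x)
    ))
  }
  invisible(x)
}

#' Regularize a raw timestamped series onto a fixed grid
#'
#' Bins raw observations into a regular grid (15 min by default). Rainfall
#' depths are summed into each bin (so e.g. 5-min radar depths aggregate to
#' depth per 15 min); flow and stage rates are averaged. Bins spanned by the
#' record but containing no observations are masked as gaps.
#'
#' @param x a data frame with columns `timestamp` and `value` (any sortable
#'   timestamp representation accepted by [as.POSIXct()]).
#' @param quantity `"rain"` (depths, summed) or `"flow"`/`"stage"` (rates,
#'   averaged).
#' @param step_min target step in minutes (default 15).
#' @return A [regular_series()] tibble covering the record span.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   timestamp = as.POSIXct("2018-01-01 00:00", tz = "UTC") + c(0, 300, 600),
#'   value = c(1, 2, 3)
#' )
#' regularize(raw, "rain")  # one 15-min bin holding 6 mm
regularize <- function(x, quantity = c("flow", "rain", "stage"),
                       step_min = 15) {
  quantity <- match.arg(quantity)
  if (!is.data.frame(x) || !all(c("timestamp", "value") %in% names(x))) {
    abort("`x` must be a data frame with `timestamp` and `value` columns.")
  }
  if (nrow(x) == 0) abort("empty input series.")
  ts <- as.POSIXct(x$timestamp, tz = "UTC")
  if (anyNA(ts)) abort("unparseable timestamps in input.")
  ord <- order(ts)
  ts <- ts[ord]
  v <- as.numeric(x$value)[ord]
  step_s <- step_min * 60
  bin <- floor(as.numeric(ts) / step_s) * step_s
  agg <- tibble::tibble(bin = bin, value = v) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      value = if (quantity == "rain") sum(.data$value) else mean(.data$value),
      .groups = "drop"
    )
  grid <- seq(min(bin), max(bin), by = step_s)
  full <- tibble::tibble(bin = grid) |> dplyr::left_join(agg, by = "bin")
  regular_series(
    timestamp = as.POSIXct(full$bin, tz = "UTC", origin = "1970-01-01"),
    value = full$value, quantity = quantity, step_min = step_min
  )
}

#' Read / write series CSV
#'
#' Series are exchanged as two-column CSV files with an ISO-8601 UTC
#' `timestamp` column and a `value` column.
#'
#' @param path file path.
#' @param quantity,step_min passed to [regularize()].
#' @return `read_series_csv()` returns a [regular_series()];
#'   `write_series_csv()` returns `path` invisibly.
#' @export
read_series_csv <- function(path, quantity = c("flow", "rain", "stage"),
                            step_min = 15) {
  quantity <- match.arg(quantity)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("timestamp", "value") %in% names(raw))) {
    abort(sprintf("'%s' must have 'timestamp' and 'value' columns.", path))
  }
  regularize(raw, quantity = quantity, step_min = step_min)
}

#' @param x a [regular_series()].
#' @rdname read_series_csv
#' @export
write_series_csv <- function(x, path) {
  assert_series(x)
  out <- tibble::tibble(
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    value = x$value
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
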