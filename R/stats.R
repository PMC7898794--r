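#' Mann-Whitney U test (rank-sum, normal approximation)
#'
#' Two-sided Mann-Whitney U with midrank tie handling, tie-corrected normal
#' approximation and continuity correction. `U` is oriented to the first
#' sample: `U = (number of (x, y) pairs with x > y) + half the ties`, so
#' complete separation with every `x` below every `y` gives `U = 0`.
#' When every value in both samples is identical the test is degenerate and
#' `p = 1` is returned by convention.
#'
#' @param x,y numeric samples (non-empty).
#' @return A one-row tibble with `u`, `p_value`, `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  if (length(unique(c(x, y))) == 1L) {
    return(tibble::tibble(
      u = length(x) * length(y) / 2, p_value = 1,
      n_x = length(x), n_y = length(y)
    ))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE, alternative = "two.sided")
  )
  tibble::tibble(
    u = unname(wt$statistic), p_value = wt$p.value,
    n_x = length(x), n_y = length(y)
  )
}

#' Summarise events before and after impact
#'
#' Per site and metric (event rainfall, total stormflow, peak Q, lag):
#' group sizes, medians and interquartile ranges for the before and after
#' beaver levels, with a Mann-Whitney p value for the before/after
#' difference. Flagged events (gap-affected, unpaired or manually excluded)
#' are dropped unless `include_flagged = TRUE`.
#'
#' @param events a labelled event table (see [label_events()]).
#' @param include_flagged keep flagged events (default FALSE).
#' @return A tibble: one row per site x metric with `n_before`, `n_after`,
#'   `median_before`, `iqr_before`, `median_after`, `iqr_after`, `p_value`.
#' @export
summarize_events <- function(events, include_flagged = FALSE) {
  ev <- analysis_events(events, include_flagged)
  if (!"beaver" %in% names(ev)) abort("events must be labelled first (label_events).")
  metrics <- c(
    rain_mm = "rain_mm", stormflow_m3 = "stormflow_m3",
    peak_q = "peak_q", lag_h = "lag_h"
  )
  purrr::map_dfr(unique(ev$site), function(s) {
    es <- ev[ev$site == s, ]
    purrr::map_dfr(names(metrics), function(m) {
      b <- es[[m]][es$beaver == "before"]
      a <- es[[m]][es$beaver == "after"]
      b <- b[!is.na(b)]
      a <- a[!is.na(a)]
      p <- if (length(b) >= 2 && length(a) >= 2) {
        mann_whitney_u(b, a)$p_value
      } else {
        warn(sprintf("site %s, metric %s: a group has n < 2; test skipped.", s, m))
        NA_real_
      }
      tibble::tibble(
        site = s, metric = m,
        n_before = length(b), n_after = length(a),
        median_before = median(b), iqr_before = IQR(b),
        median_after = median(a), iqr_after = IQR(a),
        p_value = p
      )
    })
  })
}

analysis_events <- function(events, include_flagged = FALSE) {
  ev <- tibble::as_tibble(events)
  if (!include_flagged) {
    drop <- (ev$gap_affected %||% FALSE) | (ev$unpaired %||% FALSE) |
      (ev$excluded %||% FALSE)
    ev <- ev[!drop, , drop = FALSE]
  }
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Q5:Q95 flashiness index before and after a split date
#'
#' `Q5` is the flow exceeded 5% of the time (the 95th percentile of the
#' record) and `Q95` the flow exceeded 95% of the time; their ratio is a
#' simple flashiness index -- higher means a flashier regime. Computed
#' separately for the record before and at/after `split`.
#'
#' @param flow a flow [regular_series()] spanning the split.
#' @param split POSIXct (or parseable) split timestamp.
#' @return A tibble with one row per period: `period`, `n`, `q5`, `q95`,
#'   `ratio` and `undefined` (TRUE with `ratio = Inf` when `Q95` is zero).
#' @export
flashiness_ratio <- function(flow, split) {
  assert_series(flow, "flow")
  split <- as.POSIXct(split, tz = "UTC")
  if (split <= min(flow$timestamp) || split > max(flow$timestamp)) {
    abort("`split` must fall inside the flow record.")
  }
  purrr::map_dfr(c("before", "after"), function(per) {
    sel <- if (per == "before") flow$timestamp < split else flow$timestamp >= split
    v <- flow$value[sel & !flow$gap]
    q5 <- unname(quantile(v, 0.95, na.rm = TRUE))
    q95 <- unname(quantile(v, 0.05, na.rm = TRUE))
    undef <- q95 <= 0
    tibble::tibble(
      period = per, n = length(v), q5 = q5, q95 = q95,
      ratio = if (undef) Inf else q5 / q95, undefined = undef
    )
  })
}

#' Subset events whose peaks exceed the Q5 exceedance flow
#'
#' Keeps the largest monitored events: those whose peak discharge exceeds
#' the Q5 flow (exceeded 5% of the time) of the site's flow record. By
#' default the threshold is computed from the full combined record (both
#' periods), so it is period-neutral; `period = "before"` restricts the
#' threshold computation to the pre-impact record.
#'
#' @param events a labelled event table.
#' @param flow a flow [regular_series()], or a named list of them keyed by
#'   site when `events` spans several sites.
#' @param prob exceedance quantile on the flow record (default 0.95, i.e.
#'   Q5).
#' @param period `"combined"` (default) or `"before"`.
#' @param design required when `period = "before"`: a [study_design()]
#'   providing impact dates.
#' @return The filtered event table, with the threshold(s) in attribute
#'   `"q5_threshold"`. Warns when the subset is empty.
#' @export
q5_subset <- function(events, flow, prob = 0.95, period = c("combined", "before"),
                      design = NULL) {
  period <- match.arg(period)
  flows <- if (inherits(flow, "regular_series")) {
    sites <- unique(events$site)
    if (length(sites) > 1) abort("multiple sites: supply `flow` as a named list.")
    setNames(list(flow), sites)
  } else {
    flow
  }
  thr <- purrr::imap_dbl(flows, function(f, s) {
    assert_series(f, "flow")
    v <- f$value[!f$gap]
    if (period == "before") {
      if (is.null(design)) abort("`design` needed for period = 'before'.")
      d0 <- design$sites$impact_date[design$sites$site == s]
      v <- f$value[!f$gap & f$timestamp < d0]
    }
    unname(quantile(v, prob, na.rm = TRUE))
  })
  keep <- events$peak_q > thr[events$site]
  out <- events[which(keep), , drop = FALSE]
  if (nrow(out) == 0) warn("Q5 subset is empty; downstream models will be skipped.")
  attr(out, "q5_threshold") <- thr
  class(out) <- unique(c("event_table", class(out)))
  out
}
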