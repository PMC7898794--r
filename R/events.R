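#' Event-extraction parameters
#'
#' Thresholds for identifying rainfall bursts, quickflow responses and the
#' pairing of the two into storm-event windows.
#'
#' @param dry_gap_h dry spells shorter than this (hours) are bridged when
#'   delimiting a continuous-rainfall period (default 6).
#' @param min_rain_mm rainfall periods with less total depth are discarded
#'   (default 1).
#' @param quick_frac a flow response requires quickflow to exceed this
#'   fraction of the concurrent slowflow (default 1: quick flow exceeds
#'   slow flow).
#' @param quick_floor_m3s absolute quickflow floor for a response (default
#'   0.001 m3/s), guarding against responses declared on numerical dust.
#' @param lead_h maximum time from the start of a rainfall period to the
#'   start of its flow response (default 24 h).
#' @return A list of class `event_params`.
#' @export
event_params <- function(dry_gap_h = 6, min_rain_mm = 1, quick_frac = 1,
                         quick_floor_m3s = 0.001, lead_h = 24) {
  stopifnot(
    dry_gap_h >= 0, min_rain_mm >= 0, quick_floor_m3s >= 0, lead_h >= 0,
    quick_frac >= 0, quick_frac <= 2
  )
  structure(
    list(
      dry_gap_h = dry_gap_h, min_rain_mm = min_rain_mm,
      quick_frac = quick_frac, quick_floor_m3s = quick_floor_m3s,
      lead_h = lead_h
    ),
    class = "event_params"
  )
}

# maximal runs of a logical vector, as a tibble of start/end indices
runs_of <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values) & r$values
  tibble::tibble(start_idx = starts[keep], end_idx = ends[keep])
}

#' Identify continuous-rainfall periods
#'
#' Finds maximal intervals of positive rainfall, bridging internal dry
#' spells shorter than the configured dry gap, and discards intervals whose
#' total depth is below the minimum event rainfall.
#'
#' @param rain a rain [regular_series()] (mm per step).
#' @param params an [event_params()].
#' @return A tibble with one row per rainfall period: `start_idx`,
#'   `end_idx` (inclusive sample indices), `start`, `end` (half-open
#'   `[start, end)` timestamps) and `total_mm`.
#' @export
detect_rainfall_periods <- function(rain, params = event_params()) {
  assert_series(rain, "rain")
  step <- series_step_min(rain)
  gap_samp <- floor(params$dry_gap_h * 60 / step)
  wet <- !rain$gap & rain$value > 0
  iv <- runs_of(wet)
  if (nrow(iv) > 1 && gap_samp > 0) {
    # bridge dry gaps strictly shorter than the threshold
    merged <- list(c(iv$start_idx[1], iv$end_idx[1]))
    for (i in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv$start_idx[i] - last[2] - 1L < gap_samp) {
        merged[[length(merged)]] <- c(last[1], iv$end_idx[i])
      } else {
        merged[[length(merged) + 1L]] <- c(iv$start_idx[i], iv$end_idx[i])
      }
    }
    iv <- tibble::tibble(
      start_idx = vapply(merged, `[`, integer(1), 1),
      end_idx = vapply(merged, `[`, integer(1), 2)
    )
  }
  if (nrow(iv) == 0) {
    return(tibble::tibble(
      start_idx = integer(), end_idx = integer(),
      start = rain$timestamp[0], end = rain$timestamp[0], total_mm = numeric()
    ))
  }
  iv$total_mm <- purrr::map2_dbl(
    iv$start_idx, iv$end_idx,
    ~ sum(rain$value[.x:.y], na.rm = TRUE)
  )
  iv <- iv[iv$total_mm >= params$min_rain_mm, , drop = FALSE]
  iv$start <- rain$timestamp[iv$start_idx]
  iv$end <- rain$timestamp[iv$end_idx] + series_step_min(rain) * 60
  iv[c("start_idx", "end_idx", "start", "end", "total_mm")]
}

#' Identify quickflow responses
#'
#' Finds maximal intervals where quickflow exceeds the response criterion
#' `max(quick_frac * slowflow, quick_floor_m3s)`; each interval runs until
#' quickflow falls back below the criterion (the recession end).
#'
#' @param base a [separate_baseflow()] result.
#' @param params an [event_params()].
#' @return A tibble of intervals (`start_idx`, `end_idx`, `start`, `end`,
#'   `peak_quick`).
#' @export
detect_flow_responses <- function(base, params = event_params()) {
  if (!inherits(base, "baseflow_result")) {
    abort("`base` must come from separate_baseflow().")
  }
  crit <- !base$gap &
    base$quickflow > pmax(params$quick_frac * base$slowflow,
                          params$quick_floor_m3s)
  iv <- runs_of(crit)
  iv$peak_quick <- purrr::map2_dbl(
    iv$start_idx, iv$end_idx,
    ~ max(base$quickflow[.x:.y])
  )
  iv$start <- base$timestamp[iv$start_idx]
  iv$end <- base$timestamp[iv$end_idx] + attr(base, "step_min") * 60
  iv[c("start_idx", "end_idx", "start", "end", "peak_quick")]
}

#' Pair rainfall periods with flow responses into event windows
#'
#' Each rainfall period is paired with the first flow response that overlaps
#' it or starts within the maximum lead time of its start. The event window
#' is the union span: rainfall start to flow recession end. Rainfall periods
#' sharing one flow response are merged into a single event (so total
#' stormflow stays well-defined); rainfall with no response is dropped, and
#' flow responses never matched to rain are returned flagged as candidate
#' misidentifications.
#'
#' @param rain_iv,flow_iv interval tibbles from [detect_rainfall_periods()]
#'   and [detect_flow_responses()], sorted by start.
#' @param params an [event_params()].
#' @return A tibble of windows: `start_idx`, `end_idx`, `start`, `end`,
#'   `n_rain_periods` and `unpaired_flow` (TRUE rows are flow responses with
#'   no rainfall driver).
#' @export
pair_events <- function(rain_iv, flow_iv, params = event_params()) {
  empty <- tibble::tibble(
    start_idx = integer(), end_idx = integer(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    n_rain_periods = integer(), unpaired_flow = logical()
  )
  if (nrow(flow_iv) == 0) return(empty)
  lead_s <- params$lead_h * 3600
  # qualification edges: a flow response belongs to a rainfall period when
  # the two overlap or the response starts within the lead time of the
  # rainfall start; connected components of this graph become events, so a
  # rain period followed by several response pulses spans to the last
  # recession end and rain periods sharing a response merge
  comp_rain <- seq_len(nrow(rain_iv))
  comp_flow <- rep(NA_integer_, nrow(flow_iv))
  for (i in seq_len(nrow(rain_iv))) {
    qual <- which(
      (flow_iv$start < rain_iv$end[i] & flow_iv$end > rain_iv$start[i]) |
        (flow_iv$start >= rain_iv$start[i] &
           as.numeric(flow_iv$start) - as.numeric(rain_iv$start[i]) <= lead_s)
    )
    for (j in qual) {
      if (is.na(comp_flow[j])) {
        comp_flow[j] <- comp_rain[i]
      } else if (comp_flow[j] != comp_rain[i]) {
        # this flow response was already claimed: merge the two components
        old <- comp_rain[i]
        new <- comp_flow[j]
        comp_rain[comp_rain == old] <- new
        comp_flow[comp_flow == old & !is.na(comp_flow)] <- new
      }
    }
  }
  wins <- empty
  used <- !is.na(comp_flow)
  active <- unique(comp_flow[used])
  if (length(active)) {
    na <- length(active)
    w_i0 <- w_i1 <- nper <- integer(na)
    w_t0 <- w_t1 <- numeric(na)
    for (m in seq_len(na)) {
      k <- active[m]
      ri <- which(comp_rain == k)
      fi <- which(comp_flow == k & used)
      w_i0[m] <- min(rain_iv$start_idx[ri], flow_iv$start_idx[fi])
      w_i1[m] <- max(flow_iv$end_idx[fi])
      w_t0[m] <- min(as.numeric(rain_iv$start[ri]), as.numeric(flow_iv$start[fi]))
      w_t1[m] <- max(as.numeric(flow_iv$end[fi]))
      nper[m] <- length(ri)
    }
    wins <- tibble::tibble(
      start_idx = w_i0, end_idx = w_i1,
      start = as.POSIXct(w_t0, tz = "UTC", origin = "1970-01-01"),
      end = as.POSIXct(w_t1, tz = "UTC", origin = "1970-01-01"),
      n_rain_periods = nper, unpaired_flow = FALSE
    ) |> dplyr::arrange(.data$start)
    # rain falling during a previous event's recession may pair with the
    # next flow response; clip such windows so events stay pairwise disjoint
    if (nrow(wins) > 1) {
      for (i in 2:nrow(wins)) {
        if (wins$start[i] < wins$end[i - 1]) {
          wins$start[i] <- wins$end[i - 1]
          wins$start_idx[i] <- wins$end_idx[i - 1] + 1L
        }
      }
    }
  }
  if (any(!used)) {
    wins <- dplyr::bind_rows(
      wins,
      tibble::tibble(
        start_idx = flow_iv$start_idx[!used],
        end_idx = flow_iv$end_idx[!used],
        start = flow_iv$start[!used],
        end = flow_iv$end[!used],
        n_rain_periods = 0L, unpaired_flow = TRUE
      )
    ) |> dplyr::arrange(.data$start)
  }
  wins
}

#' Compute metrics for one event window
#'
#' Over the half-open window `[start, end)`: total event rainfall `ER` is
#' the sum of rain depths; total stormflow is the quickflow volume (sum of
#' quickflow times the 900-s step); peak Q is the maximum *measured* flow
#' (cleaning never touches event peaks); the peak-to-peak lag is the time
#' from the maximum 15-min rainfall depth to the maximum flow, in hours.
#' Ties take the earliest timestamp.
#'
#' @param window one row of the [pair_events()] output (list or tibble row).
#' @param rain the rain [regular_series()].
#' @param base the [separate_baseflow()] result (carries measured flow).
#' @return A one-row tibble of event metrics.
#' @export
compute_event_metrics <- function(window, rain, base) {
  event_metrics_all(window[1, , drop = FALSE], rain, base)
}

# vectorised metric computation over all windows (hot path: plain loops
# filling preallocated vectors, one tibble at the end)
event_metrics_all <- function(wins, rain, base) {
  step_s <- series_step_min(rain) * 60
  rv_all <- rain$value
  fv_all <- base$flow
  qf_all <- base$quickflow
  gap_all <- rain$gap | base$gap
  m <- nrow(wins)
  rain_mm <- storm_m3 <- peak_q <- numeric(m)
  t_pq <- t_pr <- rep(NA_real_, m)
  gapped <- logical(m)
  for (i in seq_len(m)) {
    idx <- wins$start_idx[i]:wins$end_idx[i]
    rv <- rv_all[idx]
    fv <- fv_all[idx]
    gapped[i] <- anyNA(gap_all[idx]) || any(gap_all[idx])
    rain_mm[i] <- sum(rv, na.rm = TRUE)
    storm_m3[i] <- sum(pmax(qf_all[idx], 0), na.rm = TRUE) * step_s
    if (all(is.na(fv))) {
      peak_q[i] <- NA_real_
    } else {
      pk <- which.max(fv)                       # earliest tie wins
      peak_q[i] <- fv[pk]
      t_pq[i] <- as.numeric(base$timestamp[idx[pk]])
    }
    if (!all(is.na(rv)) && max(rv, na.rm = TRUE) > 0) {
      t_pr[i] <- as.numeric(rain$timestamp[idx[which.max(rv)]])
    }
  }
  tibble::tibble(
    start = wins$start, end = wins$end,
    rain_mm = rain_mm, stormflow_m3 = storm_m3, peak_q = peak_q,
    t_peak_q = as.POSIXct(t_pq, tz = "UTC", origin = "1970-01-01"),
    t_peak_rain = as.POSIXct(t_pr, tz = "UTC", origin = "1970-01-01"),
    lag_h = (t_pq - t_pr) / 3600,
    gap_affected = gapped
  )
}

#' Extract the storm-event table for one site
#'
#' Orchestrates rainfall-period detection, flow-response detection, pairing
#' and per-event metrics, then applies a file-driven exclusion list (events
#' are flagged, never deleted). Windows flagged as unpaired flow responses
#' are retained with `unpaired = TRUE` as candidate misidentifications.
#'
#' @param base a [separate_baseflow()] result for the site.
#' @param rain the site's rain [regular_series()] on the same timestamps.
#' @param params an [event_params()].
#' @param site site identifier stored in the table.
#' @param exclusions optional data frame of manual exclusions: either
#'   columns (`site`, `event_id`) or (`site`, `start`, `end`) time ranges.
#' @return An `event_table` tibble, one row per event, with metric columns
#'   and flags (`gap_affected`, `unpaired`, `excluded`).
#' @export
extract_events <- function(base, rain, params = event_params(),
                           site = "site", exclusions = NULL) {
  if (!inherits(base, "baseflow_result")) {
    abort("`base` must come from separate_baseflow().")
  }
  assert_series(rain, "rain")
  if (nrow(base) != nrow(rain) ||
      !isTRUE(all.equal(as.numeric(base$timestamp), as.numeric(rain$timestamp)))) {
    abort("`base` and `rain` must share identical timestamps.")
  }
  rain_iv <- detect_rainfall_periods(rain, params)
  flow_iv <- detect_flow_responses(base, params)
  wins <- pair_events(rain_iv, flow_iv, params)
  if (nrow(wins) == 0) {
    return(event_table_skeleton(site))
  }
  ev <- event_metrics_all(wins, rain, base)
  ev <- dplyr::bind_cols(
    tibble::tibble(
      site = site,
      event_id = sprintf("%s-%04d", site, seq_len(nrow(wins)))
    ),
    ev,
    tibble::tibble(
      n_rain_periods = wins$n_rain_periods,
      unpaired = wins$unpaired_flow
    )
  )
  ev$excluded <- apply_exclusions(ev, exclusions)
  survivors <- ev[!ev$excluded & !ev$unpaired, , drop = FALSE]
  if (nrow(survivors) > 1) {
    overl <- survivors$start[-1] < survivors$end[-nrow(survivors)]
    if (any(overl)) {
      abort(paste0(
        "surviving event windows overlap (first at ",
        format(survivors$start[-1][overl][1]),
        "); event parameters are likely misconfigured."
      ))
    }
  }
  structure(ev, class = c("event_table", class(ev)))
}

event_table_skeleton <- function(site = character()) {
  structure(
    tibble::tibble(
      site = character(), event_id = character(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"),
      rain_mm = numeric(), stormflow_m3 = numeric(), peak_q = numeric(),
      t_peak_q = as.POSIXct(character(), tz = "UTC"),
      t_peak_rain = as.POSIXct(character(), tz = "UTC"),
      lag_h = numeric(), gap_affected = logical(),
      n_rain_periods = integer(), unpaired = logical(), excluded = logical()
    ),
    class = c("event_table", "tbl_df", "tbl", "data.frame")
  )
}

apply_exclusions <- function(ev, exclusions) {
  excluded <- rep(FALSE, nrow(ev))
  if (is.null(exclusions) || nrow(exclusions) == 0) return(excluded)
  ex <- exclusions[is.na(exclusions$site) | exclusions$site %in% ev$site, ,
                   drop = FALSE]
  if ("event_id" %in% names(ex)) {
    excluded <- excluded | ev$event_id %in% ex$event_id
  }
  if (all(c("start", "end") %in% names(ex))) {
    for (i in seq_len(nrow(ex))) {
      if (is.na(ex$start[i]) || is.na(ex$end[i])) next
      excluded <- excluded |
        (ev$start < as.POSIXct(ex$end[i], tz = "UTC") &
           ev$end > as.POSIXct(ex$start[i], tz = "UTC"))
    }
  }
  excluded
}
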