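test_that("rainfall periods bridge short dry gaps and honour the depth floor", {
  expect_equal(nrow(detect_rainfall_periods(make_rain(rep(0, 100)))), 0)

  # two 1-h bursts, 8 h apart: stays two periods with a 6-h gap parameter
  r <- rep(0, 200)
  r[10:13] <- 1
  r[10 + 4 + 32 + 0:3] <- 1     # 8 h = 32 steps of dry between bursts
  two <- detect_rainfall_periods(make_rain(r))
  expect_equal(nrow(two), 2)
  expect_equal(two$start_idx, c(10, 46))
  expect_equal(two$total_mm, c(4, 4))

  # the same bursts 3 h apart merge into one period
  r2 <- rep(0, 200)
  r2[10:13] <- 1
  r2[10 + 4 + 12 + 0:3] <- 1
  one <- detect_rainfall_periods(make_rain(r2))
  expect_equal(nrow(one), 1)
  expect_equal(one$start_idx, 10)
  expect_equal(one$end_idx, 29)

  # sub-threshold drizzle is discarded
  r3 <- rep(0, 100)
  r3[50] <- 0.4
  expect_equal(nrow(detect_rainfall_periods(make_rain(r3))), 0)
})

test_that("flow responses start and end exactly where the criterion crosses", {
  expect_equal(nrow(detect_flow_responses(
    separate_baseflow(make_flow(rep(0.2, 200)))
  )), 0)

  # hand-built baseflow result with known quick/slow crossings
  n <- 120
  bf <- structure(
    tibble::tibble(
      timestamp = as.POSIXct("2018-01-01", tz = "UTC") + (0:(n - 1)) * 900,
      flow = 0.1, slowflow = rep(0.05, n), quickflow = rep(0, n),
      gap = FALSE
    ),
    class = c("baseflow_result", "tbl_df", "tbl", "data.frame"),
    alpha = 0.925, passes = 3L, reflect = 30L, step_min = 15
  )
  bf$quickflow[40:55] <- 0.2     # exceeds slowflow over a known run
  bf$quickflow[80:85] <- 0.2     # second response after full recession
  iv <- detect_flow_responses(bf)
  expect_equal(iv$start_idx, c(40, 80))
  expect_equal(iv$end_idx, c(55, 85))
})

test_that("pairing follows overlap and lead-time rules and merges shared responses", {
  t0 <- as.POSIXct("2018-01-01", tz = "UTC")
  p <- event_params()
  rain_iv <- tibble::tibble(
    start_idx = 10L, end_idx = 13L,
    start = t0 + 10 * 900, end = t0 + 14 * 900, total_mm = 4
  )
  flow_iv <- tibble::tibble(
    start_idx = 12L, end_idx = 40L,
    start = t0 + 12 * 900, end = t0 + 41 * 900, peak_quick = 0.5
  )
  w <- pair_events(rain_iv, flow_iv, p)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, rain_iv$start)
  expect_equal(w$end, flow_iv$end)
  expect_false(w$unpaired_flow)

  # response starting beyond the lead time: rain dropped, flow flagged
  flow_late <- dplyr::mutate(flow_iv,
    start = t0 + 30 * 3600, end = t0 + 36 * 3600,
    start_idx = 120L, end_idx = 144L
  )
  w2 <- pair_events(rain_iv, flow_late, p)
  expect_equal(nrow(w2), 1)
  expect_true(w2$unpaired_flow)

  # two rainfall periods feeding one long response merge into one event
  rain2 <- dplyr::bind_rows(
    rain_iv,
    dplyr::mutate(rain_iv,
      start_idx = 20L, end_idx = 23L,
      start = t0 + 20 * 900, end = t0 + 24 * 900
    )
  )
  w3 <- pair_events(rain2, flow_iv, p)
  expect_equal(nrow(w3), 1)
  expect_equal(w3$n_rain_periods, 2L)
  expect_equal(w3$start, rain_iv$start)
})

test_that("event metrics match hand calculation", {
  t0 <- as.POSIXct("2018-01-01 00:00", tz = "UTC")
  n <- 40
  rain <- make_rain(c(rep(0, 8), 1, 2, 3, 0.5, rep(0, n - 12)))
  qf <- rep(0, n)
  qf[9:16] <- 1                                 # 2 h of 1 m3/s quickflow
  flow <- 0.1 + qf
  flow[19] <- 2.5                                # peak at 04:30
  bf <- structure(
    tibble::tibble(
      timestamp = t0 + (0:(n - 1)) * 900, flow = flow,
      slowflow = flow - qf, quickflow = qf, gap = FALSE
    ),
    class = c("baseflow_result", "tbl_df", "tbl", "data.frame"),
    alpha = 0.925, passes = 3L, reflect = 30L, step_min = 15
  )
  window <- tibble::tibble(start_idx = 1L, end_idx = n,
                           start = t0, end = t0 + n * 900)
  m <- compute_event_metrics(window, rain, bf)
  expect_equal(m$rain_mm, 6.5)
  expect_equal(m$stormflow_m3, 8 * 900)
  expect_equal(m$peak_q, 2.5)
  # rain peak bin at 02:30, flow maximum at 04:30: lag 2 h
  expect_equal(m$lag_h, 2)
  expect_false(m$gap_affected)
})

test_that("a noise-free simulated year is recovered storm for storm", {
  cfg <- synthetic_config(
    years = 1, seed = 99, noise_cv = 0,
    storm_rate_per_day = 40 / 365, attenuation = 1, lag_shift_h = 0
  )
  st <- generate_study(cfg)
  permissive <- event_params(min_rain_mm = 0.5, quick_frac = 0.1,
                             quick_floor_m3s = 1e-5)
  ev <- pipeline_site(st$flow$impact, st$rain$impact, "impact",
                      clean = FALSE, params = permissive)
  ok <- !ev$unpaired & !ev$excluded
  tr <- st$truth$impact[st$truth$impact$depth_mm >= 1, ]
  # every generated storm of at least 1 mm lies inside exactly one window
  hits <- vapply(seq_len(nrow(tr)), function(i) {
    sum(tr$t_peak_flow[i] >= ev$start[ok] & tr$t_peak_flow[i] < ev$end[ok])
  }, numeric(1))
  expect_true(all(hits == 1))
  # windows holding a single storm reproduce its peak exactly and its lag
  # to within one 15-min step
  for (j in which(ok)) {
    in_win <- tr$t_peak_flow >= ev$start[j] & tr$t_peak_flow < ev$end[j]
    if (sum(in_win) != 1) next
    expect_equal(ev$peak_q[j], tr$peak_flow[in_win], tolerance = 1e-12)
    expect_lte(abs(ev$lag_h[j] - tr$lag_true_h[in_win]), 0.25)
  }
})

test_that("exclusions flag events without deleting them", {
  cfg <- synthetic_config(years = 1, seed = 99, noise_cv = 0,
                          storm_rate_per_day = 40 / 365,
                          attenuation = 1, lag_shift_h = 0)
  st <- generate_study(cfg)
  flow <- st$flow$impact
  bf <- separate_baseflow(flow)
  bf$flow <- flow$value
  ev0 <- extract_events(bf, st$rain$impact, site = "impact")
  excl <- data.frame(site = "impact", event_id = ev0$event_id[1:2])
  ev <- extract_events(bf, st$rain$impact, site = "impact", exclusions = excl)
  expect_equal(nrow(ev), nrow(ev0))
  expect_equal(sum(ev$excluded), 2)
  expect_equal(sum(!ev$excluded), nrow(ev0) - 2)
})

test_that("surviving event windows are pairwise disjoint and rain-driven", {
  cfg <- synthetic_config(years = 1, seed = 13)
  st <- generate_study(cfg)
  ev <- pipeline_site(st$flow$impact, st$rain$impact, "impact")
  keep <- ev[!ev$unpaired & !ev$excluded, ]
  keep <- keep[order(keep$start), ]
  expect_true(all(keep$start[-1] >= keep$end[-nrow(keep)]))
  expect_true(all(keep$rain_mm > 0))
})
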