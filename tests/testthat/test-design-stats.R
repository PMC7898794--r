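design_fixture <- function() {
  study_design(tibble::tibble(
    site = c("imp", "ctl"),
    role = c("impact", "control"),
    impact_date = c("2018-06-01", NA),
    paired_with = c(NA, "imp")
  ))
}

event_row <- function(site, start) {
  tibble::tibble(
    site = site, event_id = paste0(site, "-", format(start, "%m%d%H")),
    start = start, end = start + 3600 * 6,
    rain_mm = 5, stormflow_m3 = 100, peak_q = 0.2,
    t_peak_q = start + 3600, t_peak_rain = start,
    lag_h = 1, gap_affected = FALSE, n_rain_periods = 1L,
    unpaired = FALSE, excluded = FALSE
  )
}

test_that("season, period and hydrological year labels follow the calendar rules", {
  d <- design_fixture()
  t <- function(s) as.POSIXct(s, tz = "UTC")
  ev <- dplyr::bind_rows(
    event_row("imp", t("2017-12-15 06:00")),  # wet season, before
    event_row("imp", t("2018-04-01 00:00")),  # dry season boundary, before
    event_row("imp", t("2018-06-01 00:00")),  # impact date: after
    event_row("imp", t("2018-10-02 12:00")),  # hydrological year 2019
    event_row("ctl", t("2018-07-01 00:00"))   # control inherits the date
  )
  lab <- label_events(ev, d)
  expect_equal(as.character(lab$season),
               c("wet", "dry", "dry", "wet", "dry"))
  expect_equal(as.character(lab$beaver),
               c("before", "before", "after", "after", "after"))
  expect_equal(lab$hyd_year, c(2018, 2018, 2018, 2019, 2018))
  expect_equal(as.character(lab$role),
               c(rep("impact", 4), "control"))
})

test_that("design validation catches missing dates and partners", {
  expect_error(
    study_design(tibble::tibble(site = "a", role = "impact")),
    "impact_date"
  )
  expect_error(
    study_design(tibble::tibble(site = "c", role = "control",
                                impact_date = NA)),
    "paired_with"
  )
})

test_that("Mann-Whitney U handles symmetry, separation and degenerate ties", {
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$u, 8)           # n1 n2 / 2
  expect_gt(same$p_value, 0.9)

  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$u, 0)

  tied <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(tied$p_value, 1)
  expect_equal(tied$u, 5 * 7 / 2)
})

test_that("the normal approximation tracks exhaustive permutation for small n", {
  set.seed(41)
  worst <- 0
  for (rep in 1:12) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- round(rnorm(n1, 0, 2), 1)
    y <- round(rnorm(n2, 0.5, 2), 1)
    p_apx <- mann_whitney_u(x, y)$p_value
    p_ex <- oracle_mw_exact(x, y)
    worst <- max(worst, abs(p_apx - p_ex))
  }
  expect_lt(worst, 0.06)
})

test_that("event summaries give medians, IQRs and sensible p values", {
  d <- design_fixture()
  t0 <- as.POSIXct("2018-01-01", tz = "UTC")
  pre <- purrr::map(0:19, ~ event_row("imp", t0 + .x * 86400 * 3))
  post <- purrr::map(0:19, ~ event_row("imp", t0 + 160 * 86400 + .x * 86400 * 3))
  ev <- dplyr::bind_rows(c(pre, post))
  set.seed(42)
  vals <- rlnorm(20, -1, 0.5)
  ev$peak_q <- c(vals, vals)                 # identical groups
  ev$rain_mm <- runif(40, 2, 20)
  lab <- label_events(ev, d)
  s <- summarize_events(lab)
  pk <- s[s$metric == "peak_q", ]
  expect_equal(pk$median_before, pk$median_after)
  expect_gt(pk$p_value, 0.9)

  ev2 <- ev
  ev2$peak_q <- c(vals, vals * 0.5)          # halved after impact
  s2 <- summarize_events(label_events(ev2, d))
  pk2 <- s2[s2$metric == "peak_q", ]
  expect_equal(pk2$median_after, pk2$median_before / 2)
  expect_lt(pk2$p_value, 0.05)
})

test_that("flashiness ratio is scale-free and matches sorted-array quantiles", {
  t0 <- as.POSIXct("2018-01-01", tz = "UTC")
  const <- flashiness_ratio(make_flow(rep(0.3, 1000)), t0 + 500 * 900)
  expect_equal(const$ratio, c(1, 1))

  set.seed(43)
  v <- rlnorm(1000, -2, 1)
  x <- make_flow(v)
  split <- t0 + 600 * 900
  f1 <- flashiness_ratio(x, split)
  f2 <- flashiness_ratio(make_flow(v * 7.3), split)
  expect_equal(f1$ratio, f2$ratio, tolerance = 1e-12)
  # brute-force quantiles from the sorted halves
  before <- sort(v[1:600])
  expect_equal(f1$q5[1], unname(quantile(before, 0.95)))
  expect_equal(f1$q95[1], unname(quantile(before, 0.05)))
  expect_equal(f1$ratio[1], unname(quantile(before, 0.95) / quantile(before, 0.05)))

  zeros <- make_flow(c(rep(0, 500), rep(1, 500)))
  fz <- flashiness_ratio(zeros, t0 + 500 * 900)
  expect_true(fz$undefined[1])
  expect_identical(fz$ratio[1], Inf)
})

test_that("the Q5 subset keeps exactly the planted top events", {
  d <- design_fixture()
  t0 <- as.POSIXct("2018-01-01", tz = "UTC")
  ev <- dplyr::bind_rows(purrr::map(0:29, ~ event_row("imp", t0 + .x * 86400 * 5)))
  set.seed(44)
  flow_v <- rlnorm(5000, -2, 0.8)
  flow <- make_flow(flow_v)
  thr <- unname(quantile(flow_v, 0.95))
  ev$peak_q <- seq(thr * 0.2, thr * 2, length.out = 30)
  lab <- label_events(ev, d)
  sub <- q5_subset(lab, flow)
  expect_setequal(sub$event_id, lab$event_id[lab$peak_q > thr])
  # tightening the exceedance level never grows the subset
  sub99 <- q5_subset(lab, flow, prob = 0.99)
  expect_true(all(sub99$event_id %in% sub$event_id))
  # all peaks below the threshold: empty subset with a warning
  low <- lab
  low$peak_q <- rep(thr * 0.01, 30)
  expect_warning(empty <- q5_subset(low, flow), "empty")
  expect_equal(nrow(empty), 0)
})
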