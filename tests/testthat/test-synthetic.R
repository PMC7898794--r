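test_that("the generator is seed-reproducible and silent at rate zero", {
  cfg <- synthetic_config(years = 0.3, seed = 61)
  a <- generate_rainfall(cfg)
  b <- generate_rainfall(cfg)
  expect_identical(a$impact$value, b$impact$value)
  expect_identical(a$control$value, b$control$value)
  expect_identical(a$storms, b$storms)

  quiet <- synthetic_config(years = 0.3, storm_rate_per_day = 0, seed = 61)
  r0 <- generate_rainfall(quiet)
  expect_true(all(r0$impact$value == 0))
  expect_true(all(r0$control$value == 0))
})

test_that("storm arrivals follow the configured Poisson rate", {
  counts <- vapply(1:30, function(s) {
    cfg <- synthetic_config(years = 120 / 365, storm_rate_per_day = 0.5,
                            rate_seasonal_amp = 0, rho_control = 1,
                            seed = 7000 + s)
    nrow(generate_rainfall(cfg)$storms) / 2   # per site
  }, numeric(1))
  lambda <- 0.5 * 120
  # mean of 30 replicates within 3 sigma of the Poisson expectation
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 30))
})

test_that("kernels integrate to one exactly, before and after attenuation", {
  k0 <- uh_kernel(3, 3)
  ka <- attenuate_uh_kernel(3, 3, a = 0.6, lag_shift_h = 1)
  expect_lt(abs(sum(k0) - 1), 1e-12)
  expect_lt(abs(sum(ka) - 1), 1e-12)
  expect_equal(max(ka) / max(k0), 0.6, tolerance = 1e-8)
  # time-to-peak moved by the requested shift (one-step discretisation slack)
  expect_lte(abs((which.max(ka) - which.max(k0)) * 0.25 - 1), 0.25 + 1e-9)
  # identity case returns the original kernel bit for bit
  expect_identical(attenuate_uh_kernel(3, 3, a = 1, lag_shift_h = 0), k0)
})

test_that("attenuation lowers response peaks but conserves volume", {
  cfg <- synthetic_config(years = 1, seed = 62, noise_cv = 0,
                          wet_weighted = FALSE)
  st <- generate_study(cfg)
  tr <- st$truth$impact
  post <- tr[tr$attenuated, ]
  expect_gt(nrow(post), 20)
  ratio <- post$peak_quick / post$peak_quick_unatten
  # storm responses peak about 40% lower; convolution with finite-duration
  # storms keeps the realised ratio near but not exactly at the kernel ratio
  expect_equal(median(ratio), 0.6, tolerance = 0.12)
  expect_true(all(ratio < 1))

  # identical storms run with and without attenuation carry the same water
  cfg_null <- synthetic_config(years = 1, seed = 62, noise_cv = 0,
                               wet_weighted = FALSE, attenuation = 1,
                               lag_shift_h = 0)
  st_null <- generate_study(cfg_null)
  expect_identical(st$truth$impact$depth_mm, st_null$truth$impact$depth_mm)
  v1 <- sum(st$flow$impact$value) * 900
  v0 <- sum(st_null$flow$impact$value) * 900
  expect_lt(abs(v1 / v0 - 1), 0.01)
  expect_equal(st$truth$impact$vol_quick_m3, st_null$truth$impact$vol_quick_m3)
})

test_that("a null effect leaves pre and post kernels identical", {
  cfg <- synthetic_config(years = 0.5, seed = 63, attenuation = 1,
                          lag_shift_h = 0)
  st <- generate_study(cfg)
  expect_identical(st$kernels$original, st$kernels$attenuated)
  expect_true(all(!st$truth$impact$attenuated |
                    st$truth$impact$peak_quick ==
                      st$truth$impact$peak_quick_unatten))
})

test_that("with noise off the flow record is exact at every storm peak", {
  cfg <- synthetic_config(years = 0.5, seed = 64, noise_cv = 0)
  st <- generate_study(cfg)
  tr <- st$truth$impact
  idx <- match(as.numeric(tr$t_peak_flow), as.numeric(st$flow$impact$timestamp))
  expect_identical(st$flow$impact$value[idx], tr$peak_flow)
})

test_that("generated flow never drops below the baseflow floor", {
  cfg <- synthetic_config(years = 0.5, seed = 65, noise_cv = 0)
  st <- generate_study(cfg)
  expect_true(all(st$flow$impact$value >= cfg$baseflow_m3s - 1e-12))
  expect_true(all(st$flow$control$value >= cfg$baseflow_m3s - 1e-12))
})

test_that("an impact date outside the record span is rejected", {
  expect_error(
    synthetic_config(years = 1, impact_date = "2030-01-01"),
    "inside the record"
  )
})

test_that("a written study round-trips through the pipeline readers", {
  dir <- tempfile("study")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- synthetic_config(years = 0.3, seed = 66)
  st <- generate_study(cfg, dir = dir)
  expect_true(all(file.exists(st$files)))
  back <- read_series_csv(st$files[["impact_flow"]], "flow")
  expect_equal(back$value, st$flow$impact$value, tolerance = 1e-12)
  expect_equal(back$timestamp, st$flow$impact$timestamp)
  rain_back <- read_series_csv(st$files[["impact_rain"]], "rain")
  expect_equal(rain_back$value, st$rain$impact$value, tolerance = 1e-12)
})
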