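#' Configuration for the synthetic paired-catchment simulator
#'
#' Defines a two-site (impact + control) study: Poisson-clustered storms
#' with winter-peaking arrival rate and seasonal runoff coefficient, a
#' gamma-shaped unit hydrograph, a slow (baseflow) reservoir, multiplicative
#' low-flow sensor noise, and a post-impact attenuation effect that rescales
#' the response kernel (peak multiplied by `attenuation`, time-to-peak
#' shifted by `lag_shift_h`) while its area stays exactly 1, so attenuation
#' redistributes event volume and never removes it.
#'
#' @param start record start (UTC); defaults to a 1 October so the span
#'   aligns with hydrological years.
#' @param years record length in 365-day years.
#' @param step_min sampling step, minutes.
#' @param storm_rate_per_day mean storm arrival rate (events/day),
#'   seasonally modulated by `rate_seasonal_amp` (relative amplitude,
#'   winter peak).
#' @param depth_mean_mm mean storm depth (exponential distribution).
#' @param duration_mean_h,duration_shape storm duration gamma distribution
#'   (mean in hours, shape).
#' @param uh_time_to_peak_h,uh_shape unit-hydrograph gamma kernel:
#'   time-to-peak (hours) and shape (> 1).
#' @param runoff_coef_mean,runoff_coef_amp mean runoff coefficient and its
#'   relative seasonal amplitude (winter peak).
#' @param catchment_km2 contributing area, km2.
#' @param baseflow_m3s baseflow floor, m3/s.
#' @param baseflow_fraction fraction of effective rainfall routed through
#'   the slow reservoir (the rest becomes quickflow).
#' @param recession_days e-folding time of the slow reservoir, days.
#' @param noise_cv coefficient of variation of multiplicative low-flow
#'   noise; noise is suppressed where the storm response dominates, so
#'   event peaks remain exact ground truth.
#' @param attenuation post-impact kernel peak scaling `a` in (0, 1].
#' @param lag_shift_h post-impact time-to-peak shift, hours.
#' @param wet_weighted if TRUE the attenuated kernel applies only to storms
#'   starting in the wet season (1 Oct - 1 Apr); dry-season storms keep the
#'   original kernel.
#' @param rho_control probability that a storm is shared between the impact
#'   and control sites (storm-timing correlation).
#' @param impact_date beaver-impact date; defaults to the record midpoint.
#' @param seed master seed; component sub-streams (shared storms, each
#'   site's extra storms, each site's noise) use fixed offsets from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(start = "2016-10-01", years = 2, step_min = 15,
                             storm_rate_per_day = 0.9, rate_seasonal_amp = 0.4,
                             depth_mean_mm = 8, duration_mean_h = 2,
                             duration_shape = 2,
                             uh_time_to_peak_h = 3, uh_shape = 3,
                             runoff_coef_mean = 0.25, runoff_coef_amp = 0.4,
                             catchment_km2 = 1.5,
                             baseflow_m3s = 0.04, baseflow_fraction = 0.3,
                             recession_days = 15,
                             noise_cv = 0.05,
                             attenuation = 0.6, lag_shift_h = 1,
                             wet_weighted = TRUE,
                             rho_control = 0.8,
                             impact_date = NULL, seed = 1) {
  stopifnot(
    years > 0, step_min > 0, storm_rate_per_day >= 0,
    rate_seasonal_amp >= 0, rate_seasonal_amp < 1,
    depth_mean_mm > 0, duration_mean_h > 0, duration_shape > 0,
    uh_time_to_peak_h > 0, uh_shape > 1,
    runoff_coef_mean > 0, runoff_coef_amp >= 0, runoff_coef_amp < 1,
    catchment_km2 > 0, baseflow_m3s > 0,
    baseflow_fraction >= 0, baseflow_fraction < 1,
    recession_days > 0, noise_cv >= 0,
    attenuation > 0, attenuation <= 1, lag_shift_h >= 0,
    rho_control >= 0, rho_control <= 1
  )
  start <- as.POSIXct(start, tz = "UTC")
  span_s <- round(years * 365 * 86400)
  if (is.null(impact_date)) impact_date <- start + span_s / 2
  impact_date <- as.POSIXct(impact_date, tz = "UTC")
  if (impact_date <= start || impact_date >= start + span_s) {
    abort("`impact_date` must fall strictly inside the record span.")
  }
  cfg <- list(
    start = start, years = years, step_min = step_min,
    n_steps = span_s %/% (step_min * 60),
    storm_rate_per_day = storm_rate_per_day,
    rate_seasonal_amp = rate_seasonal_amp,
    depth_mean_mm = depth_mean_mm, duration_mean_h = duration_mean_h,
    duration_shape = duration_shape,
    uh_time_to_peak_h = uh_time_to_peak_h, uh_shape = uh_shape,
    runoff_coef_mean = runoff_coef_mean, runoff_coef_amp = runoff_coef_amp,
    catchment_km2 = catchment_km2,
    baseflow_m3s = baseflow_m3s, baseflow_fraction = baseflow_fraction,
    recession_days = recession_days, noise_cv = noise_cv,
    attenuation = attenuation, lag_shift_h = lag_shift_h,
    wet_weighted = wet_weighted, rho_control = rho_control,
    impact_date = impact_date, seed = as.integer(seed)
  )
  structure(cfg, class = "synthetic_config")
}

# run expr under a fixed sub-stream seed, restoring the RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

# winter-peaking (mid-January) sinusoid of relative amplitude `amp`
seasonal_factor <- function(t, amp) {
  doy <- as.numeric(format(t, "%j"))
  1 + amp * cos(2 * pi * (doy - 15) / 365.25)
}

# direct (non-FFT) linear convolution; the storm profiles are short, so this
# beats FFT-based convolution by a wide margin in the simulator's hot loop
conv_direct <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (j in seq_along(a)) {
    seg <- j:(j + length(b) - 1L)
    out[seg] <- out[seg] + a[j] * b
  }
  out
}

is_wet_season <- function(t, wet_start = "10-01", wet_end = "04-01") {
  md <- format(t, "%m-%d")
  md >= wet_start | md < wet_end
}

#' Discrete unit-hydrograph kernel
#'
#' A gamma-density kernel sampled at the series step and normalized to sum
#' exactly to 1, so convolving it with an effective-rainfall volume series
#' conserves volume to machine precision.
#'
#' @param time_to_peak_h kernel mode, hours.
#' @param shape gamma shape (> 1).
#' @param step_min series step, minutes.
#' @return Numeric vector of kernel weights (sum exactly 1).
#' @export
uh_kernel <- function(time_to_peak_h, shape, step_min = 15) {
  scale <- time_to_peak_h / (shape - 1)
  step_h <- step_min / 60
  len <- min(ceiling(stats::qgamma(0.9995, shape, scale = scale) / step_h) + 1L,
             50000L)
  t_h <- (seq_len(len) - 0.5) * step_h
  w <- dgamma(t_h, shape, scale = scale)
  w / sum(w)
}

#' Attenuate a unit-hydrograph kernel
#'
#' Builds the post-impact kernel: a gamma kernel whose time-to-peak is
#' shifted by `lag_shift_h` and whose (discrete) peak equals `a` times the
#' original kernel's peak, renormalized to area exactly 1. The gamma shape
#' is solved numerically for the peak condition; `a = 1` with no shift
#' returns the original kernel unchanged.
#'
#' @param time_to_peak_h,shape,step_min the original kernel parameters
#'   (see [uh_kernel()]).
#' @param a peak scaling in (0, 1].
#' @param lag_shift_h time-to-peak shift, hours.
#' @return Kernel weight vector (sum exactly 1).
#' @export
attenuate_uh_kernel <- function(time_to_peak_h, shape, a, lag_shift_h,
                                step_min = 15) {
  k0 <- uh_kernel(time_to_peak_h, shape, step_min)
  if (a >= 1 && lag_shift_h == 0) return(k0)
  p_target <- a * max(k0)
  tp_new <- time_to_peak_h + lag_shift_h
  peak_of <- function(sh) max(uh_kernel(tp_new, sh, step_min))
  # discrete kernel peak grows with shape at fixed mode; bracket and solve,
  # walking the lower bracket down geometrically (shape near 1 means a very
  # long flat kernel, so start from the original shape and descend)
  hi <- shape
  while (peak_of(hi) < p_target && hi < 1e4) hi <- 1 + (hi - 1) * 2
  lo <- 1 + (shape - 1) / 2
  while (peak_of(lo) > p_target && lo > 1 + 1e-8) lo <- 1 + (lo - 1) / 2
  if (peak_of(lo) > p_target) {
    abort("requested attenuation is too strong for this kernel family.")
  }
  sh <- uniroot(function(s) peak_of(s) - p_target, c(lo, hi),
                tol = 1e-10)$root
  uh_kernel(tp_new, sh, step_min)
}

# triangular within-storm depth profile peaking at about one third of the
# duration; deterministic given the duration
storm_profile <- function(depth_mm, dur_steps) {
  if (dur_steps == 1L) return(depth_mm)
  pk <- max(1L, ceiling(dur_steps / 3))
  w <- pmin(seq_len(dur_steps) / pk,
            (dur_steps + 1 - seq_len(dur_steps)) / (dur_steps + 1 - pk))
  depth_mm * w / sum(w)
}

# nonhomogeneous Poisson storm arrivals by thinning, plus per-storm marks
draw_storms <- function(cfg, rate_scale, seed_offset) {
  with_seed(cfg$seed + seed_offset, {
    span_days <- cfg$years * 365
    rmax <- cfg$storm_rate_per_day * rate_scale * (1 + cfg$rate_seasonal_amp)
    n_cand <- rpois(1, rmax * span_days)
    t_cand <- sort(runif(n_cand, 0, span_days))
    tt <- cfg$start + t_cand * 86400
    keep <- runif(n_cand) <
      cfg$storm_rate_per_day * rate_scale *
        seasonal_factor(tt, cfg$rate_seasonal_amp) / rmax
    tt <- tt[keep]
    n <- length(tt)
    step_s <- cfg$step_min * 60
    start_idx <- pmin(
      cfg$n_steps,
      1L + as.integer(floor(as.numeric(tt - cfg$start, units = "secs") / step_s))
    )
    dur <- pmax(1L, as.integer(round(
      rgamma(n, cfg$duration_shape,
             scale = cfg$duration_mean_h / cfg$duration_shape) * 60 / cfg$step_min
    )))
    depth <- rexp(n, 1 / cfg$depth_mean_mm)
    tibble::tibble(start_idx = start_idx, dur_steps = dur, depth_mm = depth)
  })
}

#' Generate correlated rainfall for the impact and control sites
#'
#' Storm arrivals follow a winter-peaking Poisson process. A fraction
#' `rho_control` of storms is shared between the sites (same timing and
#' duration, lognormally jittered depth at the control); each site also
#' receives independent storms at rate `(1 - rho_control)` times the base
#' rate, so both sites see the same marginal storm climate.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with rain [regular_series()] `impact` and `control`, and
#'   a `storms` tibble (site, start index, duration, depth).
#' @export
generate_rainfall <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  shared <- draw_storms(cfg, cfg$rho_control, seed_offset = 1L)
  own_i <- draw_storms(cfg, 1 - cfg$rho_control, seed_offset = 101L)
  own_c <- draw_storms(cfg, 1 - cfg$rho_control, seed_offset = 201L)
  jit <- with_seed(cfg$seed + 11L, rlnorm(nrow(shared), 0, 0.1))
  st_i <- dplyr::bind_rows(shared, own_i) |> dplyr::arrange(.data$start_idx)
  shared_c <- shared
  shared_c$depth_mm <- shared_c$depth_mm * jit
  st_c <- dplyr::bind_rows(shared_c, own_c) |> dplyr::arrange(.data$start_idx)
  st_i$site <- "impact"
  st_c$site <- "control"
  storms <- dplyr::bind_rows(st_i, st_c) |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(storm_id = sprintf("%s-s%04d", .data$site, dplyr::row_number())) |>
    dplyr::ungroup()
  ts <- cfg$start + (seq_len(cfg$n_steps) - 1) * cfg$step_min * 60
  build <- function(st) {
    v <- numeric(cfg$n_steps)
    for (i in seq_len(nrow(st))) {
      prof <- storm_profile(st$depth_mm[i], st$dur_steps[i])
      idx <- st$start_idx[i] + seq_along(prof) - 1L
      ok <- idx <= cfg$n_steps
      v[idx[ok]] <- v[idx[ok]] + prof[ok]
    }
    regular_series(ts, v, quantity = "rain", step_min = cfg$step_min)
  }
  list(
    impact = build(st_i), control = build(st_c),
    storms = storms[c("site", "storm_id", "start_idx", "dur_steps", "depth_mm")]
  )
}

#' Generate a flow record from rainfall, with known ground truth
#'
#' Flow is the baseflow floor plus a slow-reservoir response to effective
#' rainfall plus each storm's quickflow: the storm's effective-rain volume
#' convolved with the unit-hydrograph kernel. At an impact site, storms
#' starting at or after the impact date use the attenuated kernel (all of
#' them, or only wet-season storms when `wet_weighted`). Multiplicative
#' noise applies only where the quick component is negligible, so peaks are
#' exact ground truth. The truth table records, per storm, the realized
#' peak, its timing, the peak-to-peak lag, the quickflow volume and the
#' counterfactual unattenuated peak.
#'
#' @param rain the site's rain [regular_series()] from [generate_rainfall()].
#' @param cfg a [synthetic_config()].
#' @param storms the site's rows of the storms table.
#' @param impact logical: is this the impact site (attenuation applies)?
#' @return A list: `flow` ([regular_series()]), `truth` (tibble) and the
#'   two kernels.
#' @export
generate_flow <- function(rain, cfg, storms, impact = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  assert_series(rain, "rain")
  n <- nrow(rain)
  ts <- rain$timestamp
  step_s <- cfg$step_min * 60
  area_m2 <- cfg$catchment_km2 * 1e6
  k0 <- uh_kernel(cfg$uh_time_to_peak_h, cfg$uh_shape, cfg$step_min)
  ka <- attenuate_uh_kernel(cfg$uh_time_to_peak_h, cfg$uh_shape,
                            cfg$attenuation, cfg$lag_shift_h, cfg$step_min)
  quick <- numeric(n)
  quick_cf <- numeric(n)   # counterfactual: no attenuation anywhere
  eff_vol <- numeric(n)    # total effective-rain volume per bin, m3
  ns <- nrow(storms)
  s_idx0 <- s_idx1 <- integer(ns)
  s_wet <- s_post <- s_atten <- logical(ns)
  s_vol <- s_pkq <- s_pkq0 <- s_train <- numeric(ns)
  # per-grid seasonal runoff coefficient and per-storm season, computed once
  rc_grid <- cfg$runoff_coef_mean * seasonal_factor(ts, cfg$runoff_coef_amp)
  wet_start <- is_wet_season(ts[storms$start_idx])
  for (i in seq_len(ns)) {
    prof <- storm_profile(storms$depth_mm[i], storms$dur_steps[i])
    i0 <- storms$start_idx[i]
    idx <- i0 + seq_along(prof) - 1L
    ok <- idx <= n
    idx <- idx[ok]
    prof <- prof[ok]
    vol <- prof * rc_grid[idx] * area_m2 / 1000    # m3 per bin
    eff_vol[idx] <- eff_vol[idx] + vol
    qvol <- vol * (1 - cfg$baseflow_fraction)
    wet <- wet_start[i]
    post <- impact && ts[i0] >= cfg$impact_date
    atten <- post && (!cfg$wet_weighted || wet)
    ker <- if (atten) ka else k0
    add_resp <- function(acc, resp) {
      ridx <- idx[1] + seq_along(resp) - 1L
      rok <- ridx <= n
      acc[ridx[rok]] <- acc[ridx[rok]] + resp[rok]
      acc
    }
    resp <- conv_direct(qvol, ker) / step_s
    resp0 <- conv_direct(qvol, k0) / step_s
    quick <- add_resp(quick, resp)
    quick_cf <- add_resp(quick_cf, resp0)
    s_idx0[i] <- idx[1]
    s_idx1[i] <- min(n, idx[1] + length(prof) + length(ker) + 4L)
    s_wet[i] <- wet
    s_post[i] <- post
    s_atten[i] <- atten
    s_vol[i] <- sum(qvol)
    s_pkq[i] <- max(resp)
    s_pkq0[i] <- max(resp0)
    s_train[i] <- as.numeric(ts[idx[which.max(prof)]])
  }
  # slow reservoir: exponential kernel with area exactly 1 (recursive form)
  tau <- cfg$recession_days * 86400 / step_s
  rho <- exp(-1 / tau)
  slow_in <- eff_vol * cfg$baseflow_fraction * (1 - rho) / step_s
  slow <- as.numeric(stats::filter(slow_in, rho, method = "recursive"))
  base_tot <- cfg$baseflow_m3s + slow
  flow_clean <- base_tot + quick
  flow_cf <- base_tot + quick_cf
  noise <- rep(1, n)
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    site_tag <- if (impact) 301L else 401L
    raw <- with_seed(cfg$seed + site_tag, rlnorm(n, -sdlog^2 / 2, sdlog))
    lowflow <- quick < 0.05 * base_tot
    noise[lowflow] <- raw[lowflow]
  }
  flow <- flow_clean * noise
  pk_i <- pk0_i <- integer(ns)
  for (i in seq_len(ns)) {
    win <- s_idx0[i]:s_idx1[i]
    pk_i[i] <- win[which.max(flow_clean[win])]
    pk0_i[i] <- win[which.max(flow_cf[win])]
  }
  truth <- tibble::tibble(
    site = storms$site, storm_id = storms$storm_id,
    start = ts[s_idx0], wet = s_wet, post = s_post, attenuated = s_atten,
    depth_mm = storms$depth_mm,
    vol_quick_m3 = s_vol,
    peak_quick = s_pkq, peak_quick_unatten = s_pkq0,
    peak_flow = flow_clean[pk_i], t_peak_flow = ts[pk_i],
    t_rain_peak = as.POSIXct(s_train, tz = "UTC", origin = "1970-01-01"),
    lag_true_h = (as.numeric(ts[pk_i]) - s_train) / 3600,
    peak_flow_unatten = flow_cf[pk0_i]
  )
  list(
    flow = regular_series(ts, flow, quantity = "flow", step_min = cfg$step_min),
    truth = truth, kernel = k0, kernel_attenuated = ka
  )
}

#' Generate a complete synthetic study
#'
#' Produces the full pipeline-ready bundle: correlated rainfall and flow for
#' an impact and a control site, the study design, and per-storm truth
#' tables. With `dir` set, everything is written in the pipeline's CSV /
#' YAML formats (`<site>_rain.csv`, `<site>_flow.csv`, `design.yaml`,
#' `truth_<site>.csv`).
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory (created if needed).
#' @return Invisibly, a list: `rain`, `flow`, `truth` (named by site),
#'   `design`, `kernels`, `config`, and `files` when written.
#' @export
generate_study <- function(cfg = synthetic_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  rn <- generate_rainfall(cfg)
  fi <- generate_flow(rn$impact, cfg,
                      storms = rn$storms[rn$storms$site == "impact", ],
                      impact = TRUE)
  fc <- generate_flow(rn$control, cfg,
                      storms = rn$storms[rn$storms$site == "control", ],
                      impact = FALSE)
  design <- study_design(tibble::tibble(
    site = c("impact", "control"),
    role = c("impact", "control"),
    impact_date = c(format(cfg$impact_date, "%Y-%m-%d %H:%M:%S"), NA),
    paired_with = c(NA, "impact")
  ))
  out <- list(
    rain = list(impact = rn$impact, control = rn$control),
    flow = list(impact = fi$flow, control = fc$flow),
    truth = list(impact = fi$truth, control = fc$truth),
    design = design,
    kernels = list(original = fi$kernel, attenuated = fi$kernel_attenuated),
    config = cfg
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(
      impact_rain = file.path(dir, "impact_rain.csv"),
      impact_flow = file.path(dir, "impact_flow.csv"),
      control_rain = file.path(dir, "control_rain.csv"),
      control_flow = file.path(dir, "control_flow.csv"),
      design = file.path(dir, "design.yaml"),
      truth_impact = file.path(dir, "truth_impact.csv"),
      truth_control = file.path(dir, "truth_control.csv")
    )
    write_series_csv(rn$impact, files[["impact_rain"]])
    write_series_csv(fi$flow, files[["impact_flow"]])
    write_series_csv(rn$control, files[["control_rain"]])
    write_series_csv(fc$flow, files[["control_flow"]])
    yaml::write_yaml(list(
      sites = list(
        list(id = "impact", role = "impact",
             impact_date = format(cfg$impact_date, "%Y-%m-%d %H:%M:%S"),
             rain_csv = "impact_rain.csv", flow_csv = "impact_flow.csv"),
        list(id = "control", role = "control", paired_with = "impact",
             rain_csv = "control_rain.csv", flow_csv = "control_flow.csv")
      ),
      seed = cfg$seed
    ), files[["design"]])
    readr::write_csv(fi$truth, files[["truth_impact"]], progress = FALSE)
    readr::write_csv(fc$truth, files[["truth_control"]], progress = FALSE)
    out$files <- files
  }
  invisible(out)
}
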