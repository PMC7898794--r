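# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every quantity step by step from its definition and
# share no code with the package internals they check.

make_flow <- function(values, start = "2018-01-01", step_min = 15, gap = NULL) {
  regular_series(
    as.POSIXct(start, tz = "UTC") + (seq_along(values) - 1) * step_min * 60,
    values, gap = gap, quantity = "flow", step_min = step_min
  )
}

make_rain <- function(values, start = "2018-01-01", step_min = 15, gap = NULL) {
  regular_series(
    as.POSIXct(start, tz = "UTC") + (seq_along(values) - 1) * step_min * 60,
    values, gap = gap, quantity = "rain", step_min = step_min
  )
}

# naive centered rolling quantile (R quantile type 7), shrinking windows at
# the ends, skipping NA
oracle_roll_quantile <- function(x, w, p) {
  n <- length(x)
  left <- w %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - left)
    hi <- min(n, i - left + w - 1)
    v <- x[lo:hi]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else unname(quantile(v, p, type = 7))
  }, numeric(1))
}

oracle_roll_mean <- function(x, w) {
  n <- length(x)
  left <- w %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - left)
    hi <- min(n, i - left + w - 1)
    v <- x[lo:hi]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
}

# sample-by-sample evaluation of the cleaning rule from its definition
oracle_clean <- function(v, step_min = 15) {
  w_q <- round(12.5 * 60 / step_min)
  w_s <- round(7.5 * 60 / step_min)
  w_l <- round(30 * 24 * 60 / step_min)
  q25 <- oracle_roll_quantile(v, w_q, 0.25)
  q75 <- oracle_roll_quantile(v, w_q, 0.75)
  mq70 <- oracle_roll_quantile(v, w_l, 0.70)
  rmean <- oracle_roll_mean(v, w_s)
  elevated <- !is.na(q75) & !is.na(mq70) & (q75 - q25) > mq70
  out <- ifelse(elevated, v, rmean)
  n <- length(v)
  for (i in seq_len(n)) {
    nb <- setdiff(max(1, i - 2):min(n, i + 2), i)
    if (!is.na(v[i]) && all(is.na(v[nb]) | v[i] > v[nb]) && any(elevated[max(1, i - 2):min(n, i + 2)])) {
      out[i] <- v[i]
    }
  }
  out
}

# step-by-step recursive filter oracle: reflection, alternating passes,
# per-step clipping of quickflow to [0, q]
oracle_lh <- function(q, alpha = 0.925, passes = 3, reflect = 30) {
  one_pass <- function(x) {
    n <- length(x)
    bf <- numeric(n)
    bf[1] <- x[1]
    qf <- 0
    for (i in 2:n) {
      f <- alpha * qf + (1 + alpha) / 2 * (x[i] - x[i - 1])
      f <- min(max(f, 0), x[i])
      qf <- f
      bf[i] <- x[i] - qf
    }
    bf
  }
  len <- length(q)
  pad <- min(reflect, len - 1)
  x <- c(rev(q[2:(pad + 1)]), q, rev(q[(len - pad):(len - 1)]))
  for (p in seq_len(passes)) {
    x <- if (p %% 2 == 1) one_pass(x) else rev(one_pass(rev(x)))
  }
  x[(pad + 1):(pad + len)]
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (midranks for ties); two-sided via distance of U from its mean
oracle_mw_exact <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(u_of(seq_len(n1)) - n1 * n2 / 2)
  sets <- utils::combn(n1 + n2, n1)
  hits <- apply(sets, 2, function(idx) abs(u_of(idx) - n1 * n2 / 2) >= obs - 1e-9)
  mean(hits)
}

# Gamma identity-link maximum likelihood by generic numerical optimisation:
# for fixed shape the ML coefficients minimise sum(log(mu) + y / mu)
oracle_gamma_ml <- function(y, X, start) {
  nll <- function(b) {
    mu <- drop(X %*% b)
    if (any(mu <= 0)) return(1e10)
    sum(log(mu) + y / mu)
  }
  gr <- function(b) {
    mu <- drop(X %*% b)
    drop(crossprod(X, 1 / mu - y / mu^2))
  }
  o <- optim(start, nll, gr, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  o$par
}

# run the standard pipeline on one site of a synthetic study
pipeline_site <- function(flow, rain, site, clean = TRUE,
                          params = event_params()) {
  fc <- if (clean) clean_low_flow(flow) else flow
  bf <- separate_baseflow(fc)
  bf$flow <- flow$value
  extract_events(bf, rain, params = params, site = site)
}

pipeline_study <- function(st, clean = TRUE, params = event_params()) {
  ev <- dplyr::bind_rows(
    pipeline_site(st$flow$impact, st$rain$impact, "impact", clean, params),
    pipeline_site(st$flow$control, st$rain$control, "control", clean, params)
  )
  label_events(ev, st$design)
}
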