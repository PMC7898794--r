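glm_fixture <- function(n_per = 120, beta = c(0.1, 0.02, -0.05), shape = 5,
                        noiseless = FALSE, seed = 51) {
  set.seed(seed)
  rain <- runif(2 * n_per, 2, 30)
  beaver <- factor(rep(c("before", "after"), each = n_per),
                   levels = c("before", "after"))
  mu <- beta[1] + beta[2] * rain + beta[3] * (beaver == "after")
  peak <- if (noiseless) mu else rgamma(2 * n_per, shape, rate = shape / mu)
  tibble::tibble(
    site = "imp", event_id = sprintf("e%03d", seq_len(2 * n_per)),
    start = as.POSIXct("2018-01-01", tz = "UTC") + seq_len(2 * n_per) * 86400,
    rain_mm = rain, peak_q = peak, beaver = beaver,
    season = factor(rep(c("dry", "wet"), n_per), levels = c("dry", "wet")),
    gap_affected = FALSE, unpaired = FALSE, excluded = FALSE
  )
}

test_that("noiseless additive data are recovered exactly", {
  ev <- glm_fixture(noiseless = TRUE)
  fit <- fit_peakflow_glm(ev, "additive")
  expect_equal(unname(coef(fit$fit)), c(0.1, 0.02, -0.05), tolerance = 1e-6)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, nrow(ev))
})

test_that("IRLS coefficients agree with a generic ML optimiser to 1e-4", {
  ev <- glm_fixture()
  fit <- fit_peakflow_glm(ev, "additive")
  X <- model.matrix(~ rain_mm + beaver, data = ev)
  b_ml <- oracle_gamma_ml(ev$peak_q, X, start = unname(qr.coef(qr(X), ev$peak_q)))
  expect_lt(max(abs(unname(coef(fit$fit)) - b_ml)), 1e-4)
})

test_that("the beaver effect is recovered within 2 SE in most replicates", {
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    ev <- glm_fixture(n_per = 300, beta = c(0.6, 0.02, -0.2), seed = 1000 + r)
    td <- tidy(fit_peakflow_glm(ev, "additive"))
    i <- match("beaverafter", td$term)
    hits <- hits + (abs(td$estimate[i] + 0.2) <= 2 * td$std.error[i])
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("adding a constant shifts only intercept-bearing quantities", {
  ev <- glm_fixture(noiseless = TRUE)
  f1 <- fit_peakflow_glm(ev, "additive")
  ev2 <- ev
  ev2$peak_q <- ev$peak_q + 0.5
  f2 <- fit_peakflow_glm(ev2, "additive")
  c1 <- coef(f1$fit)
  c2 <- coef(f2$fit)
  expect_equal(unname(c2[1] - c1[1]), 0.5, tolerance = 1e-6)
  expect_equal(unname(c2[-1]), unname(c1[-1]), tolerance = 1e-6)
  mm1 <- marginal_means(f1, margins = "beaver")
  mm2 <- marginal_means(f2, margins = "beaver")
  expect_equal(mm2$emmean, mm1$emmean + 0.5, tolerance = 1e-6)
})

test_that("additive-model emmeans differ by exactly the beaver coefficient", {
  ev <- glm_fixture()
  fit <- fit_peakflow_glm(ev, "additive")
  mm <- marginal_means(fit, margins = "beaver")
  expect_equal(
    mm$emmean[mm$beaver == "after"] - mm$emmean[mm$beaver == "before"],
    unname(coef(fit$fit)["beaverafter"]),
    tolerance = 1e-12
  )
})

test_that("marginal means match hand calculation on an unbalanced 2x2 design", {
  set.seed(52)
  n <- c(bd = 40, bw = 15, ad = 25, aw = 50)   # deliberately unbalanced
  cell <- rep(names(n), n)
  rain <- runif(sum(n), 2, 25)
  beaver <- factor(ifelse(grepl("^b", cell), "before", "after"),
                   levels = c("before", "after"))
  season <- factor(ifelse(grepl("d$", cell), "dry", "wet"),
                   levels = c("dry", "wet"))
  mu <- 0.2 + 0.015 * rain + 0.1 * (season == "wet") -
    0.06 * (beaver == "after") - 0.05 * (beaver == "after") * (season == "wet")
  peak <- rgamma(sum(n), 6, rate = 6 / mu)
  ev <- tibble::tibble(
    site = "imp", rain_mm = rain, peak_q = peak, beaver = beaver,
    season = season, gap_affected = FALSE, unpaired = FALSE, excluded = FALSE
  )
  fit <- fit_peakflow_glm(ev, "seasonal")
  b <- coef(fit$fit)
  rbar <- mean(rain)
  # hand-built cell predictions at the covariate mean
  pred <- c(
    before_dry = as.numeric(b[1] + b["rain_mm"] * rbar),
    before_wet = as.numeric(b[1] + b["rain_mm"] * rbar + b["seasonwet"]),
    after_dry = as.numeric(b[1] + b["rain_mm"] * rbar + b["beaverafter"]),
    after_wet = as.numeric(b[1] + b["rain_mm"] * rbar + b["beaverafter"] +
      b["seasonwet"] + b["beaverafter:seasonwet"])
  )
  cells <- marginal_means(fit)
  key <- paste(cells$beaver, cells$season, sep = "_")
  expect_equal(cells$emmean[match(names(pred), key)], unname(pred),
               tolerance = 1e-10)
  mm <- marginal_means(fit, margins = "beaver")
  expect_equal(mm$emmean[mm$beaver == "before"],
               unname((pred["before_dry"] + pred["before_wet"]) / 2),
               tolerance = 1e-10)
  expect_equal(mm$emmean[mm$beaver == "after"],
               unname((pred["after_dry"] + pred["after_wet"]) / 2),
               tolerance = 1e-10)
  # hand-computed standard error of the after-level marginal mean
  X <- model.matrix(~ rain_mm + beaver * season, data = data.frame(
    rain_mm = rbar,
    beaver = factor(c("after", "after"), levels = c("before", "after")),
    season = factor(c("dry", "wet"), levels = c("dry", "wet"))
  ))
  w <- colMeans(X)
  expect_equal(mm$se[mm$beaver == "after"],
               sqrt(drop(t(w) %*% vcov(fit$fit) %*% w)),
               tolerance = 1e-10)
})

test_that("marginal means agree with the emmeans package", {
  skip_if_not_installed("emmeans")
  ev <- glm_fixture()
  fit <- fit_peakflow_glm(ev, "seasonal")
  em <- as.data.frame(emmeans::emmeans(fit$fit, ~ beaver * season,
                                       data = as.data.frame(fit$data)))
  mine <- marginal_means(fit)
  key_m <- paste(mine$beaver, mine$season)
  key_e <- paste(em$beaver, em$season)
  idx <- match(key_e, key_m)
  expect_equal(mine$emmean[idx], em$emmean, tolerance = 1e-8)
  expect_equal(mine$se[idx], em$SE, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with clear messages", {
  ev <- glm_fixture()
  ev$peak_q[1] <- 0
  expect_error(fit_peakflow_glm(ev, "additive"), "positive")
  ev2 <- glm_fixture()
  expect_error(fit_peakflow_glm(ev2, "baci"), "control")
})
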