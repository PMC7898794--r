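#' Gamma identity-link GLM of event peak flow
#'
#' Fits peak discharge against total event rainfall with beaver presence and
#' optional season / site terms, using a Gamma error distribution with an
#' identity link (the effect of each term is additive on the m3/s scale, so
#' a coefficient reads directly as a change in peak flow). Model forms:
#'
#' * `additive`: `peak_q ~ rain_mm + beaver`
#' * `seasonal`: `peak_q ~ rain_mm + beaver * season`
#' * `baci`: `peak_q ~ rain_mm + beaver * site`
#' * `baci_seasonal`: `peak_q ~ rain_mm + beaver * season * site`
#'
#' Factors use treatment contrasts with reference levels before-beaver, dry
#' season and the control site, so the `beaver` coefficient is the modelled
#' change in peak flow after impact. Fitting is by iteratively reweighted
#' least squares with an ordinary-least-squares start whose fitted means are
#' floored at a small positive value (identity-link Gamma likelihoods are
#' only defined for positive means); if the final fit has any non-positive
#' fitted mean or fails to converge an error asks for data/model review.
#' Dispersion is the Pearson statistic over the residual degrees of freedom.
#'
#' @param events a labelled event table with positive `peak_q` and complete
#'   predictors; flagged events are dropped unless `include_flagged`.
#' @param formula one of `"additive"`, `"seasonal"`, `"baci"`,
#'   `"baci_seasonal"`.
#' @param include_flagged keep flagged events (default FALSE).
#' @return An object of class `peakflow_glm` wrapping the [stats::glm] fit
#'   with the model kind and analysis data; supports `tidy()`, `glance()`,
#'   [marginal_means()] and [baci_contrast()].
#' @export
fit_peakflow_glm <- function(events,
                             formula = c("additive", "seasonal", "baci",
                                         "baci_seasonal"),
                             include_flagged = FALSE) {
  kind <- match.arg(formula)
  ev <- analysis_events(events, include_flagged)
  need <- c("peak_q", "rain_mm", "beaver")
  if (kind %in% c("seasonal", "baci_seasonal")) need <- c(need, "season")
  if (kind %in% c("baci", "baci_seasonal")) need <- c(need, "site")
  if (!all(need %in% names(ev))) {
    abort(paste("events lack columns:", paste(setdiff(need, names(ev)), collapse = ", ")))
  }
  ev <- ev[complete.cases(ev[need]), need, drop = FALSE]
  if (any(ev$peak_q <= 0)) abort("peak_q must be strictly positive for a Gamma GLM.")
  if (nrow(ev) < length(need) + 2) abort("too few events to fit this model.")
  if (kind %in% c("baci", "baci_seasonal")) {
    ev$site <- droplevels(factor(ev$site, levels = site_levels(ev, events)))
    if (nlevels(ev$site) < 2) abort("BACI models need both a control and an impact site.")
  }
  fml <- switch(kind,
    additive = peak_q ~ rain_mm + beaver,
    seasonal = peak_q ~ rain_mm + beaver * season,
    baci = peak_q ~ rain_mm + beaver * site,
    baci_seasonal = peak_q ~ rain_mm + beaver * season * site
  )
  X <- model.matrix(fml, data = ev)
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient (an empty factor cell?); review the data.")
  }
  y <- ev$peak_q
  # OLS start with fitted means floored at a small positive value
  b0 <- qr.coef(qr(X), y)
  floor_mu <- 1e-6 * median(y)
  mu0 <- drop(X %*% b0)
  if (any(mu0 <= floor_mu)) {
    b0[1] <- b0[1] + (floor_mu - min(mu0))
  }
  # transient IRLS steps can visit non-positive means, which emits harmless
  # NaN warnings from the deviance bookkeeping; only the converged fit matters
  fit <- tryCatch(
    suppressWarnings(
      glm(fml, data = ev, family = Gamma(link = "identity"),
          start = b0, control = list(maxit = 100))
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || any(fit$fitted.values <= 0)) {
    abort(paste(
      "Gamma identity GLM did not reach a valid fit (non-convergence or a",
      "non-positive fitted mean); review the data or choose a simpler model."
    ))
  }
  structure(
    list(fit = fit, kind = kind, data = ev,
         dispersion = summary(fit)$dispersion),
    class = "peakflow_glm"
  )
}

# BACI site factor: control is the reference level
site_levels <- function(ev, events) {
  sites <- unique(as.character(ev$site))
  if ("role" %in% names(events)) {
    roles <- tibble::as_tibble(events)[c("site", "role")] |> dplyr::distinct()
    ctrl <- as.character(roles$site[roles$role == "control"])
    sites <- c(intersect(ctrl, sites), setdiff(sites, ctrl))
  }
  sites
}

#' @export
print.peakflow_glm <- function(x, ...) {
  cat(sprintf(
    "<peakflow_glm> %s model, n = %d, dispersion %.4g\n",
    x$kind, nrow(x$data), x$dispersion
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.peakflow_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.peakflow_glm <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    model = x$kind, n = nrow(x$data),
    deviance = f$deviance, null.deviance = f$null.deviance,
    df.residual = f$df.residual, dispersion = x$dispersion,
    AIC = stats::AIC(f), logLik = as.numeric(stats::logLik(f))
  )
}

#' Equal-weight estimated marginal means
#'
#' Builds the reference grid -- every combination of the model's factor
#' levels with total event rainfall fixed at its observed mean -- and
#' predicts peak flow in each cell. The marginal mean of a factor level is
#' the unweighted average of cell predictions over the other factors'
#' levels, so unbalanced group sizes get equal cell weight. Standard errors
#' come from the coefficient covariance through the averaged linear form;
#' with an identity link this is exact, no delta-method approximation.
#'
#' @param fit a [fit_peakflow_glm()] object.
#' @param margins character vector of factor names to retain in the output
#'   (cells are averaged over the others); `NULL` (default) returns the
#'   full cell grid.
#' @param cov_value covariate setting; default the observed mean of
#'   `rain_mm` in the analysis data.
#' @return A tibble of class `marginal_means`: factor level columns,
#'   `emmean`, `se` and the covariate setting `rain_mm`. Cells absent from
#'   the data are still predicted (model-based) and flagged `empty_cell`.
#' @export
marginal_means <- function(fit, margins = NULL, cov_value = NULL) {
  stopifnot(inherits(fit, "peakflow_glm"))
  ev <- fit$data
  facs <- intersect(c("beaver", "season", "site"), names(ev))
  if (is.null(cov_value)) cov_value <- mean(ev$rain_mm)
  grid <- expand.grid(
    lapply(setNames(facs, facs), function(f) levels(factor(ev[[f]]))),
    stringsAsFactors = FALSE
  )
  grid$rain_mm <- cov_value
  for (f in facs) grid[[f]] <- factor(grid[[f]], levels = levels(factor(ev[[f]])))
  X <- model.matrix(stats::delete.response(stats::terms(fit$fit)), data = grid)
  V <- vcov(fit$fit)
  if (!is.null(margins)) {
    if (!all(margins %in% facs)) {
      abort(paste("unknown margins:", paste(setdiff(margins, facs), collapse = ", ")))
    }
    key <- interaction(grid[margins], drop = FALSE, lex.order = TRUE)
    W <- t(sapply(levels(key), function(k) colMeans(X[key == k, , drop = FALSE])))
    out <- unique(grid[margins])
    out <- out[order(interaction(out[margins], lex.order = TRUE)), , drop = FALSE]
  } else {
    W <- X
    out <- grid[facs]
  }
  est <- drop(W %*% coef(fit$fit))
  se <- sqrt(rowSums((W %*% V) * W))
  obs_cells <- do.call(paste, c(ev[facs], sep = "\r"))
  res <- tibble::as_tibble(out)
  res$rain_mm <- cov_value
  res$emmean <- unname(est)
  res$se <- unname(se)
  if (is.null(margins)) {
    res$empty_cell <- !(do.call(paste, c(out, sep = "\r")) %in% obs_cells)
    if (any(res$empty_cell)) {
      warn("some reference-grid cells have no observed events; predictions are model-based.")
    }
  }
  structure(res, class = c("marginal_means", class(res)), model = fit$kind)
}

#' BACI interaction contrast from marginal means
#'
#' The before-after-control-impact effect: the change at the impact site
#' minus the change at the control site,
#' `[after - before](impact) - [after - before](control)`, averaged with
#' equal weight over seasons when the model includes them. A negative value
#' means peak flows fell at the impact site relative to the control.
#'
#' @param fit a `baci` or `baci_seasonal` [fit_peakflow_glm()] object.
#' @return A one-row tibble: `estimate`, `se`, `statistic`, `p_value`.
#' @export
baci_contrast <- function(fit) {
  stopifnot(inherits(fit, "peakflow_glm"))
  if (!fit$kind %in% c("baci", "baci_seasonal")) {
    abort("`baci_contrast()` needs a baci or baci_seasonal model.")
  }
  ev <- fit$data
  facs <- intersect(c("beaver", "season", "site"), names(ev))
  grid <- expand.grid(
    lapply(setNames(facs, facs), function(f) levels(factor(ev[[f]]))),
    stringsAsFactors = FALSE
  )
  grid$rain_mm <- mean(ev$rain_mm)
  for (f in facs) grid[[f]] <- factor(grid[[f]], levels = levels(factor(ev[[f]])))
  X <- model.matrix(stats::delete.response(stats::terms(fit$fit)), data = grid)
  sgn_b <- ifelse(grid$beaver == "after", 1, -1)
  sgn_s <- ifelse(grid$site == levels(grid$site)[2], 1, -1)
  w <- sgn_b * sgn_s
  w <- w / (length(w) / 4)        # equal weight over any season levels
  cvec <- drop(crossprod(X, w))
  est <- sum(cvec * coef(fit$fit))
  se <- sqrt(drop(t(cvec) %*% vcov(fit$fit) %*% cvec))
  z <- est / se
  tibble::tibble(
    estimate = est, se = se, statistic = z,
    p_value = 2 * pnorm(-abs(z))
  )
}
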