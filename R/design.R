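#' Study design: impact dates, site roles and the season rule
#'
#' Encodes the before-after(-control-impact) layout: each impact site has a
#' beaver-impact date (events starting at or after it are "after"); control
#' sites carry no impact date of their own but inherit their paired impact
#' site's date so that both arms share the same period labelling. The wet
#' season is the half-year `[1 Oct, 1 Apr)` and the hydrological year starts
#' on 1 October.
#'
#' @param sites data frame with columns `site`, `role` (`"impact"` or
#'   `"control"`), `impact_date` (Date or parseable string; `NA` for
#'   controls) and optionally `paired_with` (the partner site id for
#'   controls).
#' @param wet_start,wet_end month-day strings delimiting the half-open wet
#'   season (defaults `"10-01"`, `"04-01"`).
#' @param hyd_year_start month-day string; the hydrological year increments
#'   here (default `"10-01"`).
#' @return A list of class `study_design`.
#' @export
study_design <- function(sites, wet_start = "10-01", wet_end = "04-01",
                         hyd_year_start = "10-01") {
  if (!is.data.frame(sites) || !all(c("site", "role") %in% names(sites))) {
    abort("`sites` needs at least `site` and `role` columns.")
  }
  if (!all(sites$role %in% c("impact", "control"))) {
    abort("`role` must be 'impact' or 'control'.")
  }
  if (anyDuplicated(sites$site)) abort("duplicate site ids in design.")
  sites <- tibble::as_tibble(sites)
  if (!"impact_date" %in% names(sites)) sites$impact_date <- NA
  sites$impact_date <- as.POSIXct(as.character(sites$impact_date), tz = "UTC")
  if (!"paired_with" %in% names(sites)) sites$paired_with <- NA_character_
  # controls inherit the partner's impact date for period labelling
  for (i in which(sites$role == "control" & is.na(sites$impact_date))) {
    partner <- sites$paired_with[i]
    if (is.na(partner) || !partner %in% sites$site) {
      abort(sprintf(
        "control site '%s' needs `paired_with` naming an impact site.",
        sites$site[i]
      ))
    }
    sites$impact_date[i] <- sites$impact_date[sites$site == partner]
  }
  if (any(sites$role == "impact" & is.na(sites$impact_date))) {
    abort("every impact site must have an impact_date.")
  }
  structure(
    list(sites = sites, wet_start = wet_start, wet_end = wet_end,
         hyd_year_start = hyd_year_start),
    class = "study_design"
  )
}

month_day <- function(t) format(t, "%m-%d")

#' Label events with study factors
#'
#' Adds to an event table: `beaver` (`"before"`/`"after"`, switching at the
#' site's impact date, start-timestamp based), `season` (`"wet"` if the
#' event start's month-day falls in the half-open wet window, else
#' `"dry"`), `hyd_year` (the year the hydrological year ends in: events
#' from 1 Oct 2018 belong to hydrological year 2019) and `role`. Factors
#' use the analysis reference levels: before, dry, control.
#'
#' @param events an [extract_events()] table (possibly several sites bound
#'   together).
#' @param design a [study_design()].
#' @return The event table with factor columns appended.
#' @export
label_events <- function(events, design) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design.")
  if (!all(events$site %in% design$sites$site)) {
    missing <- setdiff(unique(events$site), design$sites$site)
    abort(paste("sites absent from design:", paste(missing, collapse = ", ")))
  }
  info <- design$sites
  idx <- match(events$site, info$site)
  md <- month_day(events$start)
  ws <- design$wet_start
  we <- design$wet_end
  wet <- if (ws > we) (md >= ws | md < we) else (md >= ws & md < we)
  yr <- as.integer(format(events$start, "%Y"))
  hy <- yr + as.integer(month_day(events$start) >= design$hyd_year_start)
  out <- events
  out$beaver <- factor(
    ifelse(events$start >= info$impact_date[idx], "after", "before"),
    levels = c("before", "after")
  )
  out$season <- factor(ifelse(wet, "wet", "dry"), levels = c("dry", "wet"))
  out$hyd_year <- hy
  out$role <- factor(info$role[idx], levels = c("control", "impact"))
  class(out) <- unique(c("event_table", class(out)))
  out
}
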