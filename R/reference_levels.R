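#' @title Reference-level baselines for weekly excess mortality
#' @name reference_levels
#' @description Six baselines against which a target year's weekly mortality
#'   is compared. Three vary by week (week-specific averages, week-specific
#'   OLS trends, week-specific lower-quartile means) and compare the target
#'   year with previous years; three are week-constant within-year
#'   "seasonality" baselines (yearly average-week, summer average-week,
#'   yearly lower-quartile-week).
NULL

.ref_methods <- c(
  wsa = "week_specific_average",
  wst = "week_specific_trend",
  wsq = "week_specific_lower_quartile",
  yaw = "yearly_average_week",
  saw = "summer_average_week",
  ylq = "yearly_lower_quartile_week"
)

#' Winter / non-winter week partition by hemisphere
#'
#' Northern-hemisphere winter covers calendar weeks 1-12 and 48-52; the
#' non-winter ("summer") weeks are 13-47. Southern-hemisphere winter covers
#' weeks 22-38; non-winter weeks are 1-21 and 39-52. Week 53, when present,
#' is treated as winter in the north and non-winter in the south (contiguous
#' with the adjacent year-end weeks).
#'
#' @param hemisphere \code{"north"} or \code{"south"}.
#' @return a list with elements \code{hemisphere}, \code{winter} and
#'   \code{nonwinter} (integer week sets).
#' @export
hemisphere_season <- function(hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  if (hemisphere == "north") {
    winter <- c(1:12, 48:53)
    nonwinter <- 13:47
  } else {
    winter <- 22:38
    nonwinter <- c(1:21, 39:53)
  }
  list(hemisphere = hemisphere, winter = winter, nonwinter = nonwinter)
}

# Known southern-hemisphere STMF country codes; everything else defaults to
# north. Overridable by passing `hemisphere` explicitly.
.southern_codes <- c("AUS", "AUS2", "NZL_NP", "NZL_MA", "CHL", "ZAF")

#' Default hemisphere for an STMF country code
#' @param country country/region code.
#' @return \code{"north"} or \code{"south"}.
#' @export
stmf_hemisphere <- function(country) {
  if (toupper(country) %in% .southern_codes) "south" else "north"
}

#' Default reference period: up to 7 years preceding the target year
#'
#' @param series a \code{weekly_series}.
#' @param target_year the target year.
#' @param max_years maximum number of preceding years to use (default 7).
#' @return sorted integer vector of reference years present in the series.
#' @export
default_reference_years <- function(series, target_year, max_years = 7L) {
  prev <- series$years[series$years < target_year]
  if (!length(prev)) {
    stop_precondition("no years preceding target year %d in series", target_year)
  }
  sort(utils::tail(sort(prev), max_years))
}

.check_period <- function(series, period) {
  period <- sort(unique(as.integer(period)))
  if (!length(period)) stop_precondition("reference period is empty")
  absent <- setdiff(period, series$years)
  if (length(absent)) {
    stop_precondition("reference year(s) not present in series: %s",
                      paste(absent, collapse = ", "))
  }
  period
}

.target_weeks <- function(series, target_year) {
  w <- sort(unique(series$week[series$year == target_year]))
  if (!length(w)) {
    stop_precondition("target year %d not present in series", target_year)
  }
  w
}

# Reference observations for one week across the period, with the week-53
# fallback: if week 53 is requested but fewer than `min_n` reference years
# contain it (most years have 52 ISO weeks), the week-52 observations stand
# in and the week is flagged.
.ref_week_values <- function(series, week, period, min_n = 1L) {
  vals <- .series_week_over_years(series, week, period)
  fallback <- FALSE
  if (length(vals) < min_n && week == 53L) {
    vals <- .series_week_over_years(series, 52L, period)
    fallback <- TRUE
  }
  list(values = vals, fallback = fallback)
}

.new_reference_level <- function(code, target_year, weeks, level, period,
                                 diagnostics = list()) {
  structure(list(
    method = .ref_methods[[code]], code = code,
    target_year = as.integer(target_year),
    weeks = as.integer(weeks),
    level = stats::setNames(as.numeric(level), weeks),
    period = as.integer(period),
    diagnostics = diagnostics
  ), class = "reference_level")
}

#' @export
print.reference_level <- function(x, ...) {
  cat(sprintf("Reference level: %s\n", x$method))
  cat(sprintf("  target year %d, reference period %d-%d (%d year(s)), %d week(s)\n",
              x$target_year, min(x$period), max(x$period), length(x$period),
              length(x$weeks)))
  if (x$code %in% c("yaw", "saw", "ylq")) {
    cat(sprintf("  constant level: %.6g\n", x$level[[1]]))
  } else {
    cat(sprintf("  level range: %.6g to %.6g\n", min(x$level), max(x$level)))
  }
  invisible(x)
}

# ---- the three week-varying baselines ---------------------------------------

# Week-specific averages: per-week arithmetic mean over the reference years.
# Ragged data: the denominator is the number of years actually observed for
# that week, and the shortfall relative to |P| is recorded in diagnostics.
ref_week_average <- function(series, period, target_year, weeks) {
  level <- numeric(length(weeks))
  n_obs <- integer(length(weeks))
  fell <- logical(length(weeks))
  empty <- integer(0)
  for (k in seq_along(weeks)) {
    wv <- .ref_week_values(series, weeks[k], period)
    if (!length(wv$values)) { empty <- c(empty, weeks[k]); next }
    level[k] <- mean(wv$values)
    n_obs[k] <- length(wv$values)
    fell[k] <- wv$fallback
  }
  if (length(empty)) {
    stop_precondition("no reference observations for week(s): %s",
                      paste(empty, collapse = ", "))
  }
  if (any(n_obs < length(period))) {
    message(sprintf("week-specific average: %d week(s) observed in fewer than |P|=%d years",
                    sum(n_obs < length(period)), length(period)))
  }
  .new_reference_level("wsa", target_year, weeks, level, period,
                       list(n_years = stats::setNames(n_obs, weeks),
                            week53_fallback = weeks[fell]))
}

# Week-specific trends: one independent OLS regression per week of the
# measure on calendar year, extrapolated (or interpolated) to the target year.
ref_week_trend <- function(series, period, target_year, weeks) {
  if (length(period) < 2L) {
    stop_precondition(
      "week-specific trend requires at least 2 reference years (got %d)",
      length(period))
  }
  level <- numeric(length(weeks))
  ab <- matrix(NA_real_, length(weeks), 2L,
               dimnames = list(weeks, c("intercept", "slope")))
  fell <- logical(length(weeks))
  for (k in seq_along(weeks)) {
    wv <- .ref_week_values(series, weeks[k], period, min_n = 2L)
    yrs <- as.numeric(names(wv$values))
    if (length(wv$values) < 2L) {
      stop_precondition(
        "week-specific trend: week %d has %d reference observation(s), need >= 2",
        weeks[k], length(wv$values))
    }
    if (length(unique(yrs)) < 2L) {
      stop_precondition("week-specific trend: week %d observed in a single year", weeks[k])
    }
    v <- as.numeric(wv$values)
    if (diff(range(v)) == 0) {
      # constant response: the OLS line is exactly flat; skip the QR fit so
      # no floating-point noise leaks into the extrapolated level
      ab[k, ] <- c(v[1], 0)
      level[k] <- v[1]
    } else {
      # centered covariate for numerical stability; coefficients reported in
      # the calendar-year parameterization
      ym <- mean(yrs)
      fit <- stats::lm.fit(cbind(1, yrs - ym), v)
      b <- fit$coefficients[2L]
      ab[k, ] <- c(fit$coefficients[1L] - b * ym, b)
      level[k] <- fit$coefficients[1L] + b * (target_year - ym)
    }
    fell[k] <- wv$fallback
  }
  .new_reference_level("wst", target_year, weeks, level, period,
                       list(coefficients = ab, week53_fallback = weeks[fell]))
}

# Week-specific lower quartiles: per-week mean of the values at or below the
# per-week lower quartile of the reference years.
ref_week_lower_quartile <- function(series, period, target_year, weeks) {
  level <- numeric(length(weeks))
  q1 <- numeric(length(weeks))
  fell <- logical(length(weeks))
  for (k in seq_along(weeks)) {
    wv <- .ref_week_values(series, weeks[k], period)
    if (!length(wv$values)) {
      stop_precondition("no reference observations for week %d", weeks[k])
    }
    q1[k] <- quantile_linear(as.numeric(wv$values), 0.25)
    level[k] <- mean(wv$values[wv$values <= q1[k]])
    fell[k] <- wv$fallback
  }
  .new_reference_level("wsq", target_year, weeks, level, period,
                       list(lower_quartile = stats::setNames(q1, weeks),
                            week53_fallback = weeks[fell]))
}

# ---- the three week-constant ("seasonality") baselines ----------------------

# Yearly average-week: the mean of the week-specific averages over the weeks
# available in the target year, replicated as a constant level.
ref_yearly_average <- function(series, period, target_year, weeks) {
  wsa <- ref_week_average(series, period, target_year, weeks)
  const <- mean(wsa$level)
  .new_reference_level("yaw", target_year, weeks, rep(const, length(weeks)),
                       period, list(week_averages = wsa$level))
}

# Summer average-week: as above but averaging only the non-winter weeks.
ref_summer_average <- function(series, period, target_year, weeks, season) {
  wstar <- intersect(weeks, season$nonwinter)
  if (!length(wstar)) {
    stop_precondition(paste0(
      "no non-winter weeks available in the target year (%s hemisphere); ",
      "consider the yearly average-week or lower-quartile-week baseline"),
      season$hemisphere)
  }
  wsa <- ref_week_average(series, period, target_year, wstar)
  const <- mean(wsa$level)
  .new_reference_level("saw", target_year, weeks, rep(const, length(weeks)),
                       period, list(week_averages = wsa$level,
                                    nonwinter_weeks = as.integer(wstar),
                                    hemisphere = season$hemisphere))
}

# Yearly lower-quartile-week: one lower quartile over the pooled values of
# all weeks and all reference years; the constant level is the mean of the
# pooled values at or below it.
ref_yearly_lower_quartile <- function(series, period, target_year, weeks) {
  pool <- series$value[series$year %in% period]
  if (!length(pool)) stop_precondition("no observations in the reference period")
  q1 <- quantile_linear(pool, 0.25)
  const <- mean(pool[pool <= q1])
  .new_reference_level("ylq", target_year, weeks, rep(const, length(weeks)),
                       period, list(lower_quartile = q1, pool_size = length(pool)))
}

#' Compute a reference level for a target year
#'
#' Dispatches to one of the six baselines. The reference period defaults to
#' the (up to) 7 years preceding the target year that are present in the
#' series; it may be chosen to include the target year. The weeks default to
#' those available in the target year.
#'
#' @param series a \code{weekly_series} from [select_series()].
#' @param target_year the year compared against the baseline.
#' @param method one of \code{"wsa"} (week-specific average), \code{"wst"}
#'   (week-specific OLS trend), \code{"wsq"} (week-specific lower-quartile
#'   mean), \code{"yaw"} (yearly average-week), \code{"saw"} (summer
#'   average-week), \code{"ylq"} (yearly lower-quartile-week); full method
#'   names are also accepted.
#' @param reference_years integer vector of reference years (the period P);
#'   \code{NULL} for the default.
#' @param weeks integer vector of weeks to evaluate; \code{NULL} for the
#'   weeks available in the target year.
#' @param hemisphere \code{"north"} or \code{"south"}; \code{NULL} to look it
#'   up from the series' country code. Only used by \code{"saw"}.
#' @return an object of class \code{reference_level} with elements
#'   \code{method}, \code{target_year}, \code{weeks}, \code{level} (named by
#'   week; constant across weeks for yaw/saw/ylq), \code{period} and
#'   \code{diagnostics} (per-week fit metadata; OLS coefficients for wst).
#' @export
reference_level <- function(series, target_year, method = "wsa",
                            reference_years = NULL, weeks = NULL,
                            hemisphere = NULL) {
  stopifnot(inherits(series, "weekly_series"))
  code <- if (method %in% names(.ref_methods)) {
    method
  } else if (method %in% .ref_methods) {
    names(.ref_methods)[match(method, .ref_methods)]
  } else {
    stop_validation("unknown method '%s'; available: %s", method,
                    paste(names(.ref_methods), collapse = ", "))
  }
  target_year <- as.integer(target_year)
  period <- if (is.null(reference_years)) {
    default_reference_years(series, target_year)
  } else {
    .check_period(series, reference_years)
  }
  if (is.null(weeks)) weeks <- .target_weeks(series, target_year)
  weeks <- sort(unique(as.integer(weeks)))
  switch(code,
    wsa = ref_week_average(series, period, target_year, weeks),
    wst = ref_week_trend(series, period, target_year, weeks),
    wsq = ref_week_lower_quartile(series, period, target_year, weeks),
    yaw = ref_yearly_average(series, period, target_year, weeks),
    saw = {
      if (is.null(hemisphere)) hemisphere <- stmf_hemisphere(series$country)
      ref_summer_average(series, period, target_year, weeks,
                         hemisphere_season(hemisphere))
    },
    ylq = ref_yearly_lower_quartile(series, period, target_year, weeks)
  )
}
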