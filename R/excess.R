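#' @title Excess mortality: differences, polygons, summaries
#' @name excess
NULL

#' Detect excess/deficit polygons in weekly differences
#'
#' A polygon is a maximal run of consecutive available weeks whose
#' observed-minus-reference difference has a uniform strict sign. Weeks with
#' a difference of exactly zero belong to no polygon and terminate runs, as
#' does a gap in the available weeks.
#'
#' @param weeks strictly increasing integer vector of weeks.
#' @param differences numeric vector of the same length.
#' @return a data frame with columns \code{sign} (\code{"excess"} or
#'   \code{"deficit"}), \code{start_week}, \code{end_week}, \code{length}.
#' @export
detect_polygons <- function(weeks, differences) {
  stopifnot(length(weeks) == length(differences))
  empty <- data.frame(sign = character(0), start_week = integer(0),
                      end_week = integer(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(weeks)) return(empty)
  if (any(diff(weeks) <= 0)) stop_precondition("weeks must be strictly increasing")
  sgn <- sign(differences)
  out <- empty
  run_start <- NA_integer_
  run_sign <- 0
  prev_week <- NA_integer_
  flush <- function() {
    if (!is.na(run_start) && run_sign != 0) {
      out[nrow(out) + 1L, ] <<- list(
        if (run_sign > 0) "excess" else "deficit",
        run_start, prev_week, prev_week - run_start + 1L)
    }
  }
  for (k in seq_along(weeks)) {
    contiguous <- !is.na(prev_week) && weeks[k] == prev_week + 1L
    if (sgn[k] == 0 || !contiguous || sgn[k] != run_sign) {
      flush()
      run_start <- if (sgn[k] != 0) weeks[k] else NA_integer_
      run_sign <- sgn[k]
    }
    prev_week <- weeks[k]
  }
  flush()
  out$start_week <- as.integer(out$start_week)
  out$end_week <- as.integer(out$end_week)
  out$length <- as.integer(out$length)
  out
}

#' Difference a target year against a reference level
#'
#' @param series a \code{weekly_series}.
#' @param target_year the target year; must equal the level's target year.
#' @param level a \code{reference_level}.
#' @return an object of class \code{excess_mort}; see [excess_mortality()].
#' @export
compute_excess <- function(series, target_year, level) {
  stopifnot(inherits(series, "weekly_series"), inherits(level, "reference_level"))
  target_year <- as.integer(target_year)
  if (level$target_year != target_year) {
    stop_precondition("reference level was computed for target year %d, not %d",
                      level$target_year, target_year)
  }
  obs_all <- .series_year(series, target_year)
  missing_w <- setdiff(level$weeks, as.integer(names(obs_all)))
  if (length(missing_w)) {
    stop_precondition("week(s) in reference level absent from target year %d: %s",
                      target_year, paste(missing_w, collapse = ", "))
  }
  observed <- as.numeric(obs_all[as.character(level$weeks)])
  reference <- as.numeric(level$level)
  difference <- observed - reference
  structure(list(
    country = series$country, sex = series$sex,
    measure = series$measure, measure_kind = series$measure_kind,
    target_year = target_year, method = level$method,
    period = level$period,
    weeks = level$weeks, observed = observed, reference = reference,
    difference = difference,
    polygons = detect_polygons(level$weeks, difference),
    level = level, series = series
  ), class = "excess_mort")
}

#' Estimate weekly excess mortality for a target year
#'
#' The main fitting function: extracts nothing itself but chains
#' [reference_level()] and [compute_excess()] on an already selected weekly
#' series. The result holds the per-week observed values, the reference
#' level, their exact differences, and the detected excess/deficit polygons.
#'
#' @inheritParams reference_level
#' @return an object of class \code{excess_mort} with methods
#'   \code{print}, \code{summary}, \code{coef} (OLS coefficients for the
#'   trend baseline, otherwise the level), \code{fitted} (the reference
#'   level), \code{residuals} (the weekly differences), \code{plot} and
#'   \code{as.data.frame}.
#' @export
#' @examples
#' cfg <- synthetic_config(years = 2015:2020, alpha = 1000, gamma = 0.2,
#'                         shock = list(year = 2020, week_from = 10, week_to = 22,
#'                                      deaths = 1300, shape = "flat"),
#'                         noise = "none", seed = 1)
#' tab <- generate_stmf(cfg)
#' s <- select_series(tab, "SYN", "b", "dtotal")
#' fit <- excess_mortality(s, 2020, method = "wsa")
#' summary(fit)
excess_mortality <- function(series, target_year, method = "wsa",
                             reference_years = NULL, weeks = NULL,
                             hemisphere = NULL) {
  if (is.null(weeks)) weeks <- .target_weeks(series, target_year)
  lvl <- reference_level(series, target_year, method = method,
                         reference_years = reference_years, weeks = weeks,
                         hemisphere = hemisphere)
  compute_excess(series, target_year, lvl)
}

#' Summarize excess mortality over a week selection
#'
#' Totals over a user-selected window of weeks: sums for death counts, means
#' for weekly death rates. Weeks in the window that are not available in the
#' result are excluded and reported.
#'
#' @param result an \code{excess_mort}.
#' @param week_from,week_to inclusive window bounds (default: full range).
#' @return a list with \code{observed_total}, \code{reference_total},
#'   \code{excess_total}, the \code{weeks} used, any \code{excluded} weeks of
#'   the window, and the \code{kind} of total (\code{"sum"} or \code{"mean"}).
#' @export
summarize_selection <- function(result, week_from = min(result$weeks),
                                week_to = max(result$weeks)) {
  stopifnot(inherits(result, "excess_mort"))
  window <- seq.int(week_from, week_to)
  sel <- result$weeks %in% window
  if (!any(sel)) {
    stop_precondition("selection weeks %d-%d do not intersect result weeks %d-%d",
                      week_from, week_to, min(result$weeks), max(result$weeks))
  }
  agg <- if (result$measure_kind == "count") sum else mean
  list(
    observed_total = agg(result$observed[sel]),
    reference_total = agg(result$reference[sel]),
    excess_total = agg(result$difference[sel]),
    weeks = result$weeks[sel],
    excluded = setdiff(window, result$weeks),
    kind = if (result$measure_kind == "count") "sum" else "mean"
  )
}

#' Find the data point nearest to a query location
#'
#' Emulates click-point lookup on a week-by-value plot: returns the series
#' point minimizing Euclidean distance after per-axis normalization. Exact
#' ties are broken in favour of the earlier year, then the earlier week.
#'
#' @param series a non-empty \code{weekly_series}.
#' @param query_week,query_value query coordinates in data units.
#' @param scale optional list with elements \code{week} and \code{value}
#'   giving the per-axis normalization divisors; defaults to the data ranges.
#' @return a list with \code{year}, \code{week}, \code{value}, \code{distance}.
#' @export
nearest_point <- function(series, query_week, query_value, scale = NULL) {
  stopifnot(inherits(series, "weekly_series"))
  if (!length(series$value)) stop_precondition("series is empty")
  if (is.null(scale)) {
    scale <- list(week = max(diff(range(series$week)), 1),
                  value = max(diff(range(series$value)), 1))
  }
  ord <- order(series$year, series$week)
  d2 <- ((series$week[ord] - query_week) / scale$week)^2 +
        ((series$value[ord] - query_value) / scale$value)^2
  k <- which.min(d2)  # first minimum = earliest (year, week) on ties
  list(year = series$year[ord][k], week = series$week[ord][k],
       value = series$value[ord][k], distance = sqrt(d2[k]))
}

# ---- S3 methods --------------------------------------------------------------

#' @export
print.excess_mort <- function(x, ...) {
  cat(sprintf("Weekly excess mortality: %s, sex=%s, measure=%s\n",
              x$country, x$sex, x$measure))
  cat(sprintf("  target year %d vs %s over %d-%d\n", x$target_year, x$method,
              min(x$period), max(x$period)))
  s <- summarize_selection(x)
  cat(sprintf("  %d week(s); total excess (%s of differences): %.6g\n",
              length(x$weeks), s$kind, s$excess_total))
  cat(sprintf("  %d excess / %d deficit polygon(s)\n",
              sum(x$polygons$sign == "excess"), sum(x$polygons$sign == "deficit")))
  invisible(x)
}

#' @export
summary.excess_mort <- function(object, week_from = min(object$weeks),
                                week_to = max(object$weeks), ...) {
  structure(list(
    fit = object,
    selection = summarize_selection(object, week_from, week_to),
    week_from = week_from, week_to = week_to
  ), class = "summary.excess_mort")
}

#' @export
print.summary.excess_mort <- function(x, ...) {
  print(x$fit)
  s <- x$selection
  cat(sprintf("\nSelection weeks %d-%d (%s over %d available week(s)):\n",
              x$week_from, x$week_to, s$kind, length(s$weeks)))
  cat(sprintf("  observed:  %.6g\n  reference: %.6g\n  excess:    %.6g\n",
              s$observed_total, s$reference_total, s$excess_total))
  if (length(s$excluded)) {
    cat("  excluded (unavailable) weeks: ", paste(s$excluded, collapse = ", "), "\n")
  }
  if (nrow(x$fit$polygons)) {
    cat("\nPolygons:\n")
    print(x$fit$polygons, row.names = FALSE)
  } else {
    cat("\nNo excess or deficit polygons.\n")
  }
  invisible(x)
}

#' @export
coef.excess_mort <- function(object, ...) {
  if (object$level$code == "wst") object$level$diagnostics$coefficients
  else object$level$level
}

#' @export
fitted.excess_mort <- function(object, ...) {
  stats::setNames(object$reference, object$weeks)
}

#' @export
residuals.excess_mort <- function(object, ...) {
  stats::setNames(object$difference, object$weeks)
}

#' Tidy per-week representation of an excess-mortality fit
#'
#' @param x an \code{excess_mort}.
#' @param ... unused.
#' @return data frame with columns \code{week}, \code{observed},
#'   \code{reference}, \code{difference}, \code{polygon_id} (NA for weeks in
#'   no polygon) and \code{polygon_sign}.
#' @export
as.data.frame.excess_mort <- function(x, ...) {
  df <- data.frame(week = x$weeks, observed = x$observed,
                   reference = x$reference, difference = x$difference,
                   polygon_id = NA_integer_, polygon_sign = NA_character_,
                   stringsAsFactors = FALSE)
  if (nrow(x$polygons)) {
    for (p in seq_len(nrow(x$polygons))) {
      sel <- df$week >= x$polygons$start_week[p] & df$week <= x$polygons$end_week[p]
      df$polygon_id[sel] <- p
      df$polygon_sign[sel] <- x$polygons$sign[p]
    }
  }
  df
}

#' Write the tidy per-week excess table to CSV
#'
#' @param result an \code{excess_mort}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_excess_csv <- function(result, path) {
  df <- as.data.frame(result)
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_validation("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  writeLines("week,observed,reference,difference,polygon_id,polygon_sign", con)
  if (nrow(df)) {
    writeLines(paste(
      .fmt_num(df$week), .fmt_num(df$observed), .fmt_num(df$reference),
      .fmt_num(df$difference),
      ifelse(is.na(df$polygon_id), "", as.character(df$polygon_id)),
      ifelse(is.na(df$polygon_sign), "", df$polygon_sign),
      sep = ","), con)
  }
  invisible(path)
}
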