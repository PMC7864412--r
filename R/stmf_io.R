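#' @title STMF-style table input/output
#' @name stmf_io
#' @description Read, validate and write weekly mortality tables in the
#'   STMF CSV dialect, and extract single weekly series from them.
NULL

# Canonical column order of the STMF CSV dialect.
.stmf_cols <- c(
  "CountryCode", "Year", "Week", "Sex",
  "D0_14", "D15_64", "D65_74", "D75_84", "D85p", "DTotal",
  "R0_14", "R15_64", "R65_74", "R75_84", "R85p", "RTotal"
)
.stmf_death_cols <- c("D0_14", "D15_64", "D65_74", "D75_84", "D85p", "DTotal")
.stmf_rate_cols  <- c("R0_14", "R15_64", "R65_74", "R75_84", "R85p", "RTotal")

# Measure codes exposed to users (12 = {count,rate} x {5 age groups, total}).
.stmf_measures <- c(
  d0_14 = "D0_14", d15_64 = "D15_64", d65_74 = "D65_74",
  d75_84 = "D75_84", d85p = "D85p", dtotal = "DTotal",
  r0_14 = "R0_14", r15_64 = "R15_64", r65_74 = "R65_74",
  r75_84 = "R75_84", r85p = "R85p", rtotal = "RTotal"
)

#' Number of ISO-8601 weeks in a calendar year
#'
#' A year has 53 ISO weeks when 1 January or 31 December falls on a Thursday
#' (e.g. 2015, 2020); otherwise it has 52.
#'
#' @param year integer vector of calendar years.
#' @return integer vector of 52 or 53.
#' @export
#' @examples
#' iso_weeks_in_year(2019:2021)  # 52 53 52
iso_weeks_in_year <- function(year) {
  if (!length(year)) return(integer(0))
  wd <- function(d) as.POSIXlt(d)$wday  # 0 = Sunday, 4 = Thursday
  jan1 <- as.Date(paste0(year, "-01-01"))
  dec31 <- as.Date(paste0(year, "-12-31"))
  ifelse(wd(jan1) == 4L | wd(dec31) == 4L, 53L, 52L)
}

.validate_stmf <- function(df, strict, source = "table") {
  drop <- rep(FALSE, nrow(df))
  note <- character(0)
  bad_row <- function(idx, why) {
    if (strict) {
      stop_validation("%s: row %d invalid: %s", source, idx[1], why)
    }
    drop[idx] <<- TRUE
    note <<- c(note, sprintf("%d row(s) dropped: %s", length(idx), why))
  }

  num_cols <- c(.stmf_death_cols, .stmf_rate_cols)
  vals <- as.matrix(df[num_cols])
  nonfinite <- which(apply(!is.finite(vals), 1L, any))
  if (length(nonfinite)) bad_row(nonfinite, "non-finite or missing value")
  neg <- setdiff(which(apply(vals < 0, 1L, any)), nonfinite)
  if (length(neg)) bad_row(neg, "negative value")

  ok <- !drop
  badweek <- which(ok & (df$Week < 1L | df$Week > 53L | df$Week != round(df$Week)))
  if (length(badweek)) bad_row(badweek, "week outside 1..53")
  ok <- !drop
  w53 <- which(ok & df$Week == 53L & iso_weeks_in_year(df$Year) != 53L)
  if (length(w53)) bad_row(w53, "week 53 in a 52-week ISO year")
  ok <- !drop
  badyear <- which(ok & (df$Year < 1990L | df$Year != round(df$Year)))
  if (length(badyear)) bad_row(badyear, "year outside supported range (>= 1990)")
  ok <- !drop
  badsex <- which(ok & !(df$Sex %in% c("f", "m", "b")))
  if (length(badsex)) bad_row(badsex, "sex not one of f/m/b")

  ok <- !drop
  agemax <- do.call(pmax, df[c("D0_14", "D15_64", "D65_74", "D75_84", "D85p")])
  badtot <- which(ok & df$DTotal < agemax - 1e-9)
  if (length(badtot)) bad_row(badtot, "DTotal below an age-group count")

  ok <- !drop
  key <- paste(df$CountryCode, df$Year, df$Week, df$Sex)
  dupe <- which(ok & duplicated(key) & !drop)
  dupe <- dupe[!drop[dupe]]
  if (length(dupe)) {
    if (strict) {
      stop_validation("%s: duplicate (country, year, week, sex) key at row %d: %s",
                      source, dupe[1], key[dupe[1]])
    }
    bad_row(dupe, "duplicate (country, year, week, sex) key")
  }

  if (length(note)) message(source, ": ", paste(unique(note), collapse = "; "))
  df[!drop, , drop = FALSE]
}

.as_stmf_table <- function(df) {
  df$Year <- as.integer(df$Year)
  df$Week <- as.integer(df$Week)
  df$Sex <- tolower(as.character(df$Sex))
  df$CountryCode <- as.character(df$CountryCode)
  for (cc in c(.stmf_death_cols, .stmf_rate_cols)) df[[cc]] <- as.numeric(df[[cc]])
  df <- df[order(df$CountryCode, df$Year, df$Week, df$Sex), .stmf_cols, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("stmf_table", "data.frame")
  df
}

#' Construct a validated STMF table from a data frame
#'
#' @param df data frame with the canonical STMF columns.
#' @param strict logical; abort on any invariant violation (default) or drop
#'   offending rows with a message.
#' @return an object of class \code{stmf_table} (a data frame).
#' @export
stmf_table <- function(df, strict = TRUE) {
  missing_cols <- setdiff(.stmf_cols, names(df))
  if (length(missing_cols)) {
    stop_validation("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), .stmf_cols)
  if (length(extra)) {
    message("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  df <- df[.stmf_cols]
  df$Sex <- tolower(as.character(df$Sex))
  for (cc in c("Year", "Week")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (strict && anyNA(v)) stop_validation("non-numeric %s at row %d", cc, which(is.na(v))[1])
    df[[cc]] <- v
  }
  for (cc in c(.stmf_death_cols, .stmf_rate_cols)) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    df[[cc]] <- v
  }
  df <- .validate_stmf(df, strict = strict)
  .as_stmf_table(df)
}

#' Read an STMF-style CSV file
#'
#' Expects the canonical header
#' \code{CountryCode,Year,Week,Sex,D0_14,...,DTotal,R0_14,...,RTotal}.
#' Extra columns are ignored with a message. Sex codes are case-insensitive.
#'
#' @param path path to a CSV file (UTF-8, comma separated, \code{.} decimal).
#' @param strict logical; in strict mode (default) any invariant violation
#'   aborts with a validation error; in lenient mode offending rows are
#'   dropped and counted in a message.
#' @return an \code{stmf_table}.
#' @seealso [write_stmf_csv()], [select_series()]
#' @export
read_stmf_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  missing_cols <- setdiff(.stmf_cols, names(df))
  if (length(missing_cols)) {
    stop_validation("%s: missing required column(s): %s",
                    path, paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), .stmf_cols)
  if (length(extra)) message(path, ": ignoring extra column(s): ", paste(extra, collapse = ", "))
  df <- df[.stmf_cols]
  df$Sex <- tolower(as.character(df$Sex))
  for (cc in c("Year", "Week", .stmf_death_cols, .stmf_rate_cols)) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df <- .validate_stmf(df, strict = strict, source = path)
  .as_stmf_table(df)
}

# Deterministic decimal formatting: integers without a decimal point, other
# values at full double precision. A value always reprints identically after
# a read/parse cycle, which gives the byte-identical write-read-write law.
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) < 2^53) {
      sprintf("%.0f", v)
    } else {
      format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }
  }, character(1))
  out
}

#' Write an STMF table to CSV
#'
#' The inverse of [read_stmf_csv()]: \code{read_stmf_csv(write_stmf_csv(t))}
#' reproduces \code{t}, and a second write of the re-read table is
#' byte-identical to the first.
#'
#' @param table an \code{stmf_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stmf_csv <- function(table, path) {
  stopifnot(inherits(table, "stmf_table"))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_validation("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(paste(.stmf_cols, collapse = ","), con)
  if (nrow(table)) {
    cells <- cbind(
      table$CountryCode, .fmt_num(table$Year), .fmt_num(table$Week), table$Sex,
      do.call(cbind, lapply(table[c(.stmf_death_cols, .stmf_rate_cols)], .fmt_num))
    )
    writeLines(apply(cells, 1L, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Extract one weekly series from an STMF table
#'
#' Picks a single (country, sex, measure) slice and returns it as a mapping
#' from (year, week) to the measure value. Only cells present in the table
#' appear; nothing is imputed.
#'
#' @param table an \code{stmf_table}.
#' @param country country/region code, e.g. \code{"GBRTENW"}.
#' @param sex one of \code{"f"}, \code{"m"}, \code{"b"}.
#' @param measure one of the 12 measure codes \code{d0_14, d15_64, d65_74,
#'   d75_84, d85p, dtotal, r0_14, ..., rtotal} (counts resp. weekly rates).
#' @return an object of class \code{weekly_series}: a list with elements
#'   \code{country}, \code{sex}, \code{measure}, \code{measure_kind}
#'   (\code{"count"} or \code{"rate"}), and parallel vectors \code{year},
#'   \code{week}, \code{value} sorted by (year, week); \code{years} is the
#'   sorted set of available years.
#' @export
select_series <- function(table, country, sex, measure) {
  stopifnot(inherits(table, "stmf_table"))
  sex <- tolower(sex)
  measure <- tolower(measure)
  if (!country %in% unique(table$CountryCode)) {
    stop_validation("unknown country '%s'; available: %s",
                    country, paste(sort(unique(table$CountryCode)), collapse = ", "))
  }
  if (!sex %in% c("f", "m", "b")) {
    stop_validation("unknown sex '%s'; available: f, m, b", sex)
  }
  if (!measure %in% names(.stmf_measures)) {
    stop_validation("unknown measure '%s'; available: %s",
                    measure, paste(names(.stmf_measures), collapse = ", "))
  }
  sub <- table[table$CountryCode == country & table$Sex == sex, , drop = FALSE]
  if (!nrow(sub)) {
    stop_validation("no rows for country '%s', sex '%s'", country, sex)
  }
  col <- .stmf_measures[[measure]]
  structure(list(
    country = country, sex = sex, measure = measure,
    measure_kind = if (startsWith(measure, "d")) "count" else "rate",
    year = sub$Year, week = sub$Week, value = sub[[col]],
    years = sort(unique(sub$Year))
  ), class = "weekly_series")
}

#' @export
print.weekly_series <- function(x, ...) {
  cat(sprintf("Weekly mortality series: %s, sex=%s, measure=%s (%s)\n",
              x$country, x$sex, x$measure, x$measure_kind))
  cat(sprintf("  %d observations over years %s-%s\n",
              length(x$value), min(x$years), max(x$years)))
  invisible(x)
}

# Values of a series for one year, as a named vector by week.
.series_year <- function(series, year) {
  sel <- series$year == year
  stats::setNames(series$value[sel], series$week[sel])
}

# Values for one week across a set of years (only where present).
.series_week_over_years <- function(series, week, years) {
  sel <- series$week == week & series$year %in% years
  stats::setNames(series$value[sel], series$year[sel])
}
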