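# Builders for weekly series and STMF tables used across the tests.

# A weekly_series straight from a data.frame(year, week, value).
mk_series <- function(df, country = "SYN", sex = "b", measure = "dtotal") {
  df <- df[order(df$year, df$week), , drop = FALSE]
  structure(list(
    country = country, sex = sex, measure = measure,
    measure_kind = if (startsWith(measure, "d")) "count" else "rate",
    year = as.integer(df$year), week = as.integer(df$week),
    value = as.numeric(df$value), years = sort(unique(as.integer(df$year)))
  ), class = "weekly_series")
}

# Series with the same per-week values replicated across years.
mk_series_weeks <- function(week_values, years) {
  df <- expand.grid(week = as.integer(names(week_values)), year = years)
  df$value <- week_values[as.character(df$week)]
  mk_series(df)
}

# A full STMF data frame (all 16 columns) from totals; age groups split by
# fixed proportions so the DTotal invariant holds.
mk_stmf_df <- function(country, years, weeks, sexes = "b", total = 100,
                       population = 1e5) {
  grid <- expand.grid(CountryCode = country, Year = years, Week = weeks,
                      Sex = sexes, stringsAsFactors = FALSE)
  props <- c(D0_14 = 0.005, D15_64 = 0.105, D65_74 = 0.15,
             D75_84 = 0.27, D85p = 0.47)
  tot <- rep_len(total, nrow(grid))
  for (g in names(props)) grid[[g]] <- tot * props[[g]]
  grid$DTotal <- tot
  for (g in names(props)) grid[[sub("^D", "R", g)]] <- grid[[g]] / population
  grid$RTotal <- grid$DTotal / population
  grid
}

# Random ragged series instance for property tests. Returns the series plus
# the target year, reference period and target weeks, guaranteeing every
# target week keeps >= 2 reference observations (so all six baselines apply).
random_instance <- function(include_week53 = TRUE) {
  n_years <- sample(4:10, 1)
  years <- seq(2010, length.out = n_years)
  n_weeks <- sample(8:52, 1)
  weeks <- sort(sample(1:52, n_weeks))
  # keep at least one non-winter week so the summer baseline is defined
  if (!any(weeks %in% 13:47)) weeks <- sort(c(weeks, sample(13:47, 1)))
  df <- expand.grid(year = years, week = weeks)
  df$value <- round(stats::rlnorm(nrow(df), log(100), 0.3), 4)
  if (include_week53 && stats::runif(1) < 0.3 && 52 %in% weeks) {
    w53_years <- sample(years, sample(0:2, 1))
    tgt53 <- max(years)
    for (y in unique(c(w53_years, tgt53))) {
      df <- rbind(df, data.frame(year = y, week = 53,
                                 value = round(stats::rlnorm(1, log(100), 0.3), 4)))
    }
  }
  target <- max(years)
  period <- years[years < target]
  # rag the reference data: drop cells while keeping > 3 reference years per
  # week, so every target week retains enough observations for all baselines
  drop <- logical(nrow(df))
  for (k in sample(which(df$year != target))) {
    w <- df$week[k]
    n_ref <- sum(df$year %in% period & df$week == w & !drop)
    if (n_ref > 3 && stats::runif(1) < 0.15) drop[k] <- TRUE
  }
  df <- df[!drop, , drop = FALSE]
  tw <- sort(df$week[df$year == target])
  list(series = mk_series(df), df = df, target = target,
       period = period, weeks = tw)
}
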