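#' @title Synthetic STMF-format data with known ground truth
#' @name synthetic_data
#' @description Generates weekly mortality tables with a configurable linear
#'   trend, 52-week cosine seasonality, an optional epidemic shock of known
#'   total size, and optional Poisson count noise, so every baseline and the
#'   excess pipeline can be validated against exact ground truth.
NULL

# Fixed age-group split of the total (elderly-heavy, plausible but arbitrary).
.age_props <- c(D0_14 = 0.005, D15_64 = 0.105, D65_74 = 0.15,
                D75_84 = 0.27, D85p = 0.47)

#' Configuration for the synthetic weekly mortality generator
#'
#' Expected weekly deaths follow
#' \deqn{\mu_{ij} = (\alpha + \beta (j - j_0)) (1 + \gamma \cos(2\pi (i - \phi)/52)),}
#' where \eqn{j_0} is the first year: a linear annual trend modulated by
#' cosine seasonality peaking at week \eqn{\phi}. An optional shock adds a
#' known total of extra deaths over a window of weeks within one year,
#' allocated flat or triangularly. Years with 53 ISO weeks get week 53 with
#' the week-52 seasonal factor.
#'
#' @param years integer vector of consecutive calendar years.
#' @param alpha baseline expected weekly deaths (> 0).
#' @param beta additive change in expected weekly deaths per year.
#' @param gamma seasonal amplitude in [0, 1).
#' @param phi seasonal peak week (default 2, so northern winter is elevated).
#' @param shock \code{NULL} or a list with \code{year}, \code{week_from},
#'   \code{week_to}, \code{deaths} (total extra deaths K >= 0) and
#'   \code{shape} (\code{"flat"} or \code{"triangular"}).
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param population person-weeks of exposure, used for the rate columns.
#' @param country country code written into the table.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return a validated \code{synthetic_config} list.
#' @export
synthetic_config <- function(years, alpha = 1000, beta = 0, gamma = 0.15,
                             phi = 2, shock = NULL, noise = c("none", "poisson"),
                             population = 1e6, country = "SYN", seed = 1L) {
  noise <- match.arg(noise)
  years <- sort(as.integer(years))
  if (!length(years)) stop_validation("years must be non-empty")
  if (!isTRUE(alpha > 0)) stop_validation("alpha must be positive")
  if (!isTRUE(gamma >= 0 && gamma < 1)) stop_validation("gamma must be in [0, 1)")
  if (!isTRUE(population > 0)) stop_validation("population must be positive")
  cfg <- list(years = years, alpha = alpha, beta = beta, gamma = gamma,
              phi = phi, shock = shock, noise = noise,
              population = population, country = country,
              seed = as.integer(seed))
  # expected deaths must be positive everywhere
  mu <- outer(seq_along(years) - 1L, 1:53,
              function(dy, i) (alpha + beta * dy) *
                (1 + gamma * cos(2 * pi * (pmin(i, 52) - phi) / 52)))
  if (any(mu <= 0)) {
    stop_validation("trend/seasonality yields non-positive expected deaths")
  }
  if (!is.null(shock)) {
    need <- c("year", "week_from", "week_to", "deaths")
    if (!all(need %in% names(shock))) {
      stop_validation("shock needs fields: %s", paste(need, collapse = ", "))
    }
    if (is.null(shock$shape)) cfg$shock$shape <- "flat"
    if (!cfg$shock$shape %in% c("flat", "triangular")) {
      stop_validation("shock shape must be 'flat' or 'triangular'")
    }
    if (!shock$year %in% years) stop_validation("shock year not in years")
    nw <- iso_weeks_in_year(shock$year)
    if (shock$week_from < 1 || shock$week_to > nw || shock$week_from > shock$week_to) {
      stop_validation("shock window must lie within weeks 1..%d of %d", nw, shock$year)
    }
    if (shock$deaths < 0) stop_validation("shock deaths must be >= 0")
  }
  structure(cfg, class = "synthetic_config")
}

# Per-week shock allocation over the window; sums exactly to K.
.shock_weights <- function(shock) {
  wks <- seq.int(shock$week_from, shock$week_to)
  n <- length(wks)
  w <- if (identical(shock$shape, "triangular")) {
    h <- (n + 1) / 2
    raw <- h - abs(seq_len(n) - h)
    raw / sum(raw)
  } else {
    rep(1 / n, n)
  }
  stats::setNames(shock$deaths * w, wks)
}

#' Expected weekly deaths under a synthetic configuration (noise-free)
#' @param config a \code{synthetic_config}.
#' @param year,week vectors (recycled) of year/week to evaluate.
#' @return numeric vector of expected deaths, shock included.
#' @export
synthetic_mean <- function(config, year, week) {
  dy <- year - config$years[1]
  i_eff <- pmin(week, 52)  # week 53 reuses the week-52 seasonal factor
  mu <- (config$alpha + config$beta * dy) *
    (1 + config$gamma * cos(2 * pi * (i_eff - config$phi) / 52))
  if (!is.null(config$shock)) {
    w <- .shock_weights(config$shock)
    hit <- year == config$shock$year & week %in% as.integer(names(w))
    mu[hit] <- mu[hit] + w[as.character(week[hit])]
  }
  mu
}

#' Generate a synthetic STMF table
#'
#' @param config a \code{synthetic_config}.
#' @return an \code{stmf_table} with one row per (year, week) and sex
#'   \code{"b"}; age-group counts are fixed proportions of the total, rates
#'   are counts divided by the configured population.
#' @export
generate_stmf <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  rows <- do.call(rbind, lapply(config$years, function(y) {
    data.frame(Year = y, Week = seq_len(iso_weeks_in_year(y)))
  }))
  mu <- synthetic_mean(config, rows$Year, rows$Week)
  total <- if (config$noise == "poisson") as.numeric(stats::rpois(length(mu), mu)) else mu
  df <- data.frame(CountryCode = config$country, Year = rows$Year,
                   Week = rows$Week, Sex = "b", stringsAsFactors = FALSE)
  for (g in names(.age_props)) df[[g]] <- total * .age_props[[g]]
  df$DTotal <- total
  for (g in names(.age_props)) {
    df[[sub("^D", "R", g)]] <- df[[g]] / config$population
  }
  df$RTotal <- df$DTotal / config$population
  stmf_table(df, strict = TRUE)
}

#' Ground-truth shock deaths in a week window
#'
#' The exact, noise-free number of shock deaths the generator allocated to
#' weeks \code{week_from..week_to} of the shock year.
#'
#' @param config a \code{synthetic_config} with a shock.
#' @param week_from,week_to inclusive window.
#' @return a number.
#' @export
ground_truth_excess <- function(config, week_from, week_to) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$shock)) stop_precondition("configuration has no shock")
  w <- .shock_weights(config$shock)
  sel <- as.integer(names(w)) >= week_from & as.integer(names(w)) <= week_to
  sum(w[sel])
}
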