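# Hand-computed cases for each baseline, then property checks against the
# independent brute-force oracle in helper-oracle.R.

test_that("week-specific average is the per-week mean over the period", {
  s <- mk_series(data.frame(year = c(2018, 2019), week = 1, value = c(100, 110)))
  lv <- reference_level(s, 2019, "wsa", reference_years = 2018:2019, weeks = 1)
  expect_equal(unname(lv$level), 105)

  s2 <- mk_series(data.frame(year = 2015:2019, week = 1, value = c(90, 95, 100, 105, 110)))
  lv2 <- reference_level(s2, 2019, "wsa", reference_years = 2015:2019, weeks = 1)
  expect_equal(unname(lv2$level), 100)

  # singleton period: the level is that year's series on shared weeks
  s3 <- mk_series_weeks(c(`1` = 80, `2` = 90, `3` = 85), years = 2019:2020)
  lv3 <- reference_level(s3, 2020, "wsa", reference_years = 2019)
  expect_equal(unname(lv3$level), c(80, 90, 85))
})

test_that("week-specific trend extrapolates one OLS line per week", {
  s <- mk_series(data.frame(year = 2017:2019, week = 1, value = c(100, 102, 104)))
  lv <- reference_level(s, 2020, "wst", reference_years = 2017:2019, weeks = 1)
  expect_equal(unname(lv$level), 106)  # exact collinear fit
  expect_equal(unname(lv$diagnostics$coefficients[1, "slope"]), 2)

  s2 <- mk_series(data.frame(year = 2016:2019, week = 1, value = c(10, 20, 10, 20)))
  lv2 <- reference_level(s2, 2020, "wst", reference_years = 2016:2019, weeks = 1)
  expect_equal(unname(lv2$level), 20)  # slope 2, mean 15 at 2017.5 -> 15 + 2*2.5

  s3 <- mk_series(data.frame(year = 2016:2019, week = 1, value = 50))
  lv3 <- reference_level(s3, 2020, "wst", reference_years = 2016:2019, weeks = 1)
  expect_equal(unname(lv3$level), 50)

  expect_error(reference_level(s, 2020, "wst", reference_years = 2019, weeks = 1),
               "at least 2", class = "stmf_precondition_error")
  # a week observed in a single reference year
  s4 <- mk_series(data.frame(year = c(2017, 2018, 2018), week = c(1, 1, 2),
                             value = c(1, 2, 3)))
  expect_error(reference_level(s4, 2020, "wst", reference_years = 2017:2018,
                               weeks = 1:2),
               "week 2", class = "stmf_precondition_error")
})

test_that("week-specific lower quartile averages the values at or below Q1", {
  s <- mk_series(data.frame(year = 2012:2019, week = 1,
                            value = c(90, 92, 95, 100, 105, 110, 115, 120)))
  lv <- reference_level(s, 2019, "wsq", reference_years = 2012:2019, weeks = 1)
  expect_equal(unname(lv$level), 91)  # Q1 = 94.25, mean of {90, 92}
  expect_equal(unname(lv$diagnostics$lower_quartile), 94.25)

  s2 <- mk_series(data.frame(year = 2016:2019, week = 1, value = 100))
  lv2 <- reference_level(s2, 2019, "wsq", reference_years = 2016:2019, weeks = 1)
  expect_equal(unname(lv2$level), 100)  # all values tie at Q1

  s3 <- mk_series(data.frame(year = 2016:2019, week = 1, value = c(1, 2, 3, 4)))
  lv3 <- reference_level(s3, 2019, "wsq", reference_years = 2016:2019, weeks = 1)
  expect_equal(unname(lv3$level), 1)  # Q1 = 1.75, L = {1}
})

test_that("yearly average-week is the constant mean of week averages over W", {
  s <- mk_series_weeks(stats::setNames(1:4, 1:4), years = 2018:2020)
  lv <- reference_level(s, 2020, "yaw", reference_years = 2018:2019)
  expect_equal(unname(lv$level), rep(2.5, 4))

  s2 <- mk_series_weeks(stats::setNames(1:10, 1:10), years = 2018:2020)
  lv2 <- reference_level(s2, 2020, "yaw", reference_years = 2018:2019)
  expect_equal(unname(lv2$level), rep(5.5, 10))
  expect_equal(length(unique(lv2$level)), 1L)
})

test_that("summer average-week excludes winter weeks by hemisphere", {
  # x_i = 1 on northern winter weeks, 0 elsewhere
  wv <- stats::setNames(ifelse(1:52 %in% c(1:12, 48:52), 1, 0), 1:52)
  s <- mk_series_weeks(wv, years = 2018:2020)
  lv <- reference_level(s, 2020, "saw", reference_years = 2018:2019,
                        hemisphere = "north")
  expect_equal(unname(lv$level), rep(0, 52))

  # x_i = i: the northern summer mean is mean(13:47) = 30
  s2 <- mk_series_weeks(stats::setNames(1:52, 1:52), years = 2018:2020)
  lv2 <- reference_level(s2, 2020, "saw", reference_years = 2018:2019,
                         hemisphere = "north")
  expect_equal(unname(lv2$level), rep(30, 52))

  # constant series: the constant, either hemisphere
  s3 <- mk_series_weeks(stats::setNames(rep(7, 52), 1:52), years = 2018:2020)
  for (h in c("north", "south")) {
    lv3 <- reference_level(s3, 2020, "saw", reference_years = 2018:2019,
                           hemisphere = h)
    expect_equal(unname(lv3$level), rep(7, 52))
  }

  # nothing but winter weeks available -> advisory error
  s4 <- mk_series_weeks(stats::setNames(rep(1, 5), 1:5), years = 2018:2020)
  expect_error(reference_level(s4, 2020, "saw", reference_years = 2018:2019,
                               hemisphere = "north"),
               "non-winter", class = "stmf_precondition_error")
})

test_that("yearly lower-quartile-week pools all weeks of the period", {
  df <- data.frame(year = rep(2018:2019, each = 4), week = rep(1:4, 2),
                   value = 1:8)
  s <- mk_series(rbind(df, data.frame(year = 2020, week = 1:4, value = 9:12)))
  lv <- reference_level(s, 2020, "ylq", reference_years = 2018:2019)
  expect_equal(unname(lv$level), rep(1.5, 4))  # Q1 = 2.75, mean of {1, 2}

  df2 <- data.frame(year = 2019, week = 1:4, value = c(10, 10, 10, 1000))
  s2 <- mk_series(rbind(df2, data.frame(year = 2020, week = 1:4, value = 1)))
  lv2 <- reference_level(s2, 2020, "ylq", reference_years = 2019)
  expect_equal(unname(lv2$level), rep(10, 4))  # Q1 = 10, mean of the three 10s

  s3 <- mk_series_weeks(stats::setNames(rep(42, 6), 1:6), years = 2018:2020)
  lv3 <- reference_level(s3, 2020, "ylq", reference_years = 2018:2019)
  expect_equal(unname(lv3$level), rep(42, 6))
})

test_that("the winter/non-winter sets partition weeks 1..52", {
  for (h in c("north", "south")) {
    sn <- hemisphere_season(h)
    expect_setequal(intersect(c(sn$winter, sn$nonwinter), 1:52), 1:52)
    expect_length(intersect(sn$winter, sn$nonwinter), 0)
  }
  expect_setequal(intersect(hemisphere_season("north")$winter, 1:52), c(1:12, 48:52))
  expect_setequal(hemisphere_season("south")$winter, 22:38)
  expect_equal(stmf_hemisphere("AUS"), "south")
  expect_equal(stmf_hemisphere("GBRTENW"), "north")
})

test_that("the default reference period is up to 7 years preceding the target", {
  s <- mk_series_weeks(c(`1` = 1), years = 2005:2020)
  expect_equal(default_reference_years(s, 2020), 2013:2019)
  s2 <- mk_series_weeks(c(`1` = 1), years = 2017:2020)
  expect_equal(default_reference_years(s2, 2020), 2017:2019)
  expect_error(default_reference_years(s2, 2017), class = "stmf_precondition_error")
})

test_that("week 53 falls back to week 52 when reference years lack it", {
  df <- mk_stmf_df("AAA", 2016:2019, 1:52, total = 100)
  df <- rbind(df, mk_stmf_df("AAA", 2020, c(1:52, 53), total = 120))
  s <- select_series(stmf_table(df), "AAA", "b", "dtotal")
  lv <- suppressMessages(
    reference_level(s, 2020, "wsa", reference_years = 2016:2019))
  expect_true(53L %in% lv$weeks)
  expect_equal(unname(lv$level[["53"]]), 100)  # carried from week 52
  expect_equal(lv$diagnostics$week53_fallback, 53L)
})

test_that("all six baselines match the independent brute-force oracle", {
  set.seed(101)
  for (rep in 1:40) {
    inst <- random_instance()
    for (m in c("wsa", "wst", "wsq", "yaw", "saw", "ylq")) {
      lv <- suppressMessages(reference_level(
        inst$series, inst$target, m, reference_years = inst$period,
        hemisphere = "north"))
      expect_equal(unname(lv$level),
                   unname(oracle_baseline(inst$df, inst$period, inst$target,
                                          inst$weeks, m)),
                   tolerance = 1e-10,
                   label = sprintf("method %s (rep %d)", m, rep))
    }
  }
})

test_that("ordering of the input records never changes a baseline", {
  set.seed(7)
  inst <- random_instance()
  perm <- sample(nrow(inst$df))
  s_perm <- mk_series(inst$df[perm, ])
  for (m in c("wsa", "wst", "wsq", "yaw", "saw", "ylq")) {
    a <- suppressMessages(reference_level(inst$series, inst$target, m,
                                          reference_years = inst$period,
                                          hemisphere = "north"))
    b <- suppressMessages(reference_level(s_perm, inst$target, m,
                                          reference_years = inst$period,
                                          hemisphere = "north"))
    expect_equal(a$level, b$level)
  }
})

test_that("lower-quartile baselines never exceed their average counterparts", {
  set.seed(11)
  for (rep in 1:25) {
    inst <- random_instance()
    wsq <- suppressMessages(reference_level(inst$series, inst$target, "wsq",
                                            reference_years = inst$period))
    wsa <- suppressMessages(reference_level(inst$series, inst$target, "wsa",
                                            reference_years = inst$period))
    expect_true(all(wsq$level <= wsa$level + 1e-12))
  }
  # rectangular data: pooled lower-quartile-week <= yearly average-week
  set.seed(12)
  for (rep in 1:25) {
    wv <- stats::setNames(round(stats::rlnorm(52, log(100), 0.3), 3), 1:52)
    df <- expand.grid(year = 2015:2020, week = 1:52)
    df$value <- wv[as.character(df$week)] * stats::runif(nrow(df), 0.8, 1.2)
    s <- mk_series(df)
    ylq <- reference_level(s, 2020, "ylq", reference_years = 2015:2019)
    yaw <- reference_level(s, 2020, "yaw", reference_years = 2015:2019)
    expect_lte(ylq$level[[1]], yaw$level[[1]] + 1e-12)
  }
})

test_that("winter-elevated seasonality puts the summer average below the yearly average", {
  set.seed(13)
  winter <- hemisphere_season("north")$winter
  for (rep in 1:10) {
    base <- stats::runif(1, 50, 150)
    wv <- stats::setNames(
      ifelse(1:52 %in% winter, base + stats::runif(52, 5, 20), base), 1:52)
    s <- mk_series_weeks(wv, years = 2016:2020)
    saw <- reference_level(s, 2020, "saw", reference_years = 2016:2019,
                           hemisphere = "north")
    yaw <- reference_level(s, 2020, "yaw", reference_years = 2016:2019)
    expect_lte(saw$level[[1]], yaw$level[[1]])
  }
})

test_that("an exactly linear-in-year series is reproduced by the trend baseline", {
  set.seed(14)
  years <- 2013:2020
  wv_a <- stats::runif(52, 80, 120)
  wv_b <- stats::runif(52, -3, 3)
  df <- expand.grid(year = years, week = 1:52)
  df$value <- wv_a[df$week] + wv_b[df$week] * (df$year - 2013)
  s <- mk_series(df)
  lv <- reference_level(s, 2020, "wst", reference_years = 2013:2019)
  truth <- wv_a + wv_b * (2020 - 2013)
  expect_equal(unname(lv$level), truth, tolerance = 1e-9)
})

test_that("a series constant in week and year yields the constant for all six methods", {
  s <- mk_series_weeks(stats::setNames(rep(123.4, 52), 1:52), years = 2015:2020)
  for (m in c("wsa", "wst", "wsq", "yaw", "saw", "ylq")) {
    lv <- reference_level(s, 2020, m, reference_years = 2015:2019)
    expect_equal(unname(lv$level), rep(123.4, 52), label = m)
  }
})

test_that("reference periods must exist in the series and may include the target year", {
  s <- mk_series_weeks(c(`1` = 10, `2` = 20), years = 2018:2020)
  expect_error(reference_level(s, 2020, "wsa", reference_years = 2010:2015),
               "not present", class = "stmf_precondition_error")
  lv <- reference_level(s, 2020, "wsa", reference_years = 2018:2020)
  expect_equal(unname(lv$level), c(10, 20))
})
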