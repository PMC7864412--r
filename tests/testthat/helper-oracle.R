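# Independent brute-force re-implementation of the six baselines, written
# against a plain data.frame(year, week, value) with explicit loops and
# stats::quantile(type = 7) — shares no code with the package internals.

oracle_week_obs <- function(df, P, w, min_n = 1L) {
  sel <- df$year %in% P & df$week == w
  if (sum(sel) < min_n && w == 53) sel <- df$year %in% P & df$week == 52
  list(values = df$value[sel], years = df$year[sel])
}

oracle_baseline <- function(df, P, T, weeks, method, hemisphere = "north") {
  wsa_one <- function(w) mean(oracle_week_obs(df, P, w)$values)
  out <- switch(method,
    wsa = vapply(weeks, wsa_one, 0),
    wst = vapply(weeks, function(w) {
      o <- oracle_week_obs(df, P, w, min_n = 2L)
      y <- o$years; v <- o$values
      b <- sum((y - mean(y)) * (v - mean(v))) / sum((y - mean(y))^2)
      a <- mean(v) - b * mean(y)
      a + b * T
    }, 0),
    wsq = vapply(weeks, function(w) {
      v <- oracle_week_obs(df, P, w)$values
      q <- stats::quantile(v, 0.25, type = 7, names = FALSE)
      mean(v[v <= q])
    }, 0),
    yaw = rep(mean(vapply(weeks, wsa_one, 0)), length(weeks)),
    saw = {
      nonwinter <- if (hemisphere == "north") 13:47 else c(1:21, 39:53)
      ws <- weeks[weeks %in% nonwinter]
      rep(mean(vapply(ws, wsa_one, 0)), length(weeks))
    },
    ylq = {
      pool <- df$value[df$year %in% P]
      q <- stats::quantile(pool, 0.25, type = 7, names = FALSE)
      rep(mean(pool[pool <= q]), length(weeks))
    })
  stats::setNames(out, weeks)
}
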