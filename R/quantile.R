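#' Linear-interpolation (type-7) sample quantile
#'
#' Computes the quantile by linear interpolation between order statistics:
#' with sorted values \eqn{x_{(1)} \le \dots \le x_{(n)}} and
#' \eqn{h = 1 + (n - 1)p}, the quantile is
#' \deqn{x_{(\lfloor h \rfloor)} + (h - \lfloor h \rfloor)\,
#'       (x_{(\lceil h \rceil)} - x_{(\lfloor h \rfloor)}).}
#' This is the default estimator of most statistical environments and the one
#' used throughout the lower-quartile baselines in this package.
#'
#' @param values non-empty numeric vector of finite values.
#' @param p probability in \eqn{[0, 1]}.
#' @return the interpolated quantile (length 1).
#' @export
#' @examples
#' quantile_linear(c(1, 2, 3, 4), 0.25)                        # 1.75
#' quantile_linear(c(90, 92, 95, 100, 105, 110, 115, 120), 0.25)  # 94.25
quantile_linear <- function(values, p) {
  if (length(values) == 0L) stop_precondition("quantile of an empty set")
  if (!all(is.finite(values))) stop_precondition("quantile input must be finite")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop_precondition("p must be a single probability in [0, 1]")
  }
  x <- sort(values)
  n <- length(x)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
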