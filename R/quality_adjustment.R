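#' Duration-indexed utility curve
#'
#' Mean EQ-5D utility among survivors as a function of months since cohort
#' entry. Values lie in \[-1, 1\] (country tariffs permit states valued
#' worse than death) and are held constant beyond the last observed
#' duration.
#'
#' @param q numeric vector of mean utilities, one per month starting at
#'   month 0.
#' @param last_observed month of the last supporting observation.
#' @return a `utility_curve` with elements `grid`, `q`, `last_observed`.
#' @export
utility_curve <- function(q, last_observed = length(q) - 1L) {
  q <- as.numeric(q)
  if (any(q < -1 | q > 1) || anyNA(q)) stop("utilities must lie in [-1, 1]")
  structure(list(grid = seq_along(q) - 1L, q = q,
                 last_observed = as.integer(last_observed)),
            class = "utility_curve")
}

# Core k-nearest-neighbour moving average: at each grid point t the mean of
# the k samples whose x is nearest to t; ties broken by smaller x, then by
# input order.
knn_moving_average <- function(x, y, fraction, grid) {
  n <- length(x)
  if (n == 0L) stop("at least one sample is required")
  if (length(y) != n) stop("x/y length mismatch")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- max(1L, ceiling(fraction * n))
  vapply(grid, function(t) {
    ord <- order(abs(x - t), x, seq_len(n))
    mean(y[ord[seq_len(k)]])
  }, numeric(1))
}

#' Kernel-type smoothing of cross-sectional utilities along duration
#'
#' Moving average of the proximal `fraction` (default 10%) of the sample:
#' at each grid month the mean utility of the `k = ceiling(fraction * n)`
#' respondents whose duration-to-date is nearest to that month. Beyond the
#' last observed duration the estimate is constant (the nearest k samples
#' no longer change), matching the carry-forward assumption used for
#' lifetime quality-of-life curves.
#'
#' @param duration_months duration-to-date of each respondent (months from
#'   day-21 qualification to assessment).
#' @param utility EQ-5D utility index per respondent.
#' @param fraction proportion of the sample in each moving average.
#' @param grid months at which to evaluate (default `0:horizon`).
#' @param horizon last grid month when `grid` is not given (default 300).
#' @return a [utility_curve].
#' @export
kernel_smooth <- function(duration_months, utility, fraction = 0.10,
                          grid = NULL, horizon = 300) {
  if (length(duration_months) == 0L) stop("at least one sample is required")
  if (any(duration_months < 0)) stop("durations must be nonnegative")
  if (any(utility < -1 | utility > 1)) stop("utilities must lie in [-1, 1]")
  if (is.null(grid)) grid <- 0:horizon
  q <- knn_moving_average(duration_months, utility, fraction, grid)
  utility_curve(q, last_observed = min(floor(max(duration_months)),
                                       max(grid)))
}

#' Multiply a survival curve by a utility curve
#'
#' The quality-adjusted survival curve: pointwise product `S(t) * q(t)` on
#' the shared monthly grid; the area under it is the QALE.
#'
#' @param s a [survival_curve].
#' @param q a [utility_curve] on the same grid.
#' @return a [survival_curve]-like object of class
#'   `quality_adjusted_curve` (values need not start at 1 nor be
#'   monotone when utilities vary).
#' @export
quality_adjust <- function(s, q) {
  stopifnot(inherits(s, "survival_curve"), inherits(q, "utility_curve"))
  if (length(s$probs) != length(q$q)) stop("grid mismatch")
  structure(list(grid = s$grid, probs = s$probs * q$q,
                 segment_boundary = s$segment_boundary),
            class = "quality_adjusted_curve")
}

#' Quality-adjusted life expectancy (QALE)
#'
#' Area under the quality-adjusted survival curve by the same monthly
#' rectangle rule as [life_expectancy()]; units QALY.
#'
#' @inheritParams quality_adjust
#' @return QALE in QALYs.
#' @export
qale <- function(s, q) {
  qa <- quality_adjust(s, q)
  sum(qa$probs[-1L]) / 12
}
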