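#' Monthly survival curve
#'
#' A survival curve on the package's common monthly grid. Month 0 is cohort
#' entry (day 21 of ventilation); `probs[t + 1]` is the probability of
#' surviving beyond month `t`. Curves carry an optional `segment_boundary`
#' marking where observed follow-up ends and extrapolation begins.
#'
#' @param probs numeric vector of survival probabilities, one per month
#'   starting at month 0; must start at 1, be nonincreasing and lie in
#'   \[0, 1\].
#' @param segment_boundary optional month index (integer) at which the
#'   follow-up segment ends; `NULL` for purely empirical curves.
#' @return an object of class `survival_curve` with elements `grid`
#'   (months `0:H`), `probs` and `segment_boundary`.
#' @export
survival_curve <- function(probs, segment_boundary = NULL) {
  probs <- as.numeric(probs)
  if (length(probs) < 1L || anyNA(probs)) {
    stop("'probs' must be a non-empty numeric vector without NA")
  }
  if (abs(probs[1L] - 1) > 1e-12) {
    stop("survival at month 0 must equal 1")
  }
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    stop("survival probabilities must lie in [0, 1]")
  }
  if (any(diff(probs) > 1e-12)) {
    stop("survival probabilities must be nonincreasing")
  }
  probs <- pmin(pmax(probs, 0), 1)
  if (!is.null(segment_boundary)) {
    segment_boundary <- as.integer(segment_boundary)
    stopifnot(segment_boundary >= 0L, segment_boundary <= length(probs) - 1L)
  }
  structure(
    list(grid = seq_len(length(probs)) - 1L, probs = probs,
         segment_boundary = segment_boundary),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  h <- length(x$probs) - 1L
  cat("<survival_curve> months 0..", h, sep = "")
  if (!is.null(x$segment_boundary)) {
    cat(", follow-up ends at month ", x$segment_boundary, sep = "")
  }
  cat("\n  S(", min(12L, h), ") = ", signif(x$probs[min(12L, h) + 1L], 4),
      ", S(", h, ") = ", signif(x$probs[h + 1L], 4), "\n", sep = "")
  invisible(x)
}

curve_horizon <- function(s) length(s$probs) - 1L

#' Restricted mean survival time (life expectancy) in years
#'
#' Area under the monthly survival curve by the right-endpoint rectangle
#' rule: `sum over t = 1..H of S(t) / 12`. The same convention is shared by
#' the QALE and lifetime-cost integrals so the three quantities are directly
#' comparable.
#'
#' @param s a [survival_curve].
#' @return restricted mean survival time over the curve's horizon, in years.
#' @export
life_expectancy <- function(s) {
  stopifnot(inherits(s, "survival_curve"))
  sum(s$probs[-1L]) / 12
}
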