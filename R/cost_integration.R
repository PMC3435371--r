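#' Monthly cost curve among survivors
#'
#' Mean cost per person-month among patients alive in each month, in
#' CPI-adjusted currency units. Indexed from month 1 (the first month of
#' follow-up after entry).
#'
#' @param c numeric vector of mean monthly costs, one per month starting at
#'   month 1; nonnegative.
#' @param source `"insurer"` or `"out_of_pocket"`.
#' @return a `cost_curve` with elements `grid` (months `1:H`), `c`,
#'   `source`.
#' @export
cost_curve <- function(c, source = c("insurer", "out_of_pocket")) {
  source <- match.arg(source)
  c <- as.numeric(c)
  if (any(c < 0) || anyNA(c)) stop("costs must be nonnegative")
  structure(list(grid = seq_along(c), c = c, source = source),
            class = "cost_curve")
}

#' Average monthly cost among survivors from patient-month claims
#'
#' Total cost in each month divided by the number of patients alive in that
#' month. Months with alive patients but no claims get cost 0; months with
#' no alive patients carry forward the last defined value.
#'
#' @param claims data frame with columns `month_index` (1-based) and
#'   `cost` (already CPI-adjusted; see [cpi_adjust()]).
#' @param alive_counts number of patients alive in each month, a vector
#'   indexed by month 1, 2, ...
#' @param source passed to [cost_curve()].
#' @return a [cost_curve] over the months covered by `alive_counts`.
#' @export
monthly_mean_cost <- function(claims, alive_counts, source = "insurer") {
  stopifnot(all(c("month_index", "cost") %in% names(claims)))
  if (any(claims$cost < 0)) stop("costs must be nonnegative")
  m <- length(alive_counts)
  if (nrow(claims) > 0 &&
      any(alive_counts[pmin(claims$month_index, m)] <= 0 |
          claims$month_index > m)) {
    stop("claims exist in months with no alive patients")
  }
  totals <- numeric(m)
  if (nrow(claims) > 0) {
    agg <- tapply(claims$cost, factor(claims$month_index, levels = 1:m), sum)
    totals <- ifelse(is.na(agg), 0, as.numeric(agg))
  }
  cc <- ifelse(alive_counts > 0, totals / pmax(alive_counts, 1), NA_real_)
  # carry forward over months with nobody alive
  for (t in seq_len(m)) {
    if (is.na(cc[t])) cc[t] <- if (t > 1L) cc[t - 1L] else 0
  }
  cost_curve(cc, source = source)
}

#' Adjust an amount to the 2010 consumer price index
#'
#' @param amount currency amount (vectorised).
#' @param year calendar year of the amount (vectorised).
#' @param cpi_factors named numeric vector mapping year to the multiplier
#'   that converts to 2010 prices; `cpi_factors["2010"]` must be 1.
#' @return the CPI-adjusted amount.
#' @export
cpi_adjust <- function(amount, year, cpi_factors) {
  key <- as.character(year)
  if (!all(key %in% names(cpi_factors))) {
    stop("CPI factor missing for year(s): ",
         paste(unique(key[!key %in% names(cpi_factors)]), collapse = ", "))
  }
  amount * as.numeric(cpi_factors[key])
}

#' Extend a cost curve to the lifetime horizon
#'
#' Beyond the observed months, the mean of the last `tail_months` defined
#' values is held constant to the horizon.
#'
#' @param curve a [cost_curve].
#' @param horizon last month required.
#' @param tail_months months averaged for the constant tail (default 6).
#' @return a [cost_curve] over months `1:horizon`.
#' @export
extend_cost_curve <- function(curve, horizon, tail_months = 6L) {
  stopifnot(inherits(curve, "cost_curve"))
  m <- length(curve$c)
  if (m >= horizon) return(cost_curve(curve$c[seq_len(horizon)],
                                      source = curve$source))
  tail_mean <- mean(curve$c[max(1L, m - tail_months + 1L):m])
  cost_curve(c(curve$c, rep(tail_mean, horizon - m)), source = curve$source)
}

#' Survival-weighted lifetime cost
#'
#' `sum over t = 1..H of c(t) * S(t)`: average monthly expenditure among
#' survivors multiplied by the probability of being alive, summed over the
#' lifetime horizon.
#'
#' @param curve a [cost_curve] over months `1:H`.
#' @param s a [survival_curve] over months `0:H`.
#' @return lifetime cost in the curve's currency units.
#' @export
lifetime_cost <- function(curve, s) {
  stopifnot(inherits(curve, "cost_curve"), inherits(s, "survival_curve"))
  if (length(curve$c) != curve_horizon(s)) stop("grid mismatch")
  sum(curve$c * s$probs[-1L])
}

#' Kernel-smoothed out-of-pocket cost curve
#'
#' Applies the same proximal-fraction moving average as [kernel_smooth()]
#' to cross-sectional last-month expenses along duration-to-date;
#' nonnegativity is enforced.
#'
#' @param duration_months duration-to-date per respondent.
#' @param monthly_expense last-month out-of-pocket expense per respondent.
#' @param fraction proportion of the sample in each moving average.
#' @param horizon last month of the curve (default 300).
#' @return a [cost_curve] with source `"out_of_pocket"` over
#'   `1:horizon`.
#' @export
smooth_oop <- function(duration_months, monthly_expense, fraction = 0.10,
                       horizon = 300) {
  if (any(monthly_expense < 0)) stop("expenses must be nonnegative")
  cc <- knn_moving_average(duration_months, monthly_expense, fraction,
                           grid = 1:horizon)
  cost_curve(pmax(cc, 0), source = "out_of_pocket")
}

#' Cost-effectiveness ratio (cost per QALY)
#'
#' Total lifetime cost divided by quality-adjusted life expectancy.
#' Reported values are conventionally rounded to whole currency units;
#' this function returns full precision.
#'
#' @param lifetime_total total lifetime cost (insurer + out-of-pocket).
#' @param qale quality-adjusted life expectancy in QALYs (> 0 unless the
#'   cost is 0).
#' @return cost per QALY.
#' @export
cost_per_qaly <- function(lifetime_total, qale) {
  if (lifetime_total == 0) return(0)
  if (qale <= 0) stop("cost per QALY undefined for QALE <= 0")
  lifetime_total / qale
}

#' WHO-CHOICE GDP banding of a cost-effectiveness ratio
#'
#' Below 1x GDP per capita: cost-effective; between 1x and 3x: moderately
#' cost-effective; above 3x: not cost-effective. Boundary values go to the
#' lower band.
#'
#' @param cer cost per QALY (nonnegative; vectorised).
#' @param gdp_per_capita GDP per capita in the same currency (> 0).
#' @return factor with levels `cost-effective`, `moderate`,
#'   `not cost-effective`.
#' @export
classify_cer <- function(cer, gdp_per_capita) {
  if (gdp_per_capita <= 0) stop("GDP per capita must be positive")
  if (any(cer < 0)) stop("cost per QALY must be nonnegative")
  bands <- c("cost-effective", "moderate", "not cost-effective")
  factor(ifelse(cer <= gdp_per_capita, bands[1L],
                ifelse(cer <= 3 * gdp_per_capita, bands[2L], bands[3L])),
         levels = bands)
}
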