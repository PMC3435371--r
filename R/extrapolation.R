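#' Kaplan-Meier survival on the monthly grid
#'
#' Product-limit estimate via [survival::survfit()], sampled at month ends:
#' `S(t)` is the step-function value at time `t` months. Ties are handled by
#' the standard convention that deaths precede censorings at the same time.
#'
#' @param time event or censoring times in months (>= 0).
#' @param event 1 = death, 0 = censored.
#' @param horizon last month of the grid; defaults to the smallest integer
#'   month covering the largest observed time.
#' @return a [survival_curve] over months `0:horizon`.
#' @export
kaplan_meier <- function(time, event, horizon = NULL) {
  if (length(time) == 0L) stop("at least one subject is required")
  if (length(event) != length(time)) stop("time/event length mismatch")
  if (any(time < 0)) stop("times must be nonnegative")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censor) or 1 (death)")
  if (is.null(horizon)) horizon <- ceiling(max(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  months <- seq_len(horizon)
  # step function: last estimate with event time <= t
  idx <- findInterval(months + 1e-9, fit$time)
  probs <- c(1, ifelse(idx == 0L, 1, fit$surv[pmax(idx, 1L)]))
  survival_curve(cummin(probs))
}

#' Survival ratio of study over reference population with logit transform
#'
#' `W(t) = S_study(t) / S_ref(t)`, clipped into
#' `[clip_eps, 1 - clip_eps]` so that `logit(W)` is finite everywhere.
#' Under a constant excess hazard, `logit(W(t))` is approximately linear in
#' `t`, which is the basis of the lifetime extrapolation.
#'
#' @param s_study,s_ref [survival_curve]s on a shared grid (the reference
#'   may extend further; the ratio covers the study grid).
#' @param clip_eps clipping bound in (0, 0.5); default `1e-6`.
#' @return data frame with columns `month`, `W`, `logit_w` (`W` is `NA`
#'   where the reference survival is zero).
#' @export
survival_ratio <- function(s_study, s_ref, clip_eps = 1e-6) {
  stopifnot(inherits(s_study, "survival_curve"),
            inherits(s_ref, "survival_curve"))
  if (clip_eps <= 0 || clip_eps >= 0.5) stop("clip_eps must be in (0, 0.5)")
  h <- curve_horizon(s_study)
  if (curve_horizon(s_ref) < h) stop("reference curve does not cover study grid")
  s <- s_study$probs
  r <- s_ref$probs[seq_len(h + 1L)]
  w <- ifelse(r > 0, pmin(pmax(s / r, clip_eps), 1 - clip_eps), NA_real_)
  data.frame(month = 0:h, W = w, logit_w = log(w / (1 - w)))
}

#' Ordinary least squares fit of the logit survival ratio on time
#'
#' @param w_series data frame from [survival_ratio()].
#' @param fit_window integer months (inclusive range or explicit vector)
#'   used for the fit; needs at least 3 usable points.
#' @return a `logit_ratio_fit`: `intercept` (logit scale), `slope`
#'   (per month), `fit_window`, `residual_sd`.
#' @export
fit_logit_linear <- function(w_series, fit_window) {
  stopifnot(all(c("month", "logit_w") %in% names(w_series)))
  fit_window <- as.integer(fit_window)
  if (length(fit_window) == 2L) fit_window <- fit_window[1L]:fit_window[2L]
  sub <- w_series[w_series$month %in% fit_window, ]
  if (anyNA(sub$logit_w)) {
    stop("degenerate reference: survival ratio undefined inside fit window")
  }
  if (nrow(sub) < 3L) stop("fit window must contain at least 3 usable points")
  fit <- stats::lm(logit_w ~ month, data = sub)
  cf <- stats::coef(fit)
  structure(
    list(intercept = unname(cf[1L]), slope = unname(cf[2L]),
         fit_window = range(sub$month), residual_sd = stats::sigma(fit)),
    class = "logit_ratio_fit"
  )
}

#' @export
print.logit_ratio_fit <- function(x, ...) {
  cat("<logit_ratio_fit> logit W(t) = ", signif(x$intercept, 5), " + ",
      signif(x$slope, 5), " t  (months ", x$fit_window[1L], "..",
      x$fit_window[2L], ", residual SD ", signif(x$residual_sd, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Extrapolate a follow-up survival curve to a lifetime horizon
#'
#' Beyond follow-up, survival is the reference survival multiplied by the
#' inverse-logit of the fitted line, rescaled by a continuity factor so the
#' spliced curve is continuous at the boundary, then clamped to be
#' nonincreasing and no larger than the boundary value. Fitted ratios above
#' `1 - clip_eps` are clamped with a warning (the study population cannot
#' indefinitely outlive its reference).
#'
#' @param s_ref_extended reference [survival_curve] covering the full
#'   horizon.
#' @param fit a `logit_ratio_fit` from [fit_logit_linear()].
#' @param s_study_followup follow-up [survival_curve] (months
#'   `0:boundary`).
#' @param clip_eps ratio clipping bound, as in [survival_ratio()].
#' @return a [survival_curve] over the reference horizon with
#'   `segment_boundary` set to the end of follow-up.
#' @export
extrapolate <- function(s_ref_extended, fit, s_study_followup,
                        clip_eps = 1e-6) {
  stopifnot(inherits(fit, "logit_ratio_fit"),
            inherits(s_ref_extended, "survival_curve"),
            inherits(s_study_followup, "survival_curve"))
  h <- curve_horizon(s_ref_extended)
  b <- curve_horizon(s_study_followup)
  if (h <= b) stop("reference curve must extend beyond follow-up")
  months <- (b + 1L):h
  w_hat <- stats::plogis(fit$intercept + fit$slope * c(b, months))
  if (any(w_hat > 1 - clip_eps)) {
    warning("fitted survival ratio exceeds 1 - clip_eps; clamped")
    w_hat <- pmin(w_hat, 1 - clip_eps)
  }
  raw_b <- s_ref_extended$probs[b + 1L] * w_hat[1L]
  raw_tail <- s_ref_extended$probs[months + 1L] * w_hat[-1L]
  s_b <- s_study_followup$probs[b + 1L]
  scale <- if (raw_b > 0) s_b / raw_b else 0
  tail <- pmin(raw_tail * scale, s_b)
  survival_curve(c(s_study_followup$probs, cummin(pmin(tail, s_b))),
                 segment_boundary = b)
}

#' Default fit window: the latter half of observed follow-up
#'
#' Months `ceiling(L/2)..L` for follow-up length `L`, avoiding the early
#' instability of the survival ratio.
#'
#' @param followup_months length of observed follow-up in months.
#' @return integer vector of months.
#' @export
default_fit_window <- function(followup_months) {
  stopifnot(followup_months >= 3)
  ceiling(followup_months / 2):followup_months
}

#' Full extrapolation pipeline for one cohort
#'
#' Kaplan-Meier on follow-up, matched reference survival from the life
#' table, logit survival-ratio fit over the fit window, and splice-extended
#' extrapolation to the horizon.
#'
#' @param cohort data frame with columns `age_at_entry`, `sex`,
#'   `time_months`, `event`.
#' @param table a [life_table].
#' @param horizon lifetime horizon in months (default 300).
#' @param followup end of observed follow-up in months; defaults to the
#'   largest observed time.
#' @param fit_window months used in the logit-linear fit; default latter
#'   half of follow-up.
#' @param clip_eps ratio clipping bound.
#' @param reference backend for the reference survival: `"expectation"`
#'   (deterministic, default) or `"monte_carlo"`.
#' @param n_reps,seed Monte-Carlo backend parameters.
#' @return list with `curve` (extrapolated [survival_curve]), `km`,
#'   `reference`, `fit` and `life_expectancy` (years).
#' @export
extrapolated_survival <- function(cohort, table, horizon = 300,
                                  followup = NULL, fit_window = NULL,
                                  clip_eps = 1e-6,
                                  reference = c("expectation", "monte_carlo"),
                                  n_reps = 100, seed = 1L) {
  reference <- match.arg(reference)
  stopifnot(all(c("age_at_entry", "sex", "time_months", "event")
                %in% names(cohort)))
  if (is.null(followup)) followup <- ceiling(max(cohort$time_months))
  if (followup >= horizon) stop("horizon must exceed follow-up")
  km <- kaplan_meier(cohort$time_months, cohort$event, horizon = followup)
  s_ref <- switch(reference,
    expectation = expected_reference_survival(cohort, table, horizon),
    monte_carlo = simulate_reference_survival(cohort, table, horizon,
                                              n_reps = n_reps, seed = seed))
  if (is.null(fit_window)) fit_window <- default_fit_window(followup)
  w <- survival_ratio(km, s_ref, clip_eps = clip_eps)
  fit <- fit_logit_linear(w, fit_window)
  curve <- extrapolate(s_ref, fit, km, clip_eps = clip_eps)
  list(curve = curve, km = km, reference = s_ref, fit = fit,
       life_expectancy = life_expectancy(curve))
}
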