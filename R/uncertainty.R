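#' Bootstrap standard error of a cohort-level estimator
#'
#' Resamples patients (the patient is the resampling unit) with
#' replacement, recomputes the estimator on each resample, and reports the
#' standard deviation across resamples. A resample on which the estimator
#' fails is redrawn (at most 3 retries) before erroring.
#'
#' @param estimator function taking a cohort data frame and returning a
#'   scalar.
#' @param cohort data frame, one row per patient.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param statistic optional name recorded in the result.
#' @return a `bootstrap_result`: `statistic`, `estimate` (on the full
#'   cohort), `se`, `n_boot`, `seed`, `replicates`.
#' @export
bootstrap_se <- function(estimator, cohort, n_boot = 100, seed = 1L,
                         statistic = "statistic") {
  stopifnot(is.function(estimator), is.data.frame(cohort), n_boot >= 2)
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  estimate <- estimator(cohort)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    value <- NULL
    for (attempt in 1:4) {
      idx <- sample.int(n, n, replace = TRUE)
      value <- tryCatch(estimator(cohort[idx, , drop = FALSE]),
                        error = function(e) NULL)
      if (!is.null(value)) break
    }
    if (is.null(value)) {
      stop("estimator failed on a bootstrap resample after 3 retries")
    }
    reps[b] <- value
  }
  structure(
    list(statistic = statistic, estimate = estimate,
         se = stats::sd(reps), n_boot = n_boot, seed = as.integer(seed),
         replicates = reps),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$statistic, ": ", signif(x$estimate, 5),
      " (SE ", signif(x$se, 4), ", ", x$n_boot, " resamples)\n", sep = "")
  invisible(x)
}

#' Truncate-and-extrapolate validation of the extrapolation method
#'
#' Censors all follow-up at `truncate_at` months, reruns the full logit
#' survival-ratio extrapolation out to `evaluate_to` months, and compares
#' the extrapolated restricted mean with the Kaplan-Meier restricted mean
#' from the complete follow-up (taken as the gold standard). Mirrors the
#' design of validating a 4-year fit against 10-year follow-up.
#'
#' @param cohort data frame with `age_at_entry`, `sex`, `time_months`,
#'   `event` covering follow-up to at least `evaluate_to`.
#' @param truncate_at month at which follow-up is artificially cut.
#' @param evaluate_to month to which both estimates are evaluated.
#' @param table a [life_table] for the reference population.
#' @param fit_window,clip_eps passed to [extrapolated_survival()].
#' @param measure `"rmst"` compares restricted means (default);
#'   `"point_survival"` compares survival at `evaluate_to`.
#' @return a `validation_report`: `le_extrapolated`, `le_km_full` (years,
#'   or survival probabilities for `measure = "point_survival"`),
#'   `relative_bias` (signed, (extrapolated - KM) / KM), `truncate_at`,
#'   `evaluate_to`, `measure`.
#' @export
validate_extrapolation <- function(cohort, truncate_at, evaluate_to, table,
                                   fit_window = NULL, clip_eps = 1e-6,
                                   measure = c("rmst", "point_survival")) {
  measure <- match.arg(measure)
  if (!(truncate_at < evaluate_to)) stop("truncate_at must precede evaluate_to")
  if (evaluate_to > ceiling(max(cohort$time_months))) {
    stop("evaluate_to exceeds observed follow-up")
  }
  trunc <- cohort
  over <- trunc$time_months > truncate_at
  trunc$time_months[over] <- truncate_at
  trunc$event[over] <- 0
  if (sum(trunc$event) == 0) stop("no deaths before the truncation point")
  ext <- extrapolated_survival(trunc, table, horizon = evaluate_to,
                               followup = truncate_at,
                               fit_window = fit_window, clip_eps = clip_eps)
  km_full <- kaplan_meier(cohort$time_months, cohort$event,
                          horizon = evaluate_to)
  if (measure == "rmst") {
    est <- life_expectancy(ext$curve)
    gold <- life_expectancy(km_full)
  } else {
    est <- ext$curve$probs[evaluate_to + 1L]
    gold <- km_full$probs[evaluate_to + 1L]
  }
  if (gold <= 0) stop("gold-standard estimate is zero; relative bias undefined")
  structure(
    list(le_extrapolated = est, le_km_full = gold,
         relative_bias = (est - gold) / gold,
         truncate_at = truncate_at, evaluate_to = evaluate_to,
         measure = measure),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> truncate ", x$truncate_at, "m -> evaluate ",
      x$evaluate_to, "m (", x$measure, ")\n  extrapolated ",
      signif(x$le_extrapolated, 5), " vs full-KM ",
      signif(x$le_km_full, 5), "; relative bias ",
      sprintf("%+.2f%%", 100 * x$relative_bias), "\n", sep = "")
  invisible(x)
}
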