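#' Run configuration for the full analysis
#'
#' Collects inputs (data frames or CSV paths) and every tunable parameter
#' of the pipeline. Paths are read with the validating readers; data
#' frames are used as-is.
#'
#' @param cohort cohort table or path (see [read_cohort()]).
#' @param life_table a [life_table] or CSV path.
#' @param utility_survey utility survey table or path.
#' @param claims insurer claims table or path (nominal currency plus
#'   `calendar_year`; CPI adjustment is applied internally).
#' @param oop_survey out-of-pocket survey table or path (2010 USD).
#' @param horizon lifetime horizon in months (default 300).
#' @param followup end of observed follow-up; default the largest observed
#'   time.
#' @param fit_window logit-ratio fit window; default latter half of
#'   follow-up.
#' @param kernel_fraction proximal fraction for the moving-average
#'   smoother (default 0.10).
#' @param clip_eps survival-ratio clipping bound.
#' @param reference reference-survival backend, `"expectation"` or
#'   `"monte_carlo"`.
#' @param n_reps Monte-Carlo referents per patient.
#' @param n_boot bootstrap resamples for standard errors (default 100);
#'   0 disables the bootstrap.
#' @param gdp_per_capita GDP per capita used for CER banding (default
#'   18588 USD, Taiwan 2010).
#' @param cpi_factors named year-to-2010 multipliers for claim costs.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort, life_table, utility_survey, claims,
                       oop_survey, horizon = 300, followup = NULL,
                       fit_window = NULL, kernel_fraction = 0.10,
                       clip_eps = 1e-6,
                       reference = c("expectation", "monte_carlo"),
                       n_reps = 100, n_boot = 100,
                       gdp_per_capita = 18588, cpi_factors = NULL,
                       seed = 1L) {
  reference <- match.arg(reference)
  paths <- list()
  grab <- function(x, reader, name) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("input file not found: ", x)
      paths[[name]] <<- x
      reader(x)
    } else x
  }
  cohort <- grab(cohort, read_cohort, "cohort")
  life_table <- grab(life_table, read_life_table, "life_table")
  utility_survey <- grab(utility_survey, read_utility_survey,
                         "utility_survey")
  claims <- grab(claims, read_claims, "claims")
  oop_survey <- grab(oop_survey, read_oop_survey, "oop_survey")
  if (is.null(followup)) followup <- ceiling(max(cohort$time_months))
  if (horizon < followup) stop("horizon must cover follow-up")
  if (kernel_fraction <= 0 || kernel_fraction > 1) {
    stop("kernel_fraction must be in (0, 1]")
  }
  if (is.null(cpi_factors)) {
    yrs <- sort(unique(claims$calendar_year))
    cpi_factors <- stats::setNames(rep(1, length(yrs)), as.character(yrs))
  }
  structure(
    list(cohort = cohort, life_table = life_table,
         utility_survey = utility_survey, claims = claims,
         oop_survey = oop_survey, horizon = horizon, followup = followup,
         fit_window = fit_window, kernel_fraction = kernel_fraction,
         clip_eps = clip_eps, reference = reference, n_reps = n_reps,
         n_boot = n_boot, gdp_per_capita = gdp_per_capita,
         cpi_factors = cpi_factors, seed = as.integer(seed),
         input_paths = paths),
    class = "run_config")
}

# Per-patient reference survival matrix (rows aligned with demographics),
# columns months 0..horizon. colMeans() of row subsets gives the matched
# reference curve of any resampled subcohort without recomputation.
patient_reference_matrix <- function(demographics, table, horizon) {
  n <- nrow(demographics)
  out <- matrix(0, nrow = n, ncol = horizon + 1L)
  for (i in seq_len(n)) {
    h <- lt_monthly_trajectory(table, demographics$age_at_entry[i],
                               as.character(demographics$sex[i]), horizon)
    out[i, ] <- c(1, cumprod(1 - h))
  }
  out
}

# All estimates for one (sub)cohort given precomputed per-patient reference
# rows and per-patient claim record lists. Returns the extrapolated curve
# and the named estimate vector.
group_statistics <- function(sub, ref_rows, claims_by_patient,
                             q_partial, q_poor, oop_curve, cfg) {
  km <- kaplan_meier(sub$time_months, sub$event, horizon = cfg$followup)
  s_ref <- survival_curve(cummin(pmin(colMeans(ref_rows), 1)))
  fw <- if (is.null(cfg$fit_window)) default_fit_window(cfg$followup) else
    cfg$fit_window
  w <- survival_ratio(km, s_ref, clip_eps = cfg$clip_eps)
  fit <- fit_logit_linear(w, fw)
  curve <- extrapolate(s_ref, fit, km, clip_eps = cfg$clip_eps)
  le <- life_expectancy(curve)
  qale_partial <- qale(curve, q_partial)
  qale_poor <- qale(curve, q_poor)
  alive <- vapply(seq_len(cfg$followup),
                  function(t) sum(sub$time_months >= t), numeric(1))
  claims_sub <- do.call(rbind,
                        claims_by_patient[as.character(sub$patient_id)])
  if (is.null(claims_sub)) claims_sub <- data.frame(month_index = integer(),
                                                    cost = numeric())
  c_ins <- monthly_mean_cost(claims_sub, alive, source = "insurer")
  c_ins <- extend_cost_curve(c_ins, cfg$horizon)
  lifetime_insurer <- lifetime_cost(c_ins, curve)
  lifetime_oop <- lifetime_cost(oop_curve, curve)
  list(curve = curve, fit = fit, km = km, reference = s_ref,
       insurer_curve = c_ins,
       estimates = c(life_expectancy = le, qale_partial = qale_partial,
                     qale_poor = qale_poor,
                     lifetime_insurer = lifetime_insurer,
                     lifetime_oop = lifetime_oop,
                     lifetime_total = lifetime_insurer + lifetime_oop))
}

smooth_utility_strata <- function(survey, fraction, horizon) {
  lapply(c(partial = "partial", poor = "poor"), function(str) {
    sub <- survey[survey$cognition == str, ]
    if (nrow(sub) == 0L) stop("no utility respondents in stratum ", str)
    kernel_smooth(sub$duration_months, sub$utility, fraction = fraction,
                  horizon = horizon)
  })
}

#' Run the full cost-effectiveness analysis
#'
#' For each cohort group: Kaplan-Meier survival, matched reference
#' survival, logit survival-ratio fit and lifetime extrapolation, life
#' expectancy; QALE under the partial- and poor-cognition utility curves;
#' CPI-adjusted insurer cost curve and kernel-smoothed out-of-pocket curve
#' integrated into lifetime costs; cost per QALY with GDP banding; and
#' bootstrap standard errors (patient resampling; the utility and
#' out-of-pocket surveys are resampled alongside). A group whose analysis
#' fails is skipped with a diagnostic; other groups continue.
#'
#' @param config a [run_config].
#' @return a `cer_report`: `results` (one row per group with the
#'   CerResult schema), `curves` (per-group survival objects),
#'   `utility_curves`, `oop_curve`, `errors` (named diagnostics for
#'   skipped groups), `manifest`, `config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  cohort <- cfg$cohort
  qcurves <- smooth_utility_strata(cfg$utility_survey, cfg$kernel_fraction,
                                   cfg$horizon)
  oop_curve <- smooth_oop(cfg$oop_survey$duration_months,
                          cfg$oop_survey$monthly_expense,
                          fraction = cfg$kernel_fraction,
                          horizon = cfg$horizon)
  claims <- cfg$claims
  claims$cost <- cpi_adjust(claims$cost, claims$calendar_year,
                            cfg$cpi_factors)
  claims_by_patient <- split(claims[, c("month_index", "cost")],
                             as.character(claims$patient_id))
  groups <- unique(cohort$group_label)
  rows <- list(); curves <- list(); errors <- list()
  for (g in groups) {
    res <- tryCatch(
      analyze_one_group(g, cohort, claims_by_patient, qcurves, oop_curve,
                        cfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[g]] <- conditionMessage(res)
      message("group '", g, "' skipped: ", conditionMessage(res))
      next
    }
    rows[[g]] <- res$row
    curves[[g]] <- res$objects
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  manifest <- list(
    input_files = lapply(cfg$input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = cfg[c("horizon", "followup", "kernel_fraction",
                       "clip_eps", "reference", "n_reps", "n_boot",
                       "gdp_per_capita", "seed")],
    n_patients = nrow(cohort), groups = groups)
  structure(list(results = results, curves = curves,
                 utility_curves = qcurves, oop_curve = oop_curve,
                 errors = errors, manifest = manifest, config = cfg),
            class = "cer_report")
}

analyze_one_group <- function(g, cohort, claims_by_patient, qcurves,
                              oop_curve, cfg) {
  sub <- cohort[cohort$group_label == g, , drop = FALSE]
  ref_rows <- patient_reference_matrix(sub, cfg$life_table, cfg$horizon)
  if (cfg$reference == "monte_carlo") {
    s_mc <- simulate_reference_survival(sub, cfg$life_table, cfg$horizon,
                                        n_reps = cfg$n_reps,
                                        seed = cfg$seed)
    # replace expectation rows with the pooled MC curve for every patient
    ref_rows <- matrix(s_mc$probs, nrow = nrow(sub),
                       ncol = cfg$horizon + 1L, byrow = TRUE)
  }
  gs <- group_statistics(sub, ref_rows, claims_by_patient,
                         qcurves$partial, qcurves$poor, oop_curve, cfg)
  est <- gs$estimates
  ses <- rep(NA_real_, length(est))
  names(ses) <- names(est)
  if (cfg$n_boot >= 2) {
    set.seed(cfg$seed + 1000L)
    reps <- matrix(NA_real_, nrow = cfg$n_boot, ncol = length(est),
                   dimnames = list(NULL, names(est)))
    us <- cfg$utility_survey
    os <- cfg$oop_survey
    for (b in seq_len(cfg$n_boot)) {
      idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
      qb <- smooth_utility_strata(
        us[sample.int(nrow(us), nrow(us), replace = TRUE), ],
        cfg$kernel_fraction, cfg$horizon)
      ob_idx <- sample.int(nrow(os), nrow(os), replace = TRUE)
      ob <- smooth_oop(os$duration_months[ob_idx],
                       os$monthly_expense[ob_idx],
                       fraction = cfg$kernel_fraction,
                       horizon = cfg$horizon)
      val <- tryCatch(
        group_statistics(sub[idx, , drop = FALSE],
                         ref_rows[idx, , drop = FALSE], claims_by_patient,
                         qb$partial, qb$poor, ob, cfg)$estimates,
        error = function(e) NULL)
      if (!is.null(val)) reps[b, ] <- val
    }
    ses <- apply(reps, 2L, stats::sd, na.rm = TRUE)
  }
  cer_partial <- cost_per_qaly(est[["lifetime_total"]],
                               est[["qale_partial"]])
  cer_poor <- cost_per_qaly(est[["lifetime_total"]], est[["qale_poor"]])
  row <- data.frame(
    group_label = g, n_cases = nrow(sub),
    life_expectancy_years = est[["life_expectancy"]],
    life_expectancy_se = ses[["life_expectancy"]],
    qale_partial = est[["qale_partial"]],
    qale_partial_se = ses[["qale_partial"]],
    qale_poor = est[["qale_poor"]], qale_poor_se = ses[["qale_poor"]],
    lifetime_insurer = est[["lifetime_insurer"]],
    lifetime_oop = est[["lifetime_oop"]],
    lifetime_total = est[["lifetime_total"]],
    lifetime_total_se = ses[["lifetime_total"]],
    cer_partial = round(cer_partial), cer_poor = round(cer_poor),
    band_partial = as.character(classify_cer(cer_partial,
                                             cfg$gdp_per_capita)),
    band_poor = as.character(classify_cer(cer_poor, cfg$gdp_per_capita)),
    stringsAsFactors = FALSE)
  list(row = row, objects = gs[c("curve", "fit", "km", "reference",
                                 "insurer_curve")])
}

#' @export
print.cer_report <- function(x, ...) {
  cat("<cer_report> ", nrow(x$results), " group(s), horizon ",
      x$config$horizon, " months\n", sep = "")
  print(x$results[, c("group_label", "n_cases", "life_expectancy_years",
                      "qale_partial", "qale_poor", "lifetime_total",
                      "cer_partial", "cer_poor")], digits = 4)
  invisible(x)
}

#' Write a CER report to CSV and JSON
#'
#' @param report a `cer_report` from [run_full_analysis()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cer_report <- function(report, dir) {
  stopifnot(inherits(report, "cer_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "cer_results.csv")
  json <- file.path(dir, "cer_results.json")
  utils::write.csv(report$results, csv, row.names = FALSE)
  jsonlite::write_json(
    list(results = report$results, manifest = report$manifest),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(csv = csv, json = json))
}

#' Recompute the published cost-per-QALY arithmetic
#'
#' Reads the packaged transcription of the published per-group summary
#' cells (life expectancy, QALE by cognition stratum, insurer-paid and
#' out-of-pocket lifetime costs, and the printed cost-per-QALY values) and
#' recomputes total lifetime cost and CER per stratum from the cost and
#' QALE cells. Printed CERs should be matched within 1 USD (rounding of
#' the printed QALE); the overall results-text row checks that the insurer
#' and out-of-pocket components add exactly to the printed total.
#'
#' @return data frame with recomputed `total`, `cer_partial`, `cer_poor`
#'   and the differences from the printed values.
#' @export
run_worked_examples <- function() {
  path <- system.file("extdata", "printed_cer_table.csv",
                      package = "pmvcea")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$total <- tab$cost_insurer + tab$cost_oop
  tab$cer_partial <- ifelse(is.na(tab$qale_partial), NA,
                            round(tab$total / tab$qale_partial))
  tab$cer_poor <- ifelse(is.na(tab$qale_poor), NA,
                         round(tab$total / tab$qale_poor))
  tab$cer_partial_diff <- tab$cer_partial - tab$cer_partial_printed
  tab$cer_poor_diff <- tab$cer_poor - tab$cer_poor_printed
  tab$total_diff <- tab$total - tab$total_printed
  tab
}
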