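#' Read and validate pipeline input tables
#'
#' CSV readers for the five pipeline inputs. Each checks the required
#' columns and basic value constraints on load.
#'
#' @param path CSV file path.
#' @return a validated data frame.
#' @name pipeline-io
NULL

read_checked <- function(path, required, check = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(basename(path), " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(check)) check(df)
  df
}

#' @rdname pipeline-io
#' @export
read_cohort <- function(path) {
  read_checked(path,
    c("patient_id", "age_at_entry", "sex", "time_months", "event",
      "group_label"),
    function(df) {
      if (any(df$time_months < 0)) stop("negative follow-up time")
      if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
      if (any(df$age_at_entry < 0)) stop("negative age")
    })
}

#' @rdname pipeline-io
#' @export
read_utility_survey <- function(path) {
  read_checked(path,
    c("respondent_id", "duration_months", "utility", "cognition"),
    function(df) {
      if (any(df$utility < -1 | df$utility > 1)) {
        stop("utilities must lie in [-1, 1]")
      }
      if (!all(df$cognition %in% c("partial", "poor"))) {
        stop("cognition must be 'partial' or 'poor'")
      }
    })
}

#' @rdname pipeline-io
#' @export
read_claims <- function(path) {
  read_checked(path,
    c("patient_id", "month_index", "cost", "calendar_year"),
    function(df) {
      if (any(df$cost < 0)) stop("negative costs")
      if (any(df$month_index < 1)) stop("month_index must be >= 1")
    })
}

#' @rdname pipeline-io
#' @export
read_oop_survey <- function(path) {
  read_checked(path,
    c("respondent_id", "duration_months", "monthly_expense"),
    function(df) {
      if (any(df$monthly_expense < 0)) stop("negative expenses")
    })
}

#' Write the synthetic pipeline inputs to CSV
#'
#' Generates the full set of input tables for a scenario (cohort, life
#' table, utility survey, insurer claims, out-of-pocket survey) and writes
#' them in the dialects the readers expect.
#'
#' @param scenario a [simulation_scenario].
#' @param dir output directory (created if needed).
#' @param seed master seed; per-table seeds are derived by small offsets.
#' @return invisibly, the named list of file paths.
#' @export
write_scenario_inputs <- function(scenario, dir, seed = scenario$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(scenario, seed = seed)
  survey <- simulate_utility_survey(scenario, cohort, seed = seed + 1L)
  costs <- simulate_costs(scenario, cohort, seed = seed + 2L)
  table <- make_life_table(scenario)
  paths <- list(
    cohort = file.path(dir, "cohort.csv"),
    life_table = file.path(dir, "life_table.csv"),
    utility_survey = file.path(dir, "utility_survey.csv"),
    claims = file.path(dir, "claims.csv"),
    oop_survey = file.path(dir, "oop_survey.csv"))
  utils::write.csv(cohort, paths$cohort, row.names = FALSE)
  utils::write.csv(table$table, paths$life_table, row.names = FALSE)
  utils::write.csv(survey, paths$utility_survey, row.names = FALSE)
  utils::write.csv(costs$claims, paths$claims, row.names = FALSE)
  utils::write.csv(costs$oop_survey, paths$oop_survey, row.names = FALSE)
  invisible(paths)
}
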