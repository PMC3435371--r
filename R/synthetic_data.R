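#' Simulation scenario with known ground truth
#'
#' Bundles every parameter of the synthetic cohort: Gompertz-Makeham
#' background mortality, a planted constant monthly excess hazard,
#' administrative censoring, duration-dependent utility and cost curves per
#' cognition stratum, a planted latent-class comorbidity structure, and a
#' master seed. The defaults emulate a prolonged-mechanical-ventilation
#' cohort: mean entry age about 72 years, life expectancy of 2-3 years,
#' mean utility near 0.35 (partial cognition) and 0.10 (poor cognition),
#' and front-loaded monthly costs.
#'
#' @param n_patients cohort size.
#' @param mean_age,sd_age,min_age,max_entry_age entry-age distribution
#'   (normal, truncated), in years.
#' @param female_frac proportion female.
#' @param gm_a,gm_b,gm_c Gompertz-Makeham annual hazard
#'   `c + a * exp(b * age)`.
#' @param female_rate_mult multiplier on the annual hazard rate for
#'   females.
#' @param max_age terminal life-table age (annual death probability 1).
#' @param excess_hazard planted constant excess monthly death probability.
#' @param censor_months administrative censoring month.
#' @param horizon lifetime horizon in months for ground-truth quantities.
#' @param utility named list per stratum (`partial`, `poor`) of
#'   `start` (utility at entry), `drift` (per month), `noise_sd`;
#'   plus `partial_frac`, the proportion of respondents with partial
#'   cognition.
#' @param cost named list per source (`insurer`, `oop`) of `initial`
#'   (USD/month at entry), `plateau`, `decay` (per month), plus
#'   `noise_sdlog` (lognormal multiplicative noise).
#' @param lca list with `pi` (class weights) and `rho` (classes x items
#'   matrix of item probabilities).
#' @param entry_years calendar years over which entry is uniform.
#' @param cpi_factors named vector of year-to-2010 CPI multipliers
#'   covering `entry_years` and the follow-up they imply.
#' @param seed master seed.
#' @return a `simulation_scenario` list.
#' @export
simulation_scenario <- function(
    n_patients = 2000,
    mean_age = 72, sd_age = 14.5, min_age = 18, max_entry_age = 99,
    female_frac = 0.40,
    gm_a = 3e-5, gm_b = 0.09, gm_c = 5e-4, female_rate_mult = 0.6,
    max_age = 110,
    excess_hazard = 0.025,
    censor_months = 120,
    horizon = 300,
    utility = list(
      partial = list(start = 0.37, drift = -5e-4, noise_sd = 0.10),
      poor = list(start = 0.11, drift = -2e-4, noise_sd = 0.05),
      partial_frac = 0.38),
    cost = list(
      insurer = list(initial = 2500, plateau = 700, decay = 0.15),
      oop = list(initial = 1200, plateau = 750, decay = 0.10),
      noise_sdlog = 0.5),
    lca = list(
      pi = c(0.45, 0.35, 0.20),
      rho = rbind(c(0.80, 0.70, 0.10, 0.10, 0.20, 0.10),
                  c(0.10, 0.20, 0.80, 0.70, 0.10, 0.20),
                  c(0.10, 0.10, 0.10, 0.20, 0.80, 0.70))),
    entry_years = 1998:2007,
    cpi_factors = NULL,
    seed = 20120906) {
  if (is.null(cpi_factors)) {
    yrs <- seq(min(entry_years), 2010)
    cpi_factors <- stats::setNames(
      1 + 0.008 * (2010 - yrs), as.character(yrs))
  }
  stopifnot(excess_hazard >= 0, excess_hazard <= 1,
            abs(sum(lca$pi) - 1) < 1e-8,
            all(lca$rho >= 0 & lca$rho <= 1),
            censor_months <= horizon)
  structure(
    list(n_patients = n_patients, mean_age = mean_age, sd_age = sd_age,
         min_age = min_age, max_entry_age = max_entry_age,
         female_frac = female_frac,
         gm_a = gm_a, gm_b = gm_b, gm_c = gm_c,
         female_rate_mult = female_rate_mult, max_age = max_age,
         excess_hazard = excess_hazard, censor_months = censor_months,
         horizon = horizon, utility = utility, cost = cost, lca = lca,
         entry_years = entry_years, cpi_factors = cpi_factors,
         seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Parametric life table from a simulation scenario
#'
#' Annual death probability `q_x = 1 - exp(-(c + a * exp(b * x)))` per age
#' and sex (the female rate is scaled by `female_rate_mult`), with
#' terminal-age closure (`q = 1` at `max_age`).
#'
#' @param scenario a [simulation_scenario].
#' @return a [life_table].
#' @export
make_life_table <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  ages <- 0:scenario$max_age
  rate <- scenario$gm_c + scenario$gm_a * exp(scenario$gm_b * ages)
  rows <- lapply(c(male = 1, female = scenario$female_rate_mult),
                 function(mult) 1 - exp(-mult * rate))
  df <- data.frame(
    sex = rep(c("male", "female"), each = length(ages)),
    age = rep(ages, 2L),
    qx = c(rows$male, rows$female))
  df$qx[df$age == scenario$max_age] <- 1
  if (any(df$qx > 1)) {
    warning("annual death probability clamped to 1 below terminal age")
    df$qx <- pmin(df$qx, 1)
  }
  life_table(df)
}

# Per-patient true monthly survival (background + planted excess hazard),
# months 0..horizon; returns the cohort-average curve.
true_cohort_survival <- function(demographics, table, excess_hazard,
                                 horizon) {
  acc <- numeric(horizon + 1L)
  for (i in seq_len(nrow(demographics))) {
    h_bg <- lt_monthly_trajectory(table, demographics$age_at_entry[i],
                                  as.character(demographics$sex[i]), horizon)
    h <- 1 - (1 - h_bg) * (1 - excess_hazard)
    acc <- acc + c(1, cumprod(1 - h))
  }
  survival_curve(cummin(acc / nrow(demographics)))
}

#' Simulate a PMV cohort with a planted constant excess hazard
#'
#' Each patient's monthly death probability combines the background hazard
#' at their current age with the planted excess:
#' `1 - (1 - h_bg)(1 - h_E)`. Death months are drawn from the implied
#' discrete lifetime distribution; administrative censoring applies at
#' `censor_months`. Ground truth (the exact cohort-average survival curve
#' with and without excess, and true restricted-mean life expectancy) is
#' attached as attribute `"truth"`.
#'
#' @param scenario a [simulation_scenario].
#' @param seed seed; defaults to the scenario's master seed.
#' @return data frame `patient_id`, `age_at_entry`, `sex`, `entry_year`,
#'   `time_months`, `event`, `group_label`, with attribute `truth`.
#' @export
simulate_cohort <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(as.integer(seed))
  n <- scenario$n_patients
  age <- pmin(pmax(stats::rnorm(n, scenario$mean_age, scenario$sd_age),
                   scenario$min_age), scenario$max_entry_age)
  sex <- ifelse(stats::runif(n) < scenario$female_frac, "female", "male")
  entry_year <- sample(scenario$entry_years, n, replace = TRUE)
  table <- make_life_table(scenario)
  cm <- scenario$censor_months
  time <- integer(n); event <- integer(n)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    h_bg <- lt_monthly_trajectory(table, age[i], sex[i], cm)
    s <- cumprod((1 - h_bg) * (1 - scenario$excess_hazard))
    # inverse-CDF draw on the monthly grid: death in month t when
    # S(t-1) >= u > S(t); censored if still alive at cm
    if (u[i] < s[cm]) {
      time[i] <- cm; event[i] <- 0L
    } else {
      time[i] <- which(s < u[i])[1L]; event[i] <- 1L
    }
  }
  cohort <- data.frame(
    patient_id = seq_len(n), age_at_entry = age, sex = sex,
    entry_year = entry_year, time_months = time, event = event,
    group_label = "synthetic", stringsAsFactors = FALSE)
  s_true <- true_cohort_survival(cohort, table, scenario$excess_hazard,
                                 scenario$horizon)
  s_ref <- expected_reference_survival(cohort, table, scenario$horizon)
  attr(cohort, "truth") <- list(
    survival = s_true, reference = s_ref,
    le_years = life_expectancy(s_true),
    le_followup_years = sum(s_true$probs[2:(cm + 1L)]) / 12,
    life_table = table, scenario = scenario)
  cohort
}

# True mean utility at duration t (months) for one stratum.
true_utility <- function(scenario, stratum, t) {
  p <- scenario$utility[[stratum]]
  pmin(pmax(p$start + p$drift * t, -1), 1)
}

# True mean monthly cost level at month t for source "insurer" or "oop".
true_cost_level <- function(scenario, source, t) {
  p <- scenario$cost[[source]]
  p$plateau + (p$initial - p$plateau) * exp(-p$decay * t)
}

# Sample durations-to-date from the survivor distribution implied by the
# cohort's true survival curve (prevalent cross-section: density ~ S(t)).
sample_durations <- function(truth, n, max_month) {
  probs <- truth$survival$probs[2:(max_month + 1L)]
  sample.int(max_month, n, replace = TRUE, prob = probs)
}

#' Simulate a cross-sectional utility survey
#'
#' Respondent durations-to-date follow the survivor distribution of the
#' cohort's true survival curve; utilities sit on the stratum's true
#' duration curve plus Gaussian noise, truncated to \[-1, 1\].
#'
#' @param scenario a [simulation_scenario].
#' @param cohort a cohort from [simulate_cohort()] (supplies the survivor
#'   distribution).
#' @param n_respondents survey size (default 142, the convenience-sample
#'   scale the design emulates).
#' @param seed seed.
#' @return data frame `respondent_id`, `duration_months`, `utility`,
#'   `cognition`.
#' @export
simulate_utility_survey <- function(scenario, cohort, n_respondents = 142,
                                    seed = scenario$seed + 1L) {
  set.seed(as.integer(seed))
  truth <- attr(cohort, "truth")
  dur <- sample_durations(truth, n_respondents, scenario$censor_months)
  stratum <- ifelse(stats::runif(n_respondents) <
                      scenario$utility$partial_frac, "partial", "poor")
  noise <- vapply(stratum, function(s) scenario$utility[[s]]$noise_sd,
                  numeric(1))
  u <- vapply(seq_len(n_respondents), function(i) {
    true_utility(scenario, stratum[i], dur[i])
  }, numeric(1)) + stats::rnorm(n_respondents, 0, noise)
  data.frame(respondent_id = seq_len(n_respondents),
             duration_months = dur,
             utility = pmin(pmax(u, -1), 1),
             cognition = stratum, stringsAsFactors = FALSE)
}

#' Simulate insurer claims and an out-of-pocket survey
#'
#' Insurer claims: one record per alive patient-month with cost equal to
#' the true level curve times mean-one lognormal noise, recorded in nominal
#' (pre-CPI) currency for the record's calendar year. Out-of-pocket survey:
#' cross-sectional respondents with last-month expenses on the true
#' out-of-pocket level curve (2010 USD) with the same noise model. True
#' lifetime costs (level curve integrated against true survival to the
#' horizon) are attached as attribute `"truth"`.
#'
#' @param scenario a [simulation_scenario].
#' @param cohort a cohort from [simulate_cohort()].
#' @param n_oop out-of-pocket survey size (default 165).
#' @param seed seed.
#' @return list with `claims` (patient_id, month_index, cost,
#'   calendar_year, source) and `oop_survey` (respondent_id,
#'   duration_months, monthly_expense); attribute `truth` holds
#'   `lifetime_insurer` and `lifetime_oop`.
#' @export
simulate_costs <- function(scenario, cohort, n_oop = 165,
                           seed = scenario$seed + 2L) {
  set.seed(as.integer(seed))
  truth <- attr(cohort, "truth")
  sdlog <- scenario$cost$noise_sdlog
  months_alive <- cohort$time_months
  pid <- rep(cohort$patient_id, months_alive)
  mon <- unlist(lapply(months_alive, seq_len), use.names = FALSE)
  eyr <- rep(cohort$entry_year, months_alive)
  level <- true_cost_level(scenario, "insurer", mon)
  noise <- stats::rlnorm(length(mon), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  cal_year <- pmin(eyr + (mon - 1L) %/% 12L, 2010L)
  cost_2010 <- level * noise
  claims <- data.frame(
    patient_id = pid, month_index = mon,
    cost = cost_2010 / as.numeric(scenario$cpi_factors[as.character(cal_year)]),
    calendar_year = cal_year, source = "insurer",
    stringsAsFactors = FALSE)
  dur <- sample_durations(truth, n_oop, scenario$censor_months)
  oop_level <- true_cost_level(scenario, "oop", dur)
  oop_noise <- stats::rlnorm(n_oop, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  oop <- data.frame(respondent_id = seq_len(n_oop),
                    duration_months = dur,
                    monthly_expense = oop_level * oop_noise,
                    stringsAsFactors = FALSE)
  h <- scenario$horizon
  s_true <- truth$survival$probs[2:(h + 1L)]
  out <- list(claims = claims, oop_survey = oop)
  attr(out, "truth") <- list(
    lifetime_insurer = sum(true_cost_level(scenario, "insurer", 1:h) * s_true),
    lifetime_oop = sum(true_cost_level(scenario, "oop", 1:h) * s_true))
  out
}

#' Simulate a binary comorbidity matrix with planted latent classes
#'
#' Class membership follows the scenario's class weights; items are
#' independent Bernoulli within class. True class labels are attached as
#' attribute `"class"`.
#'
#' @param scenario a [simulation_scenario].
#' @param n number of patients (default the scenario's cohort size).
#' @param seed seed.
#' @return binary matrix (patients x items) with attribute `class`.
#' @export
simulate_comorbidity <- function(scenario, n = scenario$n_patients,
                                 seed = scenario$seed + 3L) {
  set.seed(as.integer(seed))
  pi <- scenario$lca$pi
  rho <- scenario$lca$rho
  cls <- sample.int(length(pi), n, replace = TRUE, prob = pi)
  X <- matrix(stats::rbinom(n * ncol(rho), 1L,
                            prob = as.vector(t(rho[cls, , drop = FALSE]))),
              nrow = n, byrow = TRUE)
  colnames(X) <- paste0("dx", seq_len(ncol(rho)))
  attr(X, "class_truth") <- cls
  X
}
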