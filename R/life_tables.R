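#' Life table of annual death probabilities
#'
#' Background-population mortality: one annual probability of death `qx` per
#' (sex, single year of age). The age range must be contiguous per sex and
#' the terminal age must have `qx = 1` (closure rule), so any trajectory
#' reaching the terminal age dies within twelve months. Ages beyond the
#' tabulated range are treated as the terminal age.
#'
#' @param df data frame with columns `sex` (`"female"`/`"male"`), `age`
#'   (integer years) and `qx` (probability in \[0, 1\]).
#' @return a `life_table` object: the validated data frame plus a per-sex
#'   lookup used by the hazard functions.
#' @export
life_table <- function(df) {
  req <- c("sex", "age", "qx")
  if (!all(req %in% names(df))) {
    stop("life table needs columns: ", paste(req, collapse = ", "))
  }
  df <- df[order(df$sex, df$age), req]
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% c("female", "male"))) {
    stop("life table 'sex' must be 'female' or 'male'")
  }
  df$age <- as.integer(df$age)
  if (any(df$qx < 0 | df$qx > 1) || anyNA(df$qx)) {
    stop("life table 'qx' must lie in [0, 1]")
  }
  lookup <- list()
  for (sx in unique(df$sex)) {
    sub <- df[df$sex == sx, ]
    if (any(duplicated(sub$age))) stop("duplicated age for sex ", sx)
    if (!identical(sub$age, seq(min(sub$age), max(sub$age)))) {
      stop("ages must form a contiguous range for sex ", sx)
    }
    if (sub$qx[nrow(sub)] != 1) {
      stop("terminal age must have qx = 1 for sex ", sx)
    }
    lookup[[sx]] <- list(min_age = min(sub$age), qx = sub$qx)
  }
  structure(list(table = df, lookup = lookup), class = "life_table")
}

#' Read a life table from CSV
#'
#' Expects a header with columns `sex`, `age`, `qx`, one row per (sex, age).
#'
#' @param path file path.
#' @return a [life_table].
#' @export
read_life_table <- function(path) {
  life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Monthly death probability from an annual one
#'
#' Constant-hazard discretisation within the year:
#' `1 - (1 - q_annual)^(1/12)`.
#'
#' @param q_annual annual death probability (vectorised), in \[0, 1\].
#' @return monthly death probability in \[0, 1\].
#' @export
monthly_hazard_from_annual <- function(q_annual) {
  if (anyNA(q_annual) || any(q_annual < 0) || any(q_annual > 1)) {
    stop("q_annual must lie in [0, 1]")
  }
  1 - (1 - q_annual)^(1 / 12)
}

# Annual qx at integer 'ages' for one sex; beyond-table ages use terminal qx
# (= 1 by the closure rule).
lt_annual_q <- function(table, sex, ages) {
  lk <- table$lookup[[sex]]
  if (is.null(lk)) stop("no life-table entries for sex ", sex)
  idx <- ages - lk$min_age + 1L
  if (any(idx < 1L)) stop("age below life-table range")
  idx[idx > length(lk$qx)] <- length(lk$qx)
  lk$qx[idx]
}

# Monthly hazard trajectory for one patient over months 0..(h-1): the hazard
# applying in interval [t, t+1) uses integer current age floor(age0 + t/12).
lt_monthly_trajectory <- function(table, age0, sex, horizon_months) {
  t <- seq_len(horizon_months) - 1L
  ages <- as.integer(floor(age0 + t / 12))
  monthly_hazard_from_annual(lt_annual_q(table, sex, ages))
}

check_demographics <- function(demographics) {
  if (!is.data.frame(demographics) || nrow(demographics) == 0L) {
    stop("demographics must be a non-empty data frame")
  }
  if (!all(c("age_at_entry", "sex") %in% names(demographics))) {
    stop("demographics needs columns age_at_entry and sex")
  }
  if (any(demographics$age_at_entry < 0)) stop("age_at_entry must be >= 0")
  invisible(demographics)
}

#' Expected reference survival of an age/sex-matched population
#'
#' Deterministic backend for the reference survival function: for each
#' patient the product of monthly survival probabilities along their aging
#' trajectory, averaged over patients. This is the exact expectation of the
#' Monte-Carlo referent procedure in [simulate_reference_survival()].
#'
#' @param demographics data frame with columns `age_at_entry` (years) and
#'   `sex`.
#' @param table a [life_table].
#' @param horizon_months months to evaluate (curve covers `0:horizon`).
#' @return a [survival_curve] for the matched reference population.
#' @export
expected_reference_survival <- function(demographics, table, horizon_months) {
  check_demographics(demographics)
  stopifnot(inherits(table, "life_table"), horizon_months >= 1)
  acc <- numeric(horizon_months + 1L)
  for (i in seq_len(nrow(demographics))) {
    h <- lt_monthly_trajectory(table, demographics$age_at_entry[i],
                               as.character(demographics$sex[i]),
                               horizon_months)
    acc <- acc + c(1, cumprod(1 - h))
  }
  survival_curve(cummin(acc / nrow(demographics)))
}

#' Monte-Carlo reference survival
#'
#' Draws `n_reps` age/sex-matched referents per patient whose monthly death
#' events are Bernoulli with life-table hazards along the aging trajectory,
#' and returns the pooled empirical survival curve. Equivalent (and faster)
#' binomial-thinning form: the count of referents alive after month t is
#' Binomial(alive at t, 1 - hazard(t)).
#'
#' @inheritParams expected_reference_survival
#' @param n_reps referents per patient (default 100).
#' @param seed integer seed; required for reproducibility.
#' @return a [survival_curve]; converges to
#'   [expected_reference_survival()] as `n_reps` grows.
#' @export
simulate_reference_survival <- function(demographics, table, horizon_months,
                                        n_reps = 100, seed) {
  check_demographics(demographics)
  stopifnot(inherits(table, "life_table"), n_reps >= 1)
  if (horizon_months <= 0) stop("horizon_months must be positive")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  n <- nrow(demographics)
  alive_total <- matrix(0, nrow = horizon_months + 1L, ncol = 1L)
  for (i in seq_len(n)) {
    h <- lt_monthly_trajectory(table, demographics$age_at_entry[i],
                               as.character(demographics$sex[i]),
                               horizon_months)
    alive <- n_reps
    traj <- numeric(horizon_months + 1L)
    traj[1L] <- alive
    for (t in seq_len(horizon_months)) {
      if (alive > 0L) alive <- stats::rbinom(1L, alive, 1 - h[t])
      traj[t + 1L] <- alive
    }
    alive_total <- alive_total + traj
  }
  survival_curve(as.numeric(alive_total) / (n * n_reps))
}
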