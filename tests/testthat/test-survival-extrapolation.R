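test_that("Kaplan-Meier matches hand-computed product limits", {
  # four deaths, no censoring: empirical survival
  s <- kaplan_meier(1:4, rep(1, 4))
  expect_equal(s$probs, c(1, 0.75, 0.5, 0.25, 0))
  # deaths at 1 and 3, censor at 2 (n = 4): 0.75 x (1/2) = 0.375
  s <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 0), horizon = 4)
  expect_equal(s$probs[c(2, 4)], c(0.75, 0.375))
  # all censored: flat at 1
  s <- kaplan_meier(c(2, 5, 7), rep(0, 3), horizon = 8)
  expect_equal(s$probs, rep(1, 9))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "at least one")
  expect_error(kaplan_meier(-1, 1), "nonnegative")
})

test_that("Kaplan-Meier equals the brute-force risk-set oracle on all
          small death/censor configurations", {
  for (n in 1:6) {
    time_sets <- list(seq_len(n), rep(1, n), ((seq_len(n) - 1) %% 3) + 1)
    for (time in time_sets) {
      horizon <- max(time) + 1
      for (mask in 0:(2^n - 1)) {
        event <- as.integer(intToBits(mask))[seq_len(n)]
        got <- kaplan_meier(time, event, horizon)$probs
        want <- km_oracle(time, event, horizon)
        expect_equal(got, want, tolerance = 1e-12,
                     info = sprintf("n=%d times=%s mask=%d", n,
                                    paste(time, collapse = ","), mask))
      }
    }
  }
})

test_that("survival ratio clips into (0, 1) and logit stays finite", {
  s1 <- survival_curve(c(1, 0.5, 0.4))
  sref <- survival_curve(c(1, 1, 0.8))
  w <- survival_ratio(s1, sref, clip_eps = 1e-6)
  expect_equal(w$W[2], 0.5)
  expect_equal(w$logit_w[2], 0)
  expect_equal(w$W[3], 0.5)          # 0.4 / 0.8
  # identical curves clip at 1 - eps with finite logit
  w2 <- survival_ratio(sref, sref)
  expect_equal(w2$W, rep(1 - 1e-6, 3))
  expect_true(all(is.finite(w2$logit_w)))
  expect_error(survival_ratio(s1, sref, clip_eps = 0.7), "clip_eps")
})

test_that("logit-linear fit recovers an exact line and flat ratios", {
  t <- 0:40
  w <- data.frame(month = t, logit_w = 2 - 0.05 * t)
  fit <- fit_logit_linear(w, c(10, 40))
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$slope, -0.05, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-8)
  # constant ratio: zero slope
  wc <- data.frame(month = t, logit_w = rep(-1.2, 41))
  expect_equal(fit_logit_linear(wc, c(0, 40))$slope, 0, tolerance = 1e-12)
  expect_error(fit_logit_linear(w[1:2, ], c(0, 1)), "at least 3")
  w$logit_w[20:30] <- NA
  expect_error(fit_logit_linear(w, c(19, 31)), "degenerate")
})

test_that("extrapolation splices continuously and respects monotonicity", {
  # flat reference beyond the boundary: tail follows expit of the line,
  # rescaled to pass through the boundary value
  km <- survival_curve(exp(-0.05 * (0:24)))
  sref <- survival_curve(rep(1, 61))
  w <- survival_ratio(km, sref)
  fit <- fit_logit_linear(w, c(12, 24))
  ext <- extrapolate(sref, fit, km)
  expect_equal(ext$segment_boundary, 24)
  expect_equal(length(ext$probs), 61)
  # continuity at the boundary
  expect_equal(ext$probs[25], km$probs[25])
  # tail equals expit(line) x continuity scale, clamped nonincreasing
  line <- stats::plogis(fit$intercept + fit$slope * (25:60))
  scale <- km$probs[25] / stats::plogis(fit$intercept + fit$slope * 24)
  expect_equal(ext$probs[26:61], cummin(pmin(line * scale, km$probs[25])),
               tolerance = 1e-12)
  expect_true(all(diff(ext$probs) <= 1e-12))
  # positive slope beyond the clip bound warns and clamps
  up <- structure(list(intercept = 5, slope = 0.5, fit_window = c(12, 24),
                       residual_sd = 0), class = "logit_ratio_fit")
  expect_warning(ext2 <- extrapolate(sref, up, km), "clamped")
  expect_true(all(ext2$probs[26:61] <= km$probs[25] + 1e-12))
})

test_that("extrapolated curve stays below the reference beyond the
          boundary when the fitted ratio is below 1", {
  lt <- flat_life_table(0.06)
  sc <- test_scenario(n = 300, censor_months = 48)
  coh <- simulate_cohort(sc, seed = 3)
  res <- extrapolated_survival(coh, attr(coh, "truth")$life_table,
                               horizon = 120)
  b <- res$curve$segment_boundary
  idx <- (b + 2):121
  expect_true(all(res$curve$probs[idx] <= res$reference$probs[idx] + 1e-9))
})

test_that("restricted mean survival follows the rectangle convention", {
  expect_equal(life_expectancy(survival_curve(rep(1, 301))), 25)
  # exponential closed form within the 5% discretisation error of the
  # right-endpoint rule
  s <- survival_curve(exp(-0.1 * (0:300)))
  expect_lt(abs(life_expectancy(s) - 1 / (0.1 * 12)) / (1 / (0.1 * 12)),
            0.05)
  # immediate drop: zero life expectancy under month-end sampling
  expect_equal(life_expectancy(survival_curve(c(1, rep(0, 12)))), 0)
})

test_that("planted constant-excess-hazard life expectancy is recovered
          within 5% in most replicates at the design follow-up", {
  ok <- 0L
  n_rep <- 6L
  biases_48 <- numeric(n_rep)
  for (seed in seq_len(n_rep)) {
    sc <- test_scenario(n = 1200, censor_months = 120, horizon = 300)
    coh <- simulate_cohort(sc, seed = 100 + seed)
    tr <- attr(coh, "truth")
    res <- extrapolated_survival(coh, tr$life_table, horizon = 300)
    rel <- abs(res$life_expectancy - tr$le_years) / tr$le_years
    ok <- ok + (rel <= 0.05)
    # truncating follow-up to 48 months degrades accuracy but stays
    # within the 20% bound the truncate-and-extrapolate design validates
    trunc <- coh
    over <- trunc$time_months > 48
    trunc$time_months[over] <- 48
    trunc$event[over] <- 0L
    res48 <- extrapolated_survival(trunc, tr$life_table, horizon = 300,
                                   followup = 48)
    biases_48[seed] <- abs(res48$life_expectancy - tr$le_years) /
      tr$le_years
  }
  expect_gte(ok, 5L)  # >= 5 of 6 within 5%
  expect_true(all(biases_48 <= 0.20))
})
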