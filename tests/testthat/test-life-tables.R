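test_that("annual-to-monthly hazard conversion follows the closed form", {
  expect_equal(monthly_hazard_from_annual(0), 0)
  expect_equal(monthly_hazard_from_annual(1), 1)
  # frozen from an independent high-precision evaluation of 1 - 0.88^(1/12)
  expect_equal(monthly_hazard_from_annual(0.12), 0.0105962410,
               tolerance = 1e-8)
  q <- seq(0, 1, by = 0.05)
  expect_true(all(diff(monthly_hazard_from_annual(q)) > 0))
  expect_error(monthly_hazard_from_annual(1.2), "\\[0, 1\\]")
  expect_error(monthly_hazard_from_annual(-0.1), "\\[0, 1\\]")
})

test_that("life table constructor enforces its invariants", {
  expect_error(life_table(data.frame(sex = "male", age = 0, qx = 2)),
               "\\[0, 1\\]")
  df <- data.frame(sex = "male", age = c(0, 2), qx = c(0.1, 1))
  expect_error(life_table(df), "contiguous")
  df <- data.frame(sex = "male", age = 0:1, qx = c(0.1, 0.5))
  expect_error(life_table(df), "terminal")
})

test_that("expected reference survival matches hand-computable cases", {
  demo <- data.frame(age_at_entry = 40, sex = "male")
  # no mortality below terminal age: survival stays 1 over the horizon
  lt0 <- flat_life_table(0)
  s <- expected_reference_survival(demo, lt0, 60)
  expect_equal(s$probs, rep(1, 61))
  # constant annual q = 0.12: twelve equal monthly factors give 0.88 at
  # one year
  lt12 <- flat_life_table(0.12)
  s <- expected_reference_survival(demo, lt12, 24)
  expect_equal(s$probs[13], 0.88, tolerance = 1e-12)
  expect_equal(s$probs[25], 0.88^2, tolerance = 1e-12)
  # certain death: gone by month 12
  lt1 <- flat_life_table(1)
  s <- expected_reference_survival(demo, lt1, 24)
  expect_equal(s$probs[13], 0)
  expect_error(expected_reference_survival(demo[0, ], lt12, 12),
               "non-empty")
})

test_that("terminal-age closure kills any trajectory within 12 months", {
  lt <- flat_life_table(0.01, max_age = 90)
  demo <- data.frame(age_at_entry = 90, sex = "female")
  s <- expected_reference_survival(demo, lt, 24)
  expect_equal(s$probs[13], 0)
  # entering above the tabulated range also uses the terminal row
  demo2 <- data.frame(age_at_entry = 95, sex = "female")
  s2 <- expected_reference_survival(demo2, lt, 24)
  expect_equal(s2$probs[13], 0)
})

test_that("Monte-Carlo referents agree with the expectation oracle", {
  demo <- data.frame(age_at_entry = 40, sex = "male")
  lt12 <- flat_life_table(0.12)
  mc <- simulate_reference_survival(demo, lt12, 12, n_reps = 10000,
                                    seed = 7)
  n_tot <- 10000
  se <- sqrt(0.88 * 0.12 / n_tot)
  expect_lt(abs(mc$probs[13] - 0.88), 3 * se)
  # reproducibility under a fixed seed
  mc2 <- simulate_reference_survival(demo, lt12, 12, n_reps = 10000,
                                     seed = 7)
  expect_identical(mc$probs, mc2$probs)
  # zero-mortality table gives a flat curve for any seed
  mc0 <- simulate_reference_survival(demo, flat_life_table(0), 24,
                                     n_reps = 50, seed = 99)
  expect_equal(mc0$probs, rep(1, 25))
  expect_error(simulate_reference_survival(demo, lt12, 0, seed = 1),
               "horizon")
})

test_that("Monte-Carlo curves stay within binomial error of expectation", {
  lt <- flat_life_table(0.08)
  demo <- data.frame(age_at_entry = c(55, 70, 80), sex = c("male",
                     "female", "male"))
  exp_curve <- expected_reference_survival(demo, lt, 36)
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    mc <- simulate_reference_survival(demo, lt, 36, n_reps = 400,
                                      seed = seed)
    n_tot <- 3 * 400
    band <- 3 * sqrt(pmax(exp_curve$probs * (1 - exp_curve$probs), 1e-12) /
                       n_tot)
    ok <- abs(mc$probs - exp_curve$probs) <= pmax(band, 1e-12)
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.95)
})

test_that("life-table CSV round-trips through the reader", {
  lt <- flat_life_table(0.05, max_age = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(lt$table, path, row.names = FALSE)
  lt2 <- read_life_table(path)
  expect_equal(lt2$table$qx, lt$table$qx)
})
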