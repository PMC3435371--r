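test_that("parametric life table inverts its closed form", {
  # a = 0: constant annual hazard c; choose c so q = 0.1 everywhere
  sc <- test_scenario(gm_a = 0, gm_c = -log(1 - 0.1), female_rate_mult = 1)
  lt <- make_life_table(sc)
  below <- lt$table$age < sc$max_age
  expect_equal(unique(round(lt$table$qx[below], 12)), 0.1)
  expect_equal(lt$table$qx[!below], c(1, 1))
  # zero parameters: no mortality below the terminal age
  sc0 <- test_scenario(gm_a = 0, gm_c = 0)
  lt0 <- make_life_table(sc0)
  expect_true(all(lt0$table$qx[lt0$table$age < sc0$max_age] == 0))
  # q nondecreasing in age for positive Gompertz parameters
  sc1 <- test_scenario()
  lt1 <- make_life_table(sc1)
  for (sx in c("male", "female")) {
    qx <- lt1$table$qx[lt1$table$sex == sx]
    expect_true(all(diff(qx) >= 0))
  }
})

test_that("cohort simulation is reproducible and respects limits", {
  sc <- test_scenario(n = 200)
  c1 <- simulate_cohort(sc, seed = 5)
  c2 <- simulate_cohort(sc, seed = 5)
  expect_identical(c1$time_months, c2$time_months)
  expect_identical(c1$event, c2$event)
  expect_true(all(c1$time_months >= 1 & c1$time_months <= sc$censor_months))
  expect_true(all(c1$event[c1$time_months < sc$censor_months] == 1))
  # overwhelming excess hazard: nearly everyone dies in month 1
  sch <- test_scenario(n = 200, excess_hazard = 0.999)
  ch <- simulate_cohort(sch, seed = 6)
  expect_gt(mean(ch$time_months == 1), 0.95)
})

test_that("with no excess hazard the cohort matches the reference
          survival", {
  sc <- test_scenario(n = 1500, excess_hazard = 0, censor_months = 60)
  coh <- simulate_cohort(sc, seed = 7)
  tr <- attr(coh, "truth")
  km <- kaplan_meier(coh$time_months, coh$event, horizon = 60)
  ref <- tr$reference$probs[1:61]
  n <- nrow(coh)
  band <- 3 * sqrt(pmax(ref * (1 - ref), 1e-12) / n)
  expect_true(mean(abs(km$probs - ref) <= band + 0.01) > 0.9)
  # and the planted truth curve equals the reference when excess = 0
  expect_equal(tr$survival$probs, tr$reference$probs, tolerance = 1e-12)
})

test_that("utility survey sits on the planted curve", {
  sc <- test_scenario(n = 600)
  coh <- simulate_cohort(sc, seed = 8)
  # zero noise: utilities exactly on the stratum curve
  sc0 <- sc
  sc0$utility$partial$noise_sd <- 0
  sc0$utility$poor$noise_sd <- 0
  us <- simulate_utility_survey(sc0, coh, n_respondents = 200, seed = 9)
  want <- mapply(function(s, d) pmvcea:::true_utility(sc0, s, d),
                 us$cognition, us$duration_months)
  expect_equal(us$utility, unname(want), tolerance = 1e-12)
  # with noise, the smoothed estimate tracks the truth at interior months
  us2 <- simulate_utility_survey(sc, coh, n_respondents = 500, seed = 10)
  sub <- us2[us2$cognition == "partial", ]
  q <- kernel_smooth(sub$duration_months, sub$utility, fraction = 0.10,
                     horizon = 120)
  k <- ceiling(0.10 * nrow(sub))
  se <- sc$utility$partial$noise_sd / sqrt(k)
  for (t in c(12, 24, 48)) {
    expect_lt(abs(q$q[t + 1] - pmvcea:::true_utility(sc, "partial", t)),
              3 * se + 0.02)
  }
})

test_that("cost generator recovers its planted level curves", {
  sc <- test_scenario(n = 400)
  coh <- simulate_cohort(sc, seed = 11)
  # zero noise, flat level: the monthly mean cost is the level exactly
  sc0 <- sc
  sc0$cost$noise_sdlog <- 1e-12
  sc0$cost$insurer <- list(initial = 800, plateau = 800, decay = 0.1)
  cs0 <- simulate_costs(sc0, coh, seed = 12)
  claims <- cs0$claims
  claims$cost <- cpi_adjust(claims$cost, claims$calendar_year,
                            sc0$cpi_factors)
  alive <- vapply(1:sc0$censor_months,
                  function(t) sum(coh$time_months >= t), numeric(1))
  cc <- monthly_mean_cost(claims, alive)
  expect_equal(cc$c, rep(800, sc0$censor_months), tolerance = 1e-6)
  # zero level curve gives zero costs
  scz <- sc
  scz$cost$insurer <- list(initial = 0, plateau = 0, decay = 0.1)
  csz <- simulate_costs(scz, coh, seed = 13)
  expect_true(all(csz$claims$cost == 0))
  # same seed reproduces the claims table
  cs1 <- simulate_costs(sc, coh, seed = 14)
  cs2 <- simulate_costs(sc, coh, seed = 14)
  expect_identical(cs1$claims$cost, cs2$claims$cost)
})

test_that("comorbidity generator matches its mixture moments", {
  sc <- test_scenario()
  X <- simulate_comorbidity(sc, n = 4000, seed = 15)
  expect_true(all(X %in% c(0, 1)))
  want <- as.numeric(sc$lca$pi %*% sc$lca$rho)
  se <- sqrt(want * (1 - want) / 4000)
  expect_true(all(abs(colMeans(X) - want) <= 3 * se + 1e-3))
  # degenerate rho gives deterministic patterns
  scd <- test_scenario(lca = list(pi = c(0.5, 0.5),
                                  rho = rbind(rep(1, 3), rep(0, 3))))
  Xd <- simulate_comorbidity(scd, n = 100, seed = 16)
  cls <- attr(Xd, "class_truth")
  expect_true(all(Xd[cls == 1, ] == 1))
  expect_true(all(Xd[cls == 2, ] == 0))
})

test_that("scenario inputs round-trip through the CSV writers", {
  sc <- test_scenario(n = 60, censor_months = 36)
  dir <- withr::local_tempdir()
  paths <- write_scenario_inputs(sc, dir, seed = 17)
  coh <- read_cohort(paths$cohort)
  expect_equal(nrow(coh), 60)
  lt <- read_life_table(paths$life_table)
  expect_s3_class(lt, "life_table")
  us <- read_utility_survey(paths$utility_survey)
  expect_true(all(us$cognition %in% c("partial", "poor")))
  cl <- read_claims(paths$claims)
  expect_equal(sort(unique(cl$patient_id)),
               sort(unique(coh$patient_id[coh$time_months >= 1])))
  oop <- read_oop_survey(paths$oop_survey)
  expect_true(all(oop$monthly_expense >= 0))
})
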