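test_that("single-class model reduces to item-wise sample means", {
  set.seed(2)
  X <- matrix(rbinom(200 * 4, 1, c(0.2, 0.5, 0.7, 0.9)), 200, 4,
              byrow = TRUE)
  m <- fit_lca(X, K = 1, seed = 5)
  expect_equal(m$pi, 1, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(as.numeric(m$rho),
               pmin(pmax(colMeans(X), 1e-4), 1 - 1e-4), tolerance = 1e-6)
})

test_that("EM log-likelihood is nondecreasing and posteriors sum to 1", {
  set.seed(3)
  sc <- test_scenario()
  X <- simulate_comorbidity(sc, n = 300, seed = 8)
  m <- fit_lca(X, K = 3, n_starts = 3, seed = 9)
  expect_true(all(diff(m$loglik_trace) >= -1e-8))
  post <- lca_posterior(m, X)
  expect_equal(rowSums(post), rep(1, nrow(X)), tolerance = 1e-12)
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_true(all(m$rho >= 0 & m$rho <= 1))
})

test_that("perfectly separated blocks are recovered up to label swap", {
  X <- rbind(matrix(1, 50, 4), matrix(0, 50, 4))
  # only two distinct response patterns: degenerate-model warning
  expect_warning(fit_lca(X, K = 3, n_starts = 1, seed = 1), "patterns")
  m <- fit_lca(X, K = 2, n_starts = 5, seed = 1)
  al <- align_lca(m, c(0.5, 0.5), rbind(rep(1, 4), rep(0, 4)))
  expect_equal(al$pi, c(0.5, 0.5), tolerance = 1e-3, ignore_attr = TRUE)
  expect_true(max(abs(al$rho - rbind(rep(1, 4), rep(0, 4)))) < 2e-3)
  labels <- assign_classes(m, X)
  expect_equal(length(unique(labels[1:50])), 1)
  expect_equal(length(unique(labels[51:100])), 1)
  expect_true(labels[1] != labels[51])
})

test_that("planted class structure is recovered within 0.05 at large n", {
  sc <- test_scenario()
  X <- simulate_comorbidity(sc, n = 5000, seed = 12)
  m <- fit_lca(X, K = 3, n_starts = 6, seed = 13)
  al <- align_lca(m, sc$lca$pi, sc$lca$rho)
  expect_lt(max(abs(al$pi - sc$lca$pi)), 0.05)
  expect_lt(max(abs(al$rho - sc$lca$rho)), 0.05)
  # modal assignment matches the planted classes for most patients
  # (up to the aligning permutation)
  truth <- attr(X, "class_truth")
  labels <- assign_classes(m, X)
  tab <- table(truth, labels)
  expect_gt(sum(apply(tab, 1, max)) / nrow(X), 0.85)
})

test_that("BIC selection finds the planted class count and degenerate
          data collapse to one class", {
  sc <- test_scenario()
  X <- simulate_comorbidity(sc, n = 2000, seed = 20)
  best <- select_k(X, 1:5, n_starts = 4, seed = 21)
  expect_equal(best$K, 3)
  sel <- attr(best, "selection")
  expect_equal(sel$K[which.min(sel$bic)], 3)
  # identical rows: K = 1 minimises BIC by brute-force comparison
  Xd <- matrix(rep(c(1, 0, 1, 0), each = 60), 60, 4)
  bestd <- suppressWarnings(select_k(Xd, 1:3, n_starts = 3, seed = 22))
  expect_equal(bestd$K, 1)
  # k_range of one returns that model
  expect_equal(select_k(X[1:50, ], 1, seed = 1)$K, 1)
})

test_that("symmetric models break assignment ties toward the lowest
          class", {
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  m <- structure(list(K = 2, pi = c(0.5, 0.5),
                      rho = rbind(c(0.5, 0.5), c(0.5, 0.5)),
                      loglik = NA, bic = NA), class = "lca_model")
  expect_equal(assign_classes(m, X), c(1L, 1L))
  expect_error(assign_classes(m, matrix(0, 2, 3)), "mismatch")
})

test_that("age-stratified grouping yields pipeline-ready labels", {
  sc <- test_scenario()
  n <- 600
  X <- simulate_comorbidity(sc, n = n, seed = 30)
  age <- runif(n, 40, 95)
  labels <- lca_group_labels(X, age, k_range = 1:4, n_starts = 3,
                             seed = 31)
  expect_length(labels, n)
  expect_true(all(grepl("^(<65|65-74|75-84|>84)/c[0-9]+$", labels)))
  # bands partition the patients consistently with age
  expect_true(all(startsWith(labels[age < 65], "<65")))
  models <- attr(labels, "models")
  expect_true(all(vapply(models, inherits, logical(1), "lca_model")))
})
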