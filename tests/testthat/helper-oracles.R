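# Independent oracles and small fixtures used across the suite.

# Brute-force product-limit estimator by direct risk-set enumeration.
# At each distinct death time t: n_t = subjects with time >= t (censorings
# at t are still at risk, i.e. deaths precede censorings), d_t = deaths at
# t; S is the running product of (1 - d_t / n_t), sampled at month ends.
km_oracle <- function(time, event, horizon) {
  death_times <- sort(unique(time[event == 1]))
  s <- 1
  steps <- vapply(death_times, function(t) {
    n_t <- sum(time >= t)
    d_t <- sum(time == t & event == 1)
    1 - d_t / n_t
  }, numeric(1))
  vapply(0:horizon, function(m) {
    prod(steps[death_times <= m + 1e-9], na.rm = TRUE)
  }, numeric(1))
}

# Brute-force k-nearest-neighbour mean with the package's tie rule
# (smaller distance, then smaller duration, then input order), written as
# an explicit per-point search rather than a vectorised order().
knn_oracle <- function(x, y, fraction, grid) {
  k <- max(1L, ceiling(fraction * length(x)))
  sapply(grid, function(t) {
    remaining <- seq_along(x)
    picked <- integer(0)
    while (length(picked) < k) {
      d <- abs(x[remaining] - t)
      best <- remaining[d == min(d)]
      if (length(best) > 1L) best <- best[x[best] == min(x[best])]
      best <- best[1L]
      picked <- c(picked, best)
      remaining <- setdiff(remaining, best)
    }
    mean(y[picked])
  })
}

# Flat life table: same annual death probability at every age below the
# terminal age, both sexes.
flat_life_table <- function(q, max_age = 110) {
  df <- data.frame(
    sex = rep(c("female", "male"), each = max_age + 1L),
    age = rep(0:max_age, 2L),
    qx = q)
  df$qx[df$age == max_age] <- 1
  life_table(df)
}

# Best label permutation aligning estimated LCA classes to a truth, by
# total absolute error on the rho matrix. Returns aligned (pi, rho).
align_lca <- function(model, pi_true, rho_true) {
  K <- model$K
  perms <- if (K == 1L) list(1L) else combinat_perms(K)
  best <- NULL; best_err <- Inf
  for (p in perms) {
    err <- sum(abs(model$rho[p, , drop = FALSE] - rho_true)) +
      sum(abs(model$pi[p] - pi_true))
    if (err < best_err) {
      best_err <- err
      best <- list(pi = model$pi[p], rho = model$rho[p, , drop = FALSE])
    }
  }
  best
}

combinat_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Small, fast scenario for unit tests.
test_scenario <- function(n = 400, ...) {
  simulation_scenario(n_patients = n, ...)
}
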