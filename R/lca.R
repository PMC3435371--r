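#' Latent class analysis of binary comorbidity indicators
#'
#' Fits a mixture of independent Bernoulli items by EM: each patient
#' belongs to one of `K` latent classes with weights `pi`; within class k
#' item j is present with probability `rho[k, j]`. Used to group patients
#' with multiple comorbidities into homogeneous clusters.
#'
#' @param X binary matrix, patients in rows, diagnosis indicators in
#'   columns (>= 2 columns).
#' @param K number of latent classes (1 <= K <= rows).
#' @param n_starts random restarts; the best log-likelihood wins.
#' @param tol EM stops when the log-likelihood gain drops below `tol`.
#' @param max_iter iteration cap per start.
#' @param seed integer seed for the random initialisations.
#' @return an `lca_model`: `K`, `pi` (class weights), `rho` (K x items
#'   matrix of positive probabilities), `loglik`, `bic`, `n_params`,
#'   `loglik_trace` of the winning start.
#' @export
fit_lca <- function(X, K, n_starts = 10, tol = 1e-6, max_iter = 500,
                    seed = 1L) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1))) stop("X must be binary")
  if (ncol(X) < 2L) stop("at least 2 indicator items are required")
  n <- nrow(X); j <- ncol(X)
  if (K < 1 || K > n) stop("K must lie in 1..nrow(X)")
  n_patterns <- nrow(unique(X))
  if (K > n_patterns) {
    warning("K exceeds the number of distinct response patterns; ",
            "the model is degenerate")
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    rho <- matrix(stats::runif(K * j, 0.2, 0.8), nrow = K)
    pi <- rep(1 / K, K)
    fit <- lca_em(X, pi, rho, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (K == 1L) break  # closed form; restarts identical
  }
  n_params <- (K - 1) + K * j
  structure(
    list(K = K, pi = best$pi, rho = best$rho, loglik = best$loglik,
         bic = -2 * best$loglik + n_params * log(n), n_params = n_params,
         loglik_trace = best$trace),
    class = "lca_model"
  )
}

# One EM run from given starting values. rho is kept in [1e-4, 1 - 1e-4]
# to avoid degenerate likelihood spikes.
lca_em <- function(X, pi, rho, tol, max_iter) {
  n <- nrow(X)
  rho_min <- 1e-4
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- lca_log_posterior_unnorm(X, pi, rho)       # n x K
    m <- apply(lp, 1L, max)
    ll <- sum(m + log(rowSums(exp(lp - m))))
    trace <- c(trace, ll)
    post <- exp(lp - m)
    post <- post / rowSums(post)
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
    nk <- colSums(post)
    pi <- nk / n
    rho <- pmin(pmax(crossprod(post, X) / nk, rho_min), 1 - rho_min)
  }
  list(pi = pi, rho = rho, loglik = ll, trace = trace)
}

# log(pi_k) + sum_j x_ij log rho_kj + (1 - x_ij) log(1 - rho_kj)
lca_log_posterior_unnorm <- function(X, pi, rho) {
  lr1 <- log(rho); lr0 <- log(1 - rho)
  X %*% t(lr1) + (1 - X) %*% t(lr0) +
    matrix(log(pi), nrow(X), length(pi), byrow = TRUE)
}

#' Log-likelihood of data under a fitted latent class model
#'
#' @param model an `lca_model`.
#' @param X binary matrix with the model's item count.
#' @return total log-likelihood.
#' @export
lca_loglik <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$rho)) stop("item count mismatch")
  lp <- lca_log_posterior_unnorm(X, model$pi, model$rho)
  m <- apply(lp, 1L, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' Posterior class probabilities under a fitted model
#'
#' @inheritParams lca_loglik
#' @return n x K matrix of posterior responsibilities (rows sum to 1).
#' @export
lca_posterior <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$rho)) stop("item count mismatch")
  lp <- lca_log_posterior_unnorm(X, model$pi, model$rho)
  m <- apply(lp, 1L, max)
  post <- exp(lp - m)
  post / rowSums(post)
}

#' Modal class assignment
#'
#' Argmax of the posterior class probability per patient; exact ties go to
#' the lowest class index.
#'
#' @inheritParams lca_loglik
#' @return integer class labels in `1..K`.
#' @export
assign_classes <- function(model, X) {
  post <- lca_posterior(model, X)
  max.col(post, ties.method = "first")
}

#' Select the number of latent classes by information criterion
#'
#' Fits each K in `k_range` and returns the model minimising BIC (the
#' default criterion).
#'
#' @inheritParams fit_lca
#' @param k_range integer vector of candidate class counts.
#' @param criterion `"bic"`.
#' @return the winning `lca_model`, with an attribute
#'   `selection` (data frame of K, loglik, bic).
#' @export
select_k <- function(X, k_range, criterion = "bic", n_starts = 10,
                     tol = 1e-6, max_iter = 500, seed = 1L) {
  criterion <- match.arg(criterion, "bic")
  if (length(k_range) == 0L) stop("k_range must be nonempty")
  fits <- lapply(seq_along(k_range), function(i) {
    fit_lca(X, k_range[i], n_starts = n_starts, tol = tol,
            max_iter = max_iter, seed = seed + i - 1L)
  })
  tab <- data.frame(K = k_range,
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    bic = vapply(fits, `[[`, numeric(1), "bic"))
  best <- fits[[which.min(tab$bic)]]
  attr(best, "selection") <- tab
  best
}

#' @export
print.lca_model <- function(x, ...) {
  cat("<lca_model> K =", x$K, " logLik =", round(x$loglik, 2),
      " BIC =", round(x$bic, 2), "\n")
  cat("  class weights:", paste(signif(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Age-stratified latent-class group labels
#'
#' Fits a latent class model per age band (`<65`, `65-74`, `75-84`,
#' `>84`), selecting the class count by BIC within each band, and returns
#' a `group_label` per patient (`band/cK`) usable directly by the
#' survival and cost pipeline.
#'
#' @param X binary comorbidity matrix.
#' @param age age at entry in years, one per row of `X`.
#' @param k_range candidate class counts per band.
#' @param ... passed to [select_k()].
#' @return character vector of labels, with the per-band fitted models in
#'   attribute `models`.
#' @export
lca_group_labels <- function(X, age, k_range = 1:4, ...) {
  X <- as.matrix(X)
  if (length(age) != nrow(X)) stop("age/X length mismatch")
  band <- cut(age, c(-Inf, 65, 75, 85, Inf), right = FALSE,
              labels = c("<65", "65-74", "75-84", ">84"))
  labels <- character(nrow(X))
  models <- list()
  for (b in levels(band)) {
    idx <- which(band == b)
    if (!length(idx)) next
    ks <- k_range[k_range <= length(idx)]
    model <- select_k(X[idx, , drop = FALSE], ks, ...)
    models[[b]] <- model
    labels[idx] <- paste0(b, "/c", assign_classes(model, X[idx, ,
                                                           drop = FALSE]))
  }
  attr(labels, "models") <- models
  labels
}
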