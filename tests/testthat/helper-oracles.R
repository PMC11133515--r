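# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where they check a wrapped standard test,
# the wrapped function too).

# Benjamini-Hochberg step-up by its definition: sort ascending, take
# p_(i) * m / i, enforce monotonicity from the largest rank down, cap at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    ranked[i] <- min(ranked[i], ranked[i + 1])
  }
  ranked <- pmin(ranked, 1)
  out <- numeric(m)
  out[o] <- ranked
  out
}

# Censored-Gaussian log-likelihood with the censored factor obtained by
# numerical integration of the latent normal density (no pnorm).
loglik_quad <- function(beta, sigma, X, y, censored, bound) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in seq_along(y)) {
    if (censored[i]) {
      f <- stats::integrate(function(t) stats::dnorm(t, eta[i], sigma),
                            -Inf, bound[i], rel.tol = 1e-12)$value
      ll <- ll + log(f)
    } else {
      ll <- ll + stats::dnorm(y[i], eta[i], sigma, log = TRUE)
    }
  }
  ll
}

# Nested grid-search maximiser of the censored-Gaussian likelihood over
# (beta0, beta1, sigma): 13^3 grid refined around the running optimum.
grid_tobit <- function(X, y, censored, bound, center, half_width = 1,
                       rounds = 8, k = 13) {
  best <- center
  w <- rep(half_width, 3)
  for (r in seq_len(rounds)) {
    g1 <- seq(best[1] - w[1], best[1] + w[1], length.out = k)
    g2 <- seq(best[2] - w[2], best[2] + w[2], length.out = k)
    g3 <- seq(max(best[3] - w[3], 1e-4), best[3] + w[3], length.out = k)
    val <- -Inf
    for (a in g1) for (b in g2) for (s in g3) {
      ll <- censmetab::tobit_loglik(c(a, b), s, X, y, censored, bound)
      if (ll > val) { val <- ll; cand <- c(a, b, s) }
    }
    best <- cand
    w <- w * (2 / (k - 1))  # grid spacing becomes the new half-width
  }
  list(par = best, loglik = val)
}

# Exact permutation p-value for a two-sample statistic at small n:
# enumerates every reassignment of the pooled values to group 1.
perm_p <- function(x, y, stat) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- abs(stat(x, y))
  idx <- utils::combn(length(pooled), n1)
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    a <- pooled[idx[, j]]
    b <- pooled[-idx[, j]]
    if (abs(stat(a, b)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(idx)
}

# Simulate one null/effect metabolite through the package's own
# preprocessing path and return the fitted univariate group model.
fit_single_metabolite <- function(n_per_group = 32, censor_q = 0.2,
                                  log_fc = 0, log_sd = 1) {
  g <- rep(0:1, each = n_per_group)
  conc <- exp(log_fc * g + stats::rnorm(2 * n_per_group, 0, log_sd))
  lod <- exp(stats::qnorm(censor_q) * log_sd)
  cv <- censmetab::substitute_lod_half(conc, lod)
  tr <- censmetab::fit_transform(cv)
  fit <- censmetab::tobit_fit(cbind("(Intercept)" = 1, group = g), tr$y,
                              cv$censored, bound = rep(tr$state$c, length(tr$y)))
  fit$scale_s <- tr$state$s  # autoscale SD, to map effects back to log units
  fit
}
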