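test_that("log-likelihood matches its closed-form and quadrature oracles", {
  X <- matrix(1, 1, 1)
  # one uncensored observation at its mean, sigma 1: standard normal at 0
  expect_equal(tobit_loglik(0, 1, X, 0, FALSE), -0.5 * log(2 * pi))
  # one censored observation with bound at the mean: log Phi(0) = log 0.5
  expect_equal(tobit_loglik(0, 1, X, 0, TRUE, bound = 0), log(0.5))
  expect_error(tobit_loglik(0, -1, X, 0, FALSE), "sigma")
  # random small instances against numerical integration
  set.seed(21)
  for (r in 1:5) {
    n <- 12
    X2 <- cbind(1, rnorm(n))
    beta <- rnorm(2); sigma <- runif(1, 0.5, 2)
    lat <- drop(X2 %*% beta) + sigma * rnorm(n)
    bound <- quantile(lat, 0.35)
    cen <- lat < bound
    y <- ifelse(cen, bound, lat)
    expect_equal(tobit_loglik(beta, sigma, X2, y, cen, bound),
                 loglik_quad(beta, sigma, X2, y, cen, rep(bound, n)),
                 tolerance = 1e-8)
  }
})

test_that("likelihood stays finite far from the data", {
  X <- cbind(1, c(-1, 0, 1, 2))
  y <- c(-8, 0.1, 0.4, 3)
  cen <- c(TRUE, FALSE, FALSE, FALSE)
  ll <- tobit_loglik(c(50, -30), 0.01, X, y, cen)
  expect_true(is.finite(ll))
})

test_that("zero censoring reproduces Gaussian maximum likelihood exactly", {
  set.seed(5)
  n <- 80
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = runif(n))
  y <- drop(X %*% c(1, -0.5, 2)) + rnorm(n)
  fit <- tobit_fit(X, y, rep(FALSE, n))
  lmfit <- lm(y ~ X - 1)
  expect_equal(unname(coef(fit)), unname(coef(lmfit)), tolerance = 1e-6)
  expect_equal(fit$sigma, sqrt(sum(resid(lmfit)^2) / n), tolerance = 1e-6)
  expect_true(fit$converged)
  # classical Gaussian-ML standard errors: vcov(beta) = sigma^2 (X'X)^-1
  se_ml <- sqrt(diag(fit$sigma^2 * solve(crossprod(X))))
  expect_equal(unname(sqrt(diag(vcov(fit, "beta")))), unname(se_ml),
               tolerance = 1e-4)
})

test_that("censored fits agree with an independent survival-regression fit", {
  skip_if_not_installed("survival")
  set.seed(13)
  n <- 150
  x <- rnorm(n)
  lat <- 0.4 + 0.8 * x + 0.9 * rnorm(n)
  bound <- -0.3
  cen <- lat < bound
  y <- ifelse(cen, bound, lat)
  fit <- tobit_fit(cbind("(Intercept)" = 1, x = x), y, cen)
  sr <- survival::survreg(survival::Surv(y, !cen, type = "left") ~ x,
                          dist = "gaussian")
  expect_equal(unname(coef(fit)), unname(coef(sr)), tolerance = 1e-5)
  expect_equal(fit$sigma, sr$scale, tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(vcov(fit, "beta")))),
               unname(sqrt(diag(vcov(sr))[1:2])), tolerance = 1e-3)
})

test_that("fitted optimum dominates a random parameter cloud around it", {
  set.seed(31)
  n <- 100
  x <- rnorm(n)
  lat <- 1 + 0.5 * x + rnorm(n)
  cen <- lat < -0.2
  y <- ifelse(cen, -0.2, lat)
  fit <- tobit_fit(cbind(1, x), y, cen)
  ll_hat <- fit$loglik
  for (r in 1:100) {
    beta <- fit$coefficients + rnorm(2, 0, 0.05)
    sigma <- fit$sigma * exp(rnorm(1, 0, 0.05))
    expect_lte(tobit_loglik(beta, sigma, fit$X, y, cen, fit$bound),
               ll_hat + 1e-10)
  }
})

test_that("parameter recovery at n = 2000 with 30% censoring", {
  set.seed(17)
  n <- 2000
  x <- rnorm(n)
  beta_true <- c(0.5, 0.7); sigma_true <- 1.2
  lat <- beta_true[1] + beta_true[2] * x + sigma_true * rnorm(n)
  bound <- qnorm(0.3, beta_true[1], sqrt(beta_true[2]^2 + sigma_true^2))
  cen <- lat < bound
  y <- ifelse(cen, bound, lat)
  fit <- tobit_fit(cbind(1, x), y, cen)
  se <- sqrt(diag(fit$vcov))
  # within 3 standard errors of truth
  expect_lt(abs(fit$coefficients[1] - beta_true[1]), 3 * se[1])
  expect_lt(abs(fit$coefficients[2] - beta_true[2]), 3 * se[2])
  expect_lt(abs(fit$sigma - sigma_true), 3 * se[3])
})

test_that("location-scale equivariance holds", {
  set.seed(23)
  n <- 120
  x <- rnorm(n)
  lat <- 0.3 + 0.6 * x + rnorm(n)
  cen <- lat < -0.5
  y <- ifelse(cen, -0.5, lat)
  X <- cbind(1, x)
  f0 <- tobit_fit(X, y, cen)
  # shift: y + k shifts the intercept by k only
  k <- 2.5
  f1 <- tobit_fit(X, y + k, cen, bound = f0$bound + k)
  expect_equal(f1$coefficients[1], f0$coefficients[1] + k, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(f1$coefficients[2], f0$coefficients[2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-6)
  # scale: a*y scales beta and sigma by a
  a <- 3
  f2 <- tobit_fit(X, a * y, cen, bound = a * f0$bound)
  expect_equal(unname(f2$coefficients), unname(a * f0$coefficients),
               tolerance = 1e-6)
  expect_equal(f2$sigma, a * f0$sigma, tolerance = 1e-6)
})

test_that("degenerate designs produce structured errors", {
  X <- cbind(1, c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  colnames(X) <- c("(Intercept)", "a", "b")
  y <- rnorm(5)
  expect_error(tobit_fit(X, y, rep(FALSE, 5)), "rank deficient.*b")
  expect_error(tobit_fit(cbind(1, rnorm(5)), rnorm(5), rep(TRUE, 5)),
               "all observations are censored")
  expect_error(tobit_fit(cbind(1, rnorm(3)), rnorm(3), rep(FALSE, 3)),
               "n > p \\+ 1")
})

test_that("Wald test has its defining properties", {
  set.seed(41)
  n <- 60
  x <- rnorm(n)
  y <- 1 + 0 * x + rnorm(n)
  fit <- tobit_fit(cbind(1, x), y, rep(FALSE, n))
  w <- wald_test(fit, 2)
  expect_equal(w$z, w$estimate / w$se)
  expect_true(w$p_value >= 0 && w$p_value <= 1)
  # a coefficient of exactly zero gives p = 1; doubling the SE halves |z|
  expect_equal(2 * pnorm(-abs(0 / w$se)), 1)
  expect_equal(abs(w$estimate / (2 * w$se)), abs(w$z) / 2)
})

test_that("formula interface and methods behave like a classical model fit", {
  set.seed(3)
  d <- data.frame(x = rnorm(120))
  lat <- 1 + 0.5 * d$x + rnorm(120)
  d$y <- pmax(lat, 0)
  fit <- tobit(y ~ x, d, left = 0)
  expect_s3_class(fit, "tobit")
  expect_equal(fit$n_censored, sum(lat <= 0))
  expect_named(coef(fit), c("(Intercept)", "x"))
  s <- summary(fit)
  expect_true(all(c("Estimate", "Std. Error") %in% colnames(s$coefficients)))
  expect_equal(unname(logLik(fit)[1]), fit$loglik, ignore_attr = TRUE)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  # predict on new data follows the linear predictor
  nd <- data.frame(x = c(-1, 0, 1))
  expect_equal(predict(fit, nd),
               unname(coef(fit)[1] + coef(fit)[2] * c(-1, 0, 1)),
               ignore_attr = TRUE)
  # residuals are defined for observed rows only
  r <- residuals(fit)
  expect_true(all(is.na(r[fit$censored])))
  expect_false(anyNA(r[!fit$censored]))
  # simulate reproduces the censoring mechanism
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(120L, 3L))
  expect_true(all(sim >= 0))
  out <- capture.output(print(fit))
  expect_match(out[1], "Tobit")
})
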