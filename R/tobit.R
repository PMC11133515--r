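#' Left-censored Gaussian (Tobit) log-likelihood
#'
#' For a latent response `y* = X beta + e`, `e ~ N(0, sigma^2)`, observed as
#' `y = y*` when uncensored and known only to satisfy `y* <= bound` for
#' censored rows, the log-likelihood is
#' `sum_unc [ log phi((y - X beta)/sigma) - log sigma ] +
#'  sum_cens log Phi((bound - X beta)/sigma)`.
#' Evaluated with log-scale normal tail functions so it stays finite for any
#' finite parameters.
#'
#' @param beta coefficient vector (length `ncol(X)`).
#' @param sigma residual scale, > 0.
#' @param X design matrix (n x p), leading intercept column by convention.
#' @param y response; censored rows hold their bound.
#' @param censored logical mask.
#' @param bound per-observation left bound for censored rows (scalar or
#'   vector); defaults to `y` itself on censored rows.
#' @return scalar log-likelihood.
#' @export
tobit_loglik <- function(beta, sigma, X, y, censored, bound = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(bound)) bound <- y
  bound <- rep_len(bound, length(y))
  eta <- drop(X %*% beta)
  ll <- 0
  if (any(!censored)) {
    z <- (y[!censored] - eta[!censored]) / sigma
    ll <- ll + sum(stats::dnorm(z, log = TRUE) - log(sigma))
  }
  if (any(censored)) {
    zb <- (bound[censored] - eta[censored]) / sigma
    ll <- ll + sum(stats::pnorm(zb, log.p = TRUE))
  }
  ll
}

# Gradient of the log-likelihood in theta = (beta, log sigma).
# Uncensored: d/dbeta = x z / sigma, d/dlogsigma = z^2 - 1.
# Censored:   d/dbeta = -x lambda / sigma, d/dlogsigma = -lambda z,
# with inverse Mills ratio lambda = phi(z)/Phi(z) computed on the log scale.
.tobit_grad <- function(theta, X, y, censored, bound) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1])
  eta <- drop(X %*% beta)
  g <- numeric(p + 1)
  if (any(!censored)) {
    z <- (y[!censored] - eta[!censored]) / sigma
    g[seq_len(p)] <- g[seq_len(p)] + drop(crossprod(X[!censored, , drop = FALSE], z)) / sigma
    g[p + 1] <- g[p + 1] + sum(z^2 - 1)
  }
  if (any(censored)) {
    zb <- (bound[censored] - eta[censored]) / sigma
    lam <- exp(stats::dnorm(zb, log = TRUE) - stats::pnorm(zb, log.p = TRUE))
    g[seq_len(p)] <- g[seq_len(p)] - drop(crossprod(X[censored, , drop = FALSE], lam)) / sigma
    g[p + 1] <- g[p + 1] - sum(lam * zb)
  }
  g
}

# Central finite-difference Hessian of the log-likelihood in
# theta = (beta, log sigma), built from the analytic gradient.
.tobit_hessian <- function(theta, X, y, censored, bound, h = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    step <- h * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + step
    tm <- theta; tm[j] <- tm[j] - step
    H[, j] <- (.tobit_grad(tp, X, y, censored, bound) -
               .tobit_grad(tm, X, y, censored, bound)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Fit a left-censored Gaussian regression by maximum likelihood
#'
#' Workhorse behind [tobit()]. Optimizes over `(beta, log sigma)` (so the
#' scale stays positive without constraints) by BFGS with the analytic
#' gradient, followed by safeguarded Newton steps on the finite-difference
#' Hessian for high-accuracy convergence. Initial values are the OLS fit of
#' `y` on `X` with `sigma0` the residual SD.
#'
#' @param X design matrix with leading intercept column; full column rank.
#' @param y response vector; censored rows must hold their bound.
#' @param censored logical mask (`TRUE` = left-censored at `bound`).
#' @param bound per-observation left bound (scalar or vector); defaults to
#'   the censored entries of `y`.
#' @param init optional initial `c(beta, sigma)`.
#' @param tol convergence tolerance: gradient norm below
#'   `tol * (1 + |loglik|)`, with a fallback on parameter change < 1e-10.
#' @param max_iter iteration cap across both phases.
#' @return an object of class `"tobit"`: list with `coefficients`, `sigma`,
#'   `loglik`, `vcov` (delta-method covariance of `(beta, sigma)`),
#'   `vcov_theta` (covariance of `(beta, log sigma)`), `converged`,
#'   `iterations`, `n_obs`, `n_censored`, and the fitting frame.
#' @export
tobit_fit <- function(X, y, censored, bound = NULL, init = NULL,
                      tol = 1e-8, max_iter = 200) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n || length(censored) != n) stop("length mismatch between y, X, censored")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p) - 1)
  if (all(censored)) stop("all observations are censored: model is unidentifiable")
  if (n <= p + 1) stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (is.null(bound)) bound <- y
  bound <- rep_len(bound, n)
  if (any(abs(y[censored] - bound[censored]) > 1e-8)) {
    stop("censored rows must carry their bound as response value")
  }

  if (is.null(init)) {
    ols <- qr.coef(qrX, y)
    res <- y - drop(X %*% ols)
    s0 <- sqrt(sum(res^2) / n)
    if (!is.finite(s0) || s0 <= 0) s0 <- 1
    init <- c(ols, s0)
  }
  theta <- c(init[seq_len(p)], log(init[p + 1]))

  negll <- function(th) {
    -tobit_loglik(th[seq_len(p)], exp(th[p + 1]), X, y, censored, bound)
  }
  neggr <- function(th) -.tobit_grad(th, X, y, censored, bound)

  opt <- stats::optim(theta, negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  theta <- opt$par
  iters <- opt$counts[["gradient"]]

  # Newton polish: step-halving keeps the likelihood non-decreasing.
  converged <- FALSE
  for (it in seq_len(25)) {
    g <- .tobit_grad(theta, X, y, censored, bound)
    ll <- -negll(theta)
    if (sqrt(sum(g^2)) < tol * (1 + abs(ll))) { converged <- TRUE; break }
    H <- .tobit_hessian(theta, X, y, censored, bound)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    moved <- FALSE
    for (half in 1:30) {
      cand <- theta + lam * step
      if (-negll(cand) >= ll - 1e-12) {
        if (max(abs(lam * step)) < 1e-10) {  # fallback: parameter change
          theta <- cand; converged <- TRUE; moved <- TRUE; break
        }
        theta <- cand; moved <- TRUE; break
      }
      lam <- lam / 2
    }
    iters <- iters + 1
    if (!moved || converged) break
  }
  if (!converged) {
    g <- .tobit_grad(theta, X, y, censored, bound)
    ll <- -negll(theta)
    converged <- sqrt(sum(g^2)) < tol * (1 + abs(ll))
  }

  beta <- theta[seq_len(p)]
  sigma <- unname(exp(theta[p + 1]))
  ll <- tobit_loglik(beta, sigma, X, y, censored, bound)

  H <- .tobit_hessian(theta, X, y, censored, bound)
  vcov_theta <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(vcov_theta) || any(!is.finite(vcov_theta))) {
    stop("singular observed information; consider a simpler model")
  }
  # delta method (beta, log sigma) -> (beta, sigma)
  J <- diag(c(rep(1, p), sigma))
  vcov <- J %*% vcov_theta %*% J
  dimnames(vcov) <- dimnames(vcov_theta) <-
    list(c(colnames(X), "sigma"), c(colnames(X), "sigma"))
  names(beta) <- colnames(X)

  structure(list(coefficients = beta, sigma = sigma, loglik = ll,
                 vcov = vcov, vcov_theta = vcov_theta,
                 converged = converged, iterations = iters,
                 n_obs = n, n_censored = sum(censored),
                 X = X, y = y, censored = censored, bound = bound),
            class = "tobit")
}

#' Tobit regression with a formula interface
#'
#' Fits a left-censored Gaussian linear model. Censoring is declared either
#' through `censored` (a logical vector or the name of a logical column of
#' `data`) with per-row bounds taken from the response, or through a `left`
#' bound: rows with response `<= left` are treated as censored at `left`.
#'
#' @param formula model formula, e.g. `y ~ group + sex + dbp + crp`.
#' @param data data frame holding the variables.
#' @param left scalar (or per-row) left-censoring bound; ignored when
#'   `censored` is given.
#' @param censored logical vector, or name of a logical column of `data`.
#' @param ... passed to [tobit_fit()] (`init`, `tol`, `max_iter`).
#' @return a `"tobit"` object; see [tobit_fit()].
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(100))
#' y <- 1 + 0.5 * d$x + rnorm(100)
#' d$y <- pmax(y, 0)  # left-censored at 0
#' fit <- tobit(y ~ x, d, left = 0)
#' summary(fit)
#' @export
tobit <- function(formula, data, left = -Inf, censored = NULL, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (is.character(censored) && length(censored) == 1) {
    censored <- data[[censored]][as.integer(rownames(mf))]
  }
  bound <- NULL
  if (is.null(censored)) {
    left <- rep_len(left, length(y))
    censored <- y <= left
    y[censored] <- left[censored]
    bound <- left
  }
  fit <- tobit_fit(X, y, censored, bound = bound, ...)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' Wald test for one coefficient of a Tobit fit
#'
#' @param fit a converged `"tobit"` object.
#' @param coef index or name of the coefficient.
#' @return list with `estimate`, `se`, `z`, `p_value` (two-sided, standard
#'   normal reference).
#' @export
wald_test <- function(fit, coef = 2) {
  stopifnot(inherits(fit, "tobit"))
  if (!fit$converged) stop("fit did not converge; Wald test unavailable")
  est <- fit$coefficients[coef]
  se <- sqrt(diag(fit$vcov))[coef]
  z <- est / se
  list(estimate = unname(est), se = unname(se), z = unname(z),
       p_value = unname(2 * stats::pnorm(-abs(z))))
}

#' Covariance matrix of a Tobit fit
#' @param object a `"tobit"` object.
#' @param parm `"all"` for `(beta, sigma)`, `"beta"` for coefficients only.
#' @param ... unused.
#' @export
vcov.tobit <- function(object, parm = c("all", "beta"), ...) {
  parm <- match.arg(parm)
  if (parm == "beta") {
    p <- length(object$coefficients)
    object$vcov[seq_len(p), seq_len(p), drop = FALSE]
  } else object$vcov
}

#' @export
coef.tobit <- function(object, ...) object$coefficients

#' @export
logLik.tobit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.tobit <- function(x, ...) {
  cat("Left-censored Gaussian (Tobit) regression\n")
  cat(sprintf("n = %d (%d censored), logLik = %.4f%s\n", x$n_obs,
              x$n_censored, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("Coefficients:\n")
  print(round(x$coefficients, 5))
  cat("sigma:", format(round(x$sigma, 5)), "\n")
  invisible(x)
}

#' @export
summary.tobit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  p <- length(object$coefficients)
  est <- c(object$coefficients, sigma = object$sigma)
  z <- est / se
  pv <- 2 * stats::pnorm(-abs(z))
  pv[p + 1] <- NA  # a scale has no null at zero
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = pv)
  structure(list(coefficients = tab, loglik = object$loglik,
                 n_obs = object$n_obs, n_censored = object$n_censored,
                 converged = object$converged, call = object$call),
            class = "summary.tobit")
}

#' @export
print.summary.tobit <- function(x, ...) {
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("Left-censored observations: %d of %d\n", x$n_censored, x$n_obs))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE,
                      na.print = "")
  cat(sprintf("Log-likelihood: %.4f  (converged: %s)\n", x$loglik,
              x$converged))
  invisible(x)
}

#' @export
predict.tobit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) {
    object$X
  } else if (is.matrix(newdata)) {
    newdata
  } else if (!is.null(object$terms)) {
    stats::model.matrix(stats::delete.response(object$terms), newdata)
  } else stop("newdata requires a matrix for fits without a formula")
  drop(X %*% object$coefficients)
}

#' @export
residuals.tobit <- function(object, ...) {
  r <- object$y - predict(object)
  r[object$censored] <- NA  # only a bound is observed there
  r
}

#' @export
confint.tobit <- function(object, parm = NULL, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  est <- c(object$coefficients, sigma = object$sigma)
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - q * se, est + q * se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Simulate responses from a fitted Tobit model
#'
#' Draws latent responses `X beta + sigma e` and left-censors them at each
#' observation's bound (uncensored rows keep their latent draw; rows whose
#' draw falls below the bound are set to the bound and flagged).
#'
#' @param object a `"tobit"` object.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param ... unused.
#' @return data frame of `nsim` columns; attribute `"censored"` holds the
#'   matching censoring masks.
#' @export
simulate.tobit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta <- predict(object)
  n <- object$n_obs
  out <- matrix(NA_real_, n, nsim)
  cens <- matrix(NA, n, nsim)
  for (j in seq_len(nsim)) {
    lat <- eta + object$sigma * stats::rnorm(n)
    cj <- lat < object$bound
    lat[cj] <- object$bound[cj]
    out[, j] <- lat
    cens[, j] <- cj
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "censored") <- cens
  out
}
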