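fx <- make_fixture_small()

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (r in 1:1000) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("fold-change is the ratio of model geometric means", {
  res <- run_multivariable(fx$concentrations, fx$samples, fx$lods, fx$panel)
  expect_equal(res$fc * res$gm_control, res$gm_case, tolerance = 1e-10)
  expect_true(all(res$gm_case_lo <= res$gm_case & res$gm_case <= res$gm_case_hi))
  expect_true(all(res$gm_control_lo <= res$gm_control &
                  res$gm_control <= res$gm_control_hi))
  expect_true(all(res$fdr_p >= res$p_value))
  # deterministic ordering by FDR p then id
  expect_equal(order(res$fdr_p, res$metabolite), seq_len(nrow(res)))
})

test_that("a zero group coefficient gives fold-change exactly 1", {
  state <- list(m = 0.5, s = 1.3)
  V <- diag(c(0.01, 0.04, 0.001))
  dimnames(V) <- rep(list(c("(Intercept)", "group", "sigma")), 2)
  fake <- structure(list(coefficients = c("(Intercept)" = 0.2, group = 0),
                         vcov = V, converged = TRUE), class = "tobit")
  fc <- fold_change(fake, state)
  expect_identical(fc$fc, 1)
  expect_lt(fc$lo, 1)
  expect_gt(fc$hi, 1)
})

test_that("geometric means back-transform the linear predictor", {
  # eta = 0 must give exp(m), the sample geometric centre
  prep <- substitute_lod_half(fx$concentrations[, "SM C16:0"],
                              fx$lods[["SM C16:0"]])
  tr <- fit_transform(prep)
  fit <- fit_metabolite(tr$y, prep$censored, tr$state$c, fx$samples,
                        model_spec(covariates = character(0)),
                        id = "SM C16:0")
  gm <- group_geometric_means(fit, tr$state, model_spec(character(0)))
  eta_ctl <- fit$coefficients[["(Intercept)"]]
  expect_equal(gm["control", "gm"],
               exp(tr$state$m + tr$state$s * eta_ctl))
  expect_equal(gm["case", "gm"] / gm["control", "gm"],
               exp(tr$state$s * fit$coefficients[["group"]]),
               tolerance = 1e-12)
  # degenerate SE: CI collapses onto the point estimate
  fit0 <- fit
  fit0$vcov[] <- 0
  gm0 <- group_geometric_means(fit0, tr$state, model_spec(character(0)))
  expect_equal(gm0$lo, gm0$gm)
  expect_equal(gm0$hi, gm0$gm)
})

test_that("an empty covariate list reduces to the univariate group model", {
  res_uni <- run_multivariable(fx$concentrations, fx$samples, fx$lods,
                               fx$panel, spec = model_spec(character(0)))
  screen <- run_univariate(fx$concentrations, fx$samples, fx$lods, fx$panel)
  merged <- merge(as.data.frame(res_uni)[, c("metabolite", "p_value")],
                  screen[, c("metabolite", "p_value")], by = "metabolite")
  expect_equal(merged$p_value.x, merged$p_value.y, tolerance = 1e-8)
})

test_that("aggregates are never censored and fit as uncensored Gaussian ML", {
  mat <- compute_aggregates(fx$concentrations, fx$panel, fx$lods)
  agg <- mat[, "lysoPC_s"]
  logs <- log(agg)
  y <- (logs - mean(logs)) / sd(logs)
  X <- cbind("(Intercept)" = 1,
             group = as.numeric(fx$samples$group == "case"))
  fit <- tobit_fit(X, y, rep(FALSE, length(y)))
  lmfit <- lm(y ~ X - 1)
  expect_equal(unname(coef(fit)), unname(coef(lmfit)), tolerance = 1e-6)
  res <- run_multivariable(fx$concentrations, fx$samples, fx$lods, fx$panel)
  expect_equal(res$n_below_lb[res$metabolite == "lysoPC_s"], 0L,
               ignore_attr = TRUE)
})

test_that("null group effects stay within 3 SE almost always", {
  set.seed(77)
  inside <- 0
  reps <- 300
  for (r in 1:reps) {
    fit <- fit_single_metabolite(n_per_group = 32, censor_q = 0.2,
                                 log_fc = 0)
    w <- wald_test(fit, "group")
    if (abs(w$estimate) < 3 * w$se) inside <- inside + 1
  }
  expect_gte(inside / reps, 0.98)
})

test_that("covariate screen flags about alpha on pure noise and handles edge cases", {
  set.seed(55)
  cfg <- sim_config(n_case = 20, n_control = 20,
                    panel = fx$panel, censor_quantile = 0, seed = 101)
  sim <- simulate_cohort(cfg)
  sim$samples$noise <- rnorm(nrow(sim$samples))
  sim$samples$const <- 1
  sc <- covariate_screen(sim$concentrations, sim$samples, sim$lods,
                         fx$panel, candidates = "noise")
  expect_equal(sc$n_tested, 8)
  # 8 null tests: 0-2 flags stays comfortably within the binomial envelope
  expect_lte(sc$n_sig, 3)
  expect_warning(
    covariate_screen(sim$concentrations, sim$samples, sim$lods, fx$panel,
                     candidates = "const"),
    "constant")
  empty <- covariate_screen(sim$concentrations, sim$samples, sim$lods,
                            fx$panel, candidates = character(0))
  expect_equal(nrow(empty), 0)
  # a binary covariate identical to group reproduces the group screen
  sim$samples$grp2 <- ifelse(sim$samples$group == "case", "yes", "no")
  sc2 <- covariate_screen(sim$concentrations, sim$samples, sim$lods,
                          fx$panel, candidates = "grp2")
  uni <- run_univariate(sim$concentrations, sim$samples, sim$lods, fx$panel)
  expect_equal(sc2$n_sig, sum(uni$p_value < 0.05))
})

test_that("volcano coordinates are the log-log map of results", {
  res <- run_multivariable(fx$concentrations, fx$samples, fx$lods, fx$panel)
  vt <- volcano_table(res)
  expect_equal(vt$log2_fc, log2(res$fc))
  expect_equal(vt$neg_log10_fdr_p, -log10(res$fdr_p))
  expect_true(all(is.finite(vt$log2_fc)))
  # fc = 1 with fdr_p = 1 maps to the origin
  fake <- data.frame(metabolite = "m", fc = 1, fdr_p = 1)
  expect_equal(unlist(volcano_table(fake)[, 2:3]), c(0, 0),
               ignore_attr = TRUE)
})

test_that("the pipeline is deterministic for identical inputs", {
  r1 <- run_multivariable(fx$concentrations, fx$samples, fx$lods, fx$panel)
  r2 <- run_multivariable(fx$concentrations, fx$samples, fx$lods, fx$panel)
  expect_identical(r1, r2)
})

test_that("FDR family can exclude aggregates by configuration", {
  res <- run_multivariable(fx$concentrations, fx$samples, fx$lods, fx$panel,
                           fdr_family = "measured_only")
  expect_true(is.na(res$fdr_p[res$metabolite == "lysoPC_s"]))
  meas <- !res$metabolite %in% "lysoPC_s"
  expect_equal(sort(res$fdr_p[meas]), sort(bh_brute(res$p_value[meas])))
})
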