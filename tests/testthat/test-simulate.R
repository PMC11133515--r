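test_that("identical seed and config give identical datasets", {
  cfg <- sim_config(n_case = 10, n_control = 10, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$concentrations, b$concentrations)
  expect_identical(a$samples, b$samples)
  expect_identical(a$lods, b$lods)
  c2 <- simulate_cohort(sim_config(n_case = 10, n_control = 10, seed = 8))
  expect_false(identical(a$concentrations, c2$concentrations))
})

test_that("cohort structure matches the configured design", {
  sim <- simulate_cohort(sim_config(seed = 3))
  expect_equal(dim(sim$concentrations), c(64L, 188L))
  expect_equal(table(sim$samples$group)[["case"]], 32L)
  # 23 F : 9 M in each group
  expect_equal(unname(table(sim$samples$sex, sim$samples$group)["F", ]),
               c(23L, 23L))
  expect_true(all(sim$concentrations > 0))
  expect_true(all(sim$lods > 0))
  expect_true(validate_panel_data(sim$concentrations, default_panel(),
                                  sim$lods))
})

test_that("realized censoring fraction matches the configured quantile", {
  panel <- make_panel("m1", "acylcarnitine")
  cfg <- sim_config(n_case = 5000, n_control = 5000, panel = panel,
                    log_mean = 0, log_sd = 0.6, censor_quantile = 0.35,
                    seed = 19)
  sim <- simulate_cohort(cfg)
  frac <- mean(sim$concentrations[, 1] < sim$lods[[1]])
  expect_lt(abs(frac - 0.35), 4 * sqrt(0.35 * 0.65 / 10000))
  # censor_quantile = 0: effectively nothing below the (positive) LOD
  cfg0 <- sim_config(n_case = 500, n_control = 500, panel = panel,
                     censor_quantile = 0, seed = 19)
  sim0 <- simulate_cohort(cfg0)
  expect_equal(sum(sim0$concentrations[, 1] < sim0$lods[[1]]), 0L,
               ignore_attr = TRUE)
})

test_that("noise-free two-fold effect flows through the pipeline as FC = 2", {
  panel <- make_panel(c("m1", "m2"), "PC_aa")
  cfg <- sim_config(n_case = 8, n_control = 8, panel = panel,
                    log_mean = log(10), log_sd = c(0, 0.3),
                    group_log_fc = c(log(2), 0), censor_quantile = 0,
                    seed = 2)
  sim <- simulate_cohort(cfg)
  # noise-free metabolite: every case value exactly 2x every control value
  expect_equal(unique(sim$concentrations[sim$samples$group == "case", "m1"]) /
                 unique(sim$concentrations[sim$samples$group == "control", "m1"]),
               2)
  expect_equal(sim$truth$fc, c(2, 1))
})

test_that("blank_below_lod stores censored raw values as missing", {
  panel <- make_panel("m1", "acylcarnitine")
  base <- sim_config(n_case = 50, n_control = 50, panel = panel,
                     censor_quantile = 0.4, seed = 5)
  blank <- base; blank$blank_below_lod <- TRUE
  s1 <- simulate_cohort(base)
  s2 <- simulate_cohort(blank)
  below <- s1$concentrations[, 1] < s1$lods[[1]]
  expect_true(any(below))
  expect_true(all(is.na(s2$concentrations[below, 1])))
  expect_equal(s1$concentrations[!below, 1], s2$concentrations[!below, 1])
})

test_that("standardized group effects are recovered without bias", {
  # moderate scale: n = 200+200, 30% censoring, truth on the latent scale
  set.seed(14)
  reps <- 60
  err <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- rep(0:1, each = 200)
    log_fc <- 0.5; log_sd <- 1
    conc <- exp(log_fc * g + rnorm(400, 0, log_sd))
    lod <- exp(qnorm(0.3) * log_sd)
    cv <- substitute_lod_half(conc, lod)
    tr <- fit_transform(cv)
    fit <- tobit_fit(cbind(1, group = g), tr$y, cv$censored,
                     bound = rep(tr$state$c, 400))
    # estimated effect mapped back to the log-concentration scale
    err[r] <- tr$state$s * fit$coefficients[["group"]] - log_fc
  }
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(reps) + 0.03)
})

test_that("the small fixture has its documented shape", {
  fx <- make_fixture_small()
  expect_equal(dim(fx$concentrations), c(12L, 8L))
  expect_true(validate_panel_data(fx$concentrations, fx$panel, fx$lods))
  cen_c10 <- sum(fx$concentrations[, "C10"] < fx$lods[["C10"]])
  cen_c141 <- sum(fx$concentrations[, "C14:1"] < fx$lods[["C14:1"]])
  expect_gte(cen_c10, 2); expect_lte(cen_c10, 6)      # ~30% censored
  expect_gte(cen_c141, 8)                             # ~80% censored
  filt <- detection_filter(fx$concentrations, fx$lods)
  # the detection rule decides membership exactly
  rate_c141 <- mean(fx$concentrations[, "C14:1"] >= fx$lods[["C14:1"]])
  expect_identical("C14:1" %in% filt$kept, rate_c141 >= 0.20)
  expect_true(all(fx$concentrations[, "H1"] >= fx$lods[["H1"]]))
  # identical on re-generation
  expect_identical(fx$concentrations, make_fixture_small()$concentrations)
})

test_that("config validation rejects inconsistent inputs", {
  panel <- make_panel(c("a", "b"), "hexose")
  expect_error(sim_config(panel = panel, log_mean = c(1, 2, 3)),
               "length 1 or 2")
  expect_error(sim_config(panel = panel, censor_quantile = 0.99),
               "\\[0, 0.95\\]")
  expect_error(sim_config(panel = panel, log_sd = -1), ">= 0")
})
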