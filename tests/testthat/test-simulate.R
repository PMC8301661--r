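test_that("truth layer satisfies Gamma = gamma * beta + alpha exactly", {
  sim <- simulate_study(simulation_config(
    p_total = 100L, K = 2L, beta = c(0.4, -0.1), tau2 = 1e-4,
    correlated_a = 0.3, seed = 8L))
  expected <- as.numeric(sim$truth$gamma %*% c(0.4, -0.1)) + sim$truth$alpha
  expect_equal(sim$truth$Gamma, expected, tolerance = 1e-12)
})

test_that("pathway SNPs concentrate at ratio beta + kappa/delta in truth", {
  sim <- simulate_study(simulation_config(
    p_total = 200L, beta = 0.2,
    pathways = list(list(kappa = 0.3, delta = 0.6, fraction = 0.4)),
    seed = 13L))
  on_pw <- sim$truth$pathway == 1L
  expect_equal(sum(on_pw), 80L)
  ratios <- sim$truth$Gamma[on_pw] / sim$truth$gamma[on_pw, 1]
  expect_equal(ratios, rep(0.2 + 0.3 / 0.6, sum(on_pw)), tolerance = 1e-10)
})

test_that("two-pathway fixture has three distinct truth-layer ratio clusters", {
  sim <- make_fixture("two-pathway")
  ratios <- sim$truth$Gamma / sim$truth$gamma[, 1]
  centers <- sort(as.numeric(tapply(ratios, sim$truth$pathway, median)))
  expect_equal(centers, c(-0.4, 0.2, 0.7), tolerance = 1e-10)
})

test_that("reverse-direction fixture splits SNPs into two ratio groups", {
  sim <- make_fixture("reverse-direction")
  ratios <- sim$truth$Gamma / sim$truth$gamma[, 1]
  direct <- sim$truth$pathway == 0L   # act on the reverse exposure only
  expect_equal(unique(ratios[direct]), 0)
  expect_equal(unique(round(ratios[!direct], 10)), 2)
})

test_that("estimation noise matches the nominal standard errors", {
  # pooled standardized errors over replicates are standard normal
  z <- unlist(lapply(1:20, function(i) {
    sim <- simulate_study(simulation_config(p_total = 200L, seed = 300L + i))
    (sim$study$gamma_hat[, 1] - sim$truth$gamma[, 1]) / sim$study$se_gamma[, 1]
  }))
  n <- length(z)
  expect_lt(abs(mean(z)), 3 / sqrt(n))
  expect_lt(abs(sd(z) - 1), 3 * sqrt(1 / (2 * n)) + 0.01)
})

test_that("overlap induces the predicted error correlation", {
  sim <- make_fixture("overlapping-cohorts")
  null_rows <- sim$truth$gamma[, 1] == 0 & sim$truth$Gamma == 0
  zg <- sim$study$gamma_hat[null_rows, 1] / sim$study$se_gamma[null_rows, 1]
  zG <- sim$study$Gamma_hat[null_rows] / sim$study$se_Gamma[null_rows]
  expect_equal(cor(zg, zG), 0.5, tolerance = 3 / sqrt(sum(null_rows)))
})

test_that("independent selection leaves estimation errors unbiased, own-cohort selection does not", {
  # weak effects make selection genuinely informative
  bias <- vapply(c(independent = TRUE, own = FALSE), function(indep) {
    errs <- unlist(lapply(1:30, function(i) {
      sim <- simulate_study(simulation_config(
        p_total = 400L, beta = 0.5, gamma_scale = 0.012,
        seed = 700L + i))
      p_sel <- if (indep) sim$study$sel_pvalues[, 1] else
        2 * pnorm(-abs(sim$study$gamma_hat[, 1] / sim$study$se_gamma[, 1]))
      keep <- p_sel <= 1e-2
      # signed error, oriented by the statistic that did the selecting:
      # winner's curse inflates the estimate in its own selected direction
      orient <- if (indep) sign(sim$truth$gamma_sel[keep, 1]) else
        sign(sim$study$gamma_hat[keep, 1])
      ((sim$study$gamma_hat[keep, 1] - sim$truth$gamma[keep, 1]) *
         orient) / sim$study$se_gamma[keep, 1]
    }))
    mean(errs)
  }, numeric(1))
  expect_lt(abs(bias["independent"]), 0.05)  # three-sample design: no winner's curse
  expect_gt(bias["own"], 0.15)               # own-cohort selection inflates
})

test_that("a fixed seed reproduces the study exactly, other seeds differ", {
  cfg <- simulation_config(p_total = 50L, seed = 12345L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$study, s2$study)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(simulation_config(p_total = 50L, seed = 54321L))
  expect_false(identical(s1$study$Gamma_hat, s3$study$Gamma_hat))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_study(simulation_config(seed = 77L)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(
    pathways = list(list(kappa = 0.3, delta = 0, fraction = 0.2))),
    "delta")
  expect_error(simulation_config(
    pathways = list(list(kappa = 1, delta = 1, fraction = 0.7),
                    list(kappa = 1, delta = 1, fraction = 0.6))),
    "fractions")
  expect_error(simulation_config(N_overlap = 2e5), "N_overlap")
  expect_error(simulation_config(tau2 = -1), "tau2")
  expect_error(make_fixture("not-a-scenario"), "unknown")
})

test_that("binary outcomes are attenuated by the stated ratio", {
  cfg_c <- simulation_config(p_total = 80L, seed = 44L)
  cfg_b <- simulation_config(p_total = 80L, seed = 44L,
                             outcome_binary = TRUE, attenuation = 1.5)
  s_c <- simulate_study(cfg_c)
  s_b <- simulate_study(cfg_b)
  expect_equal(s_b$study$Gamma_hat, s_c$study$Gamma_hat / 1.5,
               tolerance = 1e-12)
  expect_true(s_b$study$outcome_is_binary)
})
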