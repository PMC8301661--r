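test_that("profile residual reduces to known closed forms", {
  study <- residual_design_study(Gamma_hat = 0.12, gamma_hat = 0.2)
  study$se_Gamma <- 0.05
  study$se_gamma <- matrix(0.02, 1, 1)
  # beta = 0, tau2 = 0: residual is Gamma_hat / se_Gamma
  expect_equal(unname(profile_t(study, beta = 0)), 0.12 / 0.05)
  # hand arithmetic: (0.12 - 0.5*0.2) / sqrt(0.05^2 + 0.25*0.02^2)
  expect_equal(unname(profile_t(study, beta = 0.5)),
               0.02 / sqrt(0.0026), tolerance = 1e-12)
  # tau2 enters the denominator additively
  expect_equal(unname(profile_t(study, beta = 0.5, tau2 = 0.01)),
               0.02 / sqrt(0.0026 + 0.01), tolerance = 1e-12)
})

test_that("residual denominator matches a Monte-Carlo variance oracle", {
  # K = 1 with shared correlation theta: draw (Gamma_hat, gamma_hat) from
  # the assumed error law and compare Var(Gamma_hat - b*gamma_hat) with
  # the squared denominator of t_j
  set.seed(88)
  theta <- 0.6; sY <- 0.04; sX <- 0.03; b <- 0.7; tau2 <- 4e-4
  n <- 2e5
  zy <- rnorm(n); zx <- theta * zy + sqrt(1 - theta^2) * rnorm(n)
  alpha <- rnorm(n, 0, sqrt(tau2))
  Gh <- 0.5 + alpha + zy * sY   # true Gamma = 0.5 plus pleiotropy
  gh <- 0.5 / b + zx * sX       # true gamma chosen so numerator mean is 0
  emp_var <- var(Gh - b * gh)
  ana_var <- sY^2 + b^2 * sX^2 - 2 * b * theta * sX * sY + tau2
  mc_err <- 3 * emp_var * sqrt(2 / n)
  expect_equal(emp_var, ana_var, tolerance = mc_err / ana_var)

  study <- residual_design_study(Gamma_hat = Gh[1], gamma_hat = gh[1])
  study$se_Gamma <- sY; study$se_gamma <- matrix(sX, 1, 1)
  sg <- mr_sigma(matrix(c(1, theta, theta, 1), 2))
  tv <- profile_t(study, beta = b, tau2 = tau2, sigma = sg)
  expect_equal(unname(tv), (Gh[1] - b * gh[1]) / sqrt(ana_var),
               tolerance = 1e-12)
})

test_that("an invalid Sigma produces a hard error naming the SNP", {
  study <- residual_design_study(Gamma_hat = 0.1, gamma_hat = 0.2)
  study$se_Gamma <- 0.01
  study$se_gamma <- matrix(0.01, 1, 1)
  sg <- mr_sigma(matrix(c(1, 1, 1, 1), 2))
  # perfectly correlated errors with matched scales collapse the variance
  # term to zero at beta = 1
  expect_error(profile_t(study, beta = 1, tau2 = 0, sigma = sg),
               "s01")
})

test_that("noiseless data give back beta exactly with zero overdispersion", {
  set.seed(4)
  p <- 50L
  gamma <- rnorm(p, 0, 0.1)
  beta0 <- 0.37
  study <- mr_study(
    snp = sprintf("n%02d", 1:p),
    effect_allele = rep("A", p), other_allele = rep("G", p),
    gamma_hat = matrix(gamma, ncol = 1), se_gamma = matrix(1e-6, p, 1),
    Gamma_hat = gamma * beta0, se_Gamma = rep(1e-6, p),
    sel_pvalues = matrix(1e-10, p, 1)
  )
  fit <- fit_effects(study, study$snp)
  expect_equal(unname(fit$beta_hat), beta0, tolerance = 1e-6)
  expect_equal(fit$tau2_hat, 0)
  expect_true(fit$converged)
  expect_true(fit$ci[1, 1] <= fit$beta_hat[1] &&
                fit$beta_hat[1] <= fit$ci[1, 2])
})

test_that("estimates are scale-equivariant in the exposure units", {
  sim <- make_fixture("inside-pleiotropy")
  instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
  f1 <- fit_effects(sim$study, instr)
  a <- 3.7
  scaled <- sim$study
  scaled$gamma_hat <- scaled$gamma_hat * a
  scaled$se_gamma <- scaled$se_gamma * a
  f2 <- fit_effects(scaled, instr)
  expect_equal(unname(f2$beta_hat), unname(f1$beta_hat) / a,
               tolerance = 1e-6)
})

test_that("one wild outcome value has bounded influence on the fit", {
  sim <- make_fixture("no-pleiotropy")
  instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
  f0 <- fit_effects(sim$study, instr)
  poisoned <- sim$study
  idx <- match(instr$ids[1], poisoned$snp)
  poisoned$Gamma_hat[idx] <- 1e8
  f1 <- fit_effects(poisoned, instr)
  expect_lt(abs(f1$beta_hat - f0$beta_hat), 0.05)
})

test_that("mean estimate recovers the truth over simulation replicates", {
  est <- vapply(1:60, function(i) {
    sim <- simulate_study(simulation_config(
      p_total = 300L, beta = 0.5, tau2 = 0, seed = 4000L + i))
    instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
    unname(fit_effects(sim$study, instr)$beta_hat)
  }, numeric(1))
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * mcse)
})

test_that("beta agrees with a fine-grid maximizer at the fitted tau2", {
  sim <- make_fixture("inside-pleiotropy")
  instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
  fit <- fit_effects(sim$study, instr)
  sub <- subset_study(sim$study, instr$ids)
  pt <- mrprofile:::profile_t_parts(sub, NULL)
  step <- 1e-3
  grid <- seq(fit$beta_hat - 1, fit$beta_hat + 1, by = step)
  lvals <- vapply(grid, function(b)
    mrprofile:::profile_loglik(pt, b, fit$tau2_hat, 4.6851), numeric(1))
  expect_lt(abs(grid[which.max(lvals)] - fit$beta_hat), step + 1e-9)
})

test_that("overdispersion variance is recovered with small relative bias", {
  tau2_0 <- 1e-4
  est <- vapply(1:25, function(i) {
    sim <- simulate_study(simulation_config(
      p_total = 1000L, beta = 0.5, tau2 = tau2_0, seed = 6000L + i))
    instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
    fit_effects(sim$study, instr)$tau2_hat
  }, numeric(1))
  expect_lt(abs(mean(est) - tau2_0) / tau2_0, 0.2)
})

test_that("too few instruments is a hard error", {
  sim <- simulate_study(simulation_config(p_total = 30L, seed = 9L))
  expect_error(fit_effects(sim$study, sim$study$snp[1]), "instruments")
})

test_that("multivariable fits recover both effects jointly", {
  est <- t(vapply(1:10, function(i) {
    sim <- simulate_study(simulation_config(
      p_total = 500L, K = 2L, beta = c(0.3, -0.2), tau2 = 1e-5,
      seed = 500L + i))
    instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
    unname(fit_effects(sim$study, instr)$beta_hat)
  }, numeric(2)))
  mcse <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 0.3), 4 * mcse[1])
  expect_lt(abs(mean(est[, 2]) + 0.2), 4 * mcse[2])
})
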