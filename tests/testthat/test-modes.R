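test_that("single-pathway data give one mode near the causal effect", {
  sim <- simulate_study(simulation_config(
    p_total = 200L, beta = 0.3, tau2 = 0, seed = 55L))
  instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
  prof <- profile_curve(sim$study, instr)
  expect_equal(nrow(prof$modes), 1L)
  expect_lt(abs(prof$modes$position - 0.3), 0.05)
  expect_false(prof$modes$likely_outlier)
})

test_that("a confounding pathway raises a second mode at beta + kappa/delta", {
  sim <- make_fixture("one-pathway")  # beta 0.2, kappa 0.3, delta 0.6
  instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
  prof <- profile_curve(sim$study, instr)
  expect_equal(nrow(prof$modes), 2L)
  expect_lt(abs(prof$modes$position[1] - 0.2), 0.05)
  expect_lt(abs(prof$modes$position[2] - (0.2 + 0.3 / 0.6)), 0.05)
})

test_that("the profile curve is translation-equivariant in b", {
  # exact when the exposure SEs are negligible (the residual denominator
  # is then b-free); with noisy exposures the equivariance holds for the
  # numerator, so mode positions shift by b0 up to the grid bandwidth
  set.seed(66)
  study <- residual_design_study(Gamma_hat = rnorm(40, 0.5, 0.8),
                                 gamma_hat = rnorm(40, 1, 0.1))
  b0 <- 0.4
  grid <- seq(-2, 3, length.out = 501)
  p1 <- profile_curve(study, study$snp, grid = grid)
  shifted <- study
  shifted$Gamma_hat <- shifted$Gamma_hat + b0 * shifted$gamma_hat[, 1]
  p2 <- profile_curve(shifted, study$snp, grid = grid + b0)
  expect_equal(p2$values, p1$values, tolerance = 1e-6)

  sim <- simulate_study(simulation_config(p_total = 100L, seed = 66L))
  instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
  m1 <- profile_curve(sim$study, instr)
  noisy_shift <- sim$study
  noisy_shift$Gamma_hat <- noisy_shift$Gamma_hat +
    b0 * noisy_shift$gamma_hat[, 1]
  m2 <- profile_curve(noisy_shift, instr)
  expect_equal(m2$modes$position, m1$modes$position + b0,
               tolerance = 0.02)
})

test_that("mode detection handles concave curves and merges ripple", {
  g <- seq(-1, 1, length.out = 201)
  concave <- structure(list(grid = g, values = -g^2, c = 3,
                            ids = character(0)), class = "mr_profile")
  m <- find_modes(concave)
  expect_equal(nrow(m), 1L)
  expect_equal(m$position, 0)
  # two maxima one grid step apart collapse to the higher one
  v <- -g^2
  peak <- which.min(abs(g))
  v[peak + 1L] <- v[peak] + 1e-9
  ripple <- structure(list(grid = g, values = v, c = 3,
                           ids = character(0)), class = "mr_profile")
  expect_equal(nrow(find_modes(ripple)), 1L)
})

test_that("a mode supported by a single SNP is flagged likely-outlier", {
  # 40 strong SNPs tightly consistent with b = 0, one lone SNP at ratio 2
  set.seed(10)
  gamma <- c(runif(40, 5, 10) * sample(c(-1, 1), 40, replace = TRUE), 5)
  Gamma <- c(rnorm(40, 0, 0.3), 10)
  study <- residual_design_study(Gamma_hat = Gamma, gamma_hat = gamma)
  prof <- profile_curve(study, study$snp, grid = seq(-1, 3, length.out = 801))
  lone <- prof$modes[abs(prof$modes$position - 2) < 0.2, ]
  expect_equal(nrow(lone), 1L)
  expect_equal(lone$support, 1L)
  expect_true(lone$likely_outlier)
})

test_that("mode positions are invariant to SNP order", {
  sim <- make_fixture("one-pathway")
  instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
  p1 <- profile_curve(sim$study, instr)
  p2 <- profile_curve(sim$study, rev(instr$ids))
  expect_equal(p2$modes$position, p1$modes$position)
})

test_that("marker rule reproduces hand-enumerated assignments", {
  # residuals against modes (0, 1) with unit outcome SE are
  # r_jm = Gamma_j - m * gamma_j by construction
  study <- residual_design_study(
    Gamma_hat = c(0.5, 0.5, -0.2, 3.2),
    gamma_hat = c(-2.5, -1.0, -2.8, 0.4))
  mk <- select_markers(study, study$snp, modes = c(0, 1))
  # SNP1: r = (0.5, 3.0) -> marker for mode 1 only
  # SNP2: r = (0.5, 1.5) -> |1.5| <= t1: marker for no mode
  # SNP3: r = (-0.2, 2.6) -> marker for mode 1
  # SNP4: r = (3.2, 2.8) -> marker for no mode
  expect_equal(unname(mk$residuals[, 1]), c(0.5, 0.5, -0.2, 3.2),
               tolerance = 1e-6)
  expect_equal(unname(mk$residuals[, 2]), c(3.0, 1.5, 2.6, 2.8),
               tolerance = 1e-6)
  expect_setequal(mk$markers$mode1, c("s01", "s03"))
  expect_length(mk$markers$mode2, 0L)
})

test_that("a single mode makes the exclusion condition vacuous", {
  study <- residual_design_study(
    Gamma_hat = c(0.5, 1.5, -0.9), gamma_hat = c(1, 1, 1))
  mk <- select_markers(study, study$snp, modes = 0)
  expect_setequal(mk$markers$mode1, c("s01", "s03"))
})

test_that("marker sets are disjoint across modes on simulated pathways", {
  sim <- make_fixture("two-pathway")
  instr <- build_instruments(sim$study, 1e-2, assume_independent = TRUE)
  prof <- profile_curve(sim$study, instr)
  mk <- select_markers(sim$study, instr$ids, prof$modes)
  all_markers <- unlist(mk$markers)
  expect_equal(anyDuplicated(all_markers), 0L)
})

test_that("t0 >= t1 is rejected", {
  study <- residual_design_study(Gamma_hat = 0.1, gamma_hat = 1)
  expect_error(select_markers(study, study$snp, modes = 0, t0 = 2, t1 = 2),
               "t0 < t1")
})

test_that("direction diagnosis separates forward from reverse orientation", {
  fwd <- make_fixture("no-pleiotropy")      # true X -> Y, beta = 0.5
  rev <- make_fixture("reverse-direction")  # same truth, roles swapped
  fi <- build_instruments(fwd$study, 1e-2, assume_independent = TRUE)
  ri <- build_instruments(rev$study, 1e-2, assume_independent = TRUE)
  dd <- direction_diagnostic(fwd$study, rev$study, fi, ri)
  expect_equal(dd$call, "forward")
  expect_equal(nrow(dd$forward$modes), 1L)
  expect_lt(abs(dd$forward_mode - 0.5), 0.05)
  expect_equal(nrow(dd$reverse$modes), 2L)
  expect_lt(abs(dd$reverse_mode_near_zero), 0.05)
  # the second reverse mode sits near the reciprocal of the forward effect
  expect_lt(abs(dd$reverse_mode_near_reciprocal - 2), 0.2)
})
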