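test_that("instrument conversion applies spring constant and sensitivity", {
  seg <- data.frame(piezo_position = c(0, 1e-9, 2e-9), deflection = c(0, 0, 1))
  cv <- force_curve(seg, seg, k = 0.139, defl_sens = 40.7e-9, R = 20e-9)
  fs <- to_force_separation(cv, baseline_frac = 1e-9)  # no baseline here
  # 1 V deflection -> k * sens = 0.139 * 40.7e-9 N
  expect_equal(max(fs$retract$force), 0.139 * 40.7e-9, tolerance = 1e-12)
  expect_equal(max(fs$retract$force), 5.66e-9, tolerance = 1e-3)
  # separation corrects piezo travel for cantilever bending
  expect_equal(fs$retract$separation,
               seg$piezo_position - fs$retract$force / 0.139,
               tolerance = 1e-15)
  # zero deflection everywhere -> zero force everywhere
  z <- data.frame(piezo_position = seq(0, 1e-8, length.out = 30),
                  deflection = 0)
  fz <- to_force_separation(force_curve(z, z, k = 0.139,
                                        defl_sens = 40.7e-9, R = 20e-9))
  expect_true(all(fz$approach$force == 0))
  # metre-deflection curves skip the sensitivity
  segm <- data.frame(piezo_position = c(1e-8, 0), deflection = c(0, 1e-9))
  cm <- force_curve(segm, segm, k = 0.2, R = 20e-9, deflection_unit = "m")
  expect_equal(max(to_force_separation(cm, 1e-9)$retract$force), 0.2e-9)
})

test_that("missing calibration is reported by field name", {
  seg <- data.frame(piezo_position = 0, deflection = 0)
  expect_error(force_curve(seg, seg, k = -1, defl_sens = 1e-9, R = 1e-9), "`k`")
  expect_error(force_curve(seg, seg, k = 1, defl_sens = NA, R = 1e-9),
               "`defl_sens`")
  expect_error(force_curve(seg, seg, k = 1, defl_sens = 1e-9, R = 0), "`R`")
})

test_that("calibration round trip recovers the generator's force array", {
  cfg <- jkr_sim_config(E = 1.5e8, delta_r = 10, R = 20e-9)
  cv <- simulate_jkr_curve(cfg)
  fs <- to_force_separation(cv)
  tr <- attr(cv, "truth")
  expect_equal(fs$retract$force, tr$force$retract, tolerance = 1e-12)
  expect_equal(fs$approach$force, tr$force$approach, tolerance = 1e-12)
})

test_that("pull-off detection matches the closed form and flags no adhesion", {
  fs <- to_force_separation(simulate_jkr_curve(
    jkr_sim_config(E = 41.6e6, delta_r = 3.37, R = 20e-9)))
  po <- detect_pull_off(fs)
  expect_false(po$no_adhesion)
  expect_equal(po$P_adh, oracle_pull_off(3.37, 20e-9), tolerance = 1e-10)
  expect_equal(po$P_adh, -3.18e-7, tolerance = 1e-2)
  # all-positive retract forces
  po0 <- detect_pull_off(data.frame(force = c(0.1, 0.5, 0.2)))
  expect_true(po0$no_adhesion)
  expect_identical(po0$P_adh, 0)
  expect_error(detect_pull_off(data.frame(force = numeric(0))), "non-empty")
})

test_that("noisy pull-off detection obeys the extreme-value error bound", {
  # the minimum of n noisy samples is biased low by ~ sigma*sqrt(2 log n);
  # detection error must stay within that envelope and never overshoot much
  sigma <- 2e-9
  true_P <- oracle_pull_off(3.37, 20e-9)
  set.seed(99)
  det <- replicate(100, {
    cv <- simulate_jkr_curve(jkr_sim_config(E = 41.6e6, delta_r = 3.37,
                                            R = 20e-9, noise_sd = sigma))
    detect_pull_off(to_force_separation(cv))$P_adh
  })
  n <- 200
  bound <- sigma * (sqrt(2 * log(n)) + 1.5)
  expect_true(all(det - true_P >= -bound))
  # overshoot is limited to noise at the deepest grid point plus the
  # baseline-estimate shift (~sigma/sqrt(n_baseline))
  expect_true(all(det - true_P <= sigma * 4.5))
  expect_lte(mean(det) - true_P, 0)        # bias is downward
  expect_lt(abs(mean(det) - true_P), bound)
})

test_that("work of adhesion inverts the pull-off relation", {
  expect_equal(delta_r_from_pull_off(-3.18e-7, 20e-9), 3.37, tolerance = 2e-3)
  expect_equal(delta_r_from_pull_off(0, 20e-9), 0)
  # doubling R at fixed pull-off halves the work of adhesion
  d1 <- delta_r_from_pull_off(-1e-8, 5e-9)
  expect_equal(delta_r_from_pull_off(-1e-8, 1e-8), d1 / 2)
  expect_error(delta_r_from_pull_off(1e-9, 20e-9), "convention")
  expect_error(delta_r_from_pull_off(-1e-9, -1), "positive")
})

test_that("depth-load law honours its special points", {
  a0 <- 7.7e-8; R <- 20e-9; Pa <- -3.18e-7
  expect_equal(jkr_depth(0, a0, R, Pa), a0^2 / (3 * R), tolerance = 1e-14)
  cst <- (1 / 2)^(4 / 3) - (2 / 3) * (1 / 2)^(1 / 3)  # -0.13228...
  expect_equal(jkr_depth(Pa, a0, R, Pa), cst * a0^2 / R, tolerance = 1e-14)
  expect_equal(cst, -0.13228, tolerance = 1e-4)
  expect_error(jkr_depth(2 * Pa, a0, R, Pa), "unphysical")
  expect_error(jkr_depth(0, a0, R, 1e-9), "negative")
})

test_that("noiseless fits recover the generator parameters", {
  fit <- fit_jkr(simulate_jkr_curve(jkr_sim_config(E = 41.6e6, delta_r = 3.37)))
  expect_true(fit$converged)
  expect_equal(fit$E_jkr, 41.6e6, tolerance = 1e-6)
  expect_equal(fit$delta_r, 3.37, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["a0"]), oracle_a0(41.6e6, 3.37, 20e-9),
               tolerance = 1e-9)
  expect_equal(unname(coef(fit)["h0"]), 0, tolerance = 1e-15)
  # residual consistency: the fitted law reproduces the depths within rss
  expect_equal(sum(residuals(fit)^2), fit$rss, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-24)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  # co-estimation of the pull-off force agrees on noiseless data
  fit2 <- fit_jkr(simulate_jkr_curve(jkr_sim_config(E = 41.6e6, delta_r = 3.37)),
                  co_estimate = TRUE)
  expect_equal(fit2$E_jkr, 41.6e6, tolerance = 1e-3)
})

test_that("fits are refused or flagged on degenerate inputs", {
  df <- data.frame(separation = c(-1e-9, -2e-9, -3e-9),
                   force = c(-1e-9, 0, 1e-9))
  expect_error(fit_jkr(df, R = 20e-9, P_adh = -1e-9), "refused")
  expect_error(fit_jkr(df, R = 20e-9, P_adh = 1e-9), "negative")
  expect_error(fit_jkr(df, R = NULL, P_adh = -1e-9), "radius")
  # adhesionless curve cannot be fit by the adhesive model
  cv0 <- simulate_jkr_curve(jkr_sim_config(E = 5e7, delta_r = 0))
  expect_error(fit_jkr(cv0), "no adhesion")
})

test_that("stiffer samples fit smaller contact radii at fixed adhesion", {
  a0s <- vapply(c(10e6, 50e6, 200e6, 450e6), function(E) {
    fit_jkr(simulate_jkr_curve(jkr_sim_config(E = E, delta_r = 5)))$a0
  }, numeric(1))
  expect_true(all(diff(a0s) < 0))
})

test_that("hysteresis integration matches closed-form oracles", {
  # rectangle: approach at zero force, retract at -c over width d -> area c*d
  h <- seq(0, 4e-8, length.out = 101)  # depth grid, separation = -h
  cc <- 2e-9; d <- 4e-8
  app <- data.frame(separation = -h, force = 0)
  ret <- data.frame(separation = -h, force = -cc)
  wa <- work_of_adhesion(app, ret, R = 20e-9)
  expect_equal(wa$hysteresis_area, cc * d, tolerance = 1e-12)
  expect_equal(wa$contact_area, pi * 20e-9 * max(h), tolerance = 1e-12)
  # dimensional bookkeeping: W = area / contact area (J/m^2 == N/m)
  expect_identical(wa$W, wa$hysteresis_area / wa$contact_area)

  # reversible JKR loop: enclosed area equals the quadrature oracle
  cfg <- jkr_sim_config(E = 162e6, delta_r = 17.2, n_points = 1000)
  fs <- to_force_separation(simulate_jkr_curve(cfg))
  wa2 <- work_of_adhesion(fs)
  expect_equal(wa2$hysteresis_area, oracle_loop_area(162e6, 17.2, 20e-9),
               tolerance = 1e-4)
  # ... which fixes W at 0.34775 * delta_r under the default load range,
  # independent of (E, delta_r, R)
  for (p in list(c(41.6e6, 3.37), c(132e6, 2.39), c(1e7, 25))) {
    fsx <- to_force_separation(simulate_jkr_curve(
      jkr_sim_config(E = p[1], delta_r = p[2], n_points = 1000)))
    mp <- (1 + sqrt(6)) / 2
    ratio_oracle <- (3 / 4) * (oracle_loop_area(p[1], p[2], 20e-9) /
                                 ((3 / 4) * pi * p[2] *
                                    oracle_a0(p[1], p[2], 20e-9)^2)) /
      (mp^(4 / 3) - (2 / 3) * mp^(1 / 3))
    expect_equal(work_of_adhesion(fsx)$W / p[2], ratio_oracle,
                 tolerance = 1e-3)
    expect_equal(ratio_oracle, 0.347751, tolerance = 1e-5)
  }

  # degenerate cases
  expect_error(work_of_adhesion(app, ret, R = 20e-9, h_t_max = -1),
               "h_t_max")
  far <- data.frame(separation = -h + 1e-6, force = 0)
  expect_error(work_of_adhesion(far, ret, R = 20e-9), "overlap")
})

test_that("sample summaries use the standard-error definition SD/sqrt(n)", {
  s <- sample_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$se, 1 / sqrt(3))
  expect_equal(sample_summary(rep(5, 8))$se, 0)
  expect_error(sample_summary(3), "two")
  # planted spread: values rescaled to sample SD 85.7 at n = 51
  set.seed(4)
  v <- rnorm(51)
  v <- 132 + (v - mean(v)) / sd(v) * 85.7
  s2 <- sample_summary(v)
  expect_equal(s2$se, 85.7 / sqrt(51), tolerance = 1e-12)
  expect_equal(s2$se, 12.0, tolerance = 1e-2)
})
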