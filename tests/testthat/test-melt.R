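# High-resolution-melt branch: baselines, yields, Keq, Tm, motif dG.

test_that("baselines on ideal plateaus are recovered to 1e-9", {
  # exact step curve: fully duplexed below 50 C, fully dissociated above 74 C
  tc <- seq(95, 30, by = -1)
  up <- c(intercept = 110, slope = -0.2)
  lo <- c(intercept = 25, slope = -0.05)
  theta <- ifelse(tc <= 50, 1, ifelse(tc >= 74, 0, (74 - tc) / 24))
  fl <- lo[[1]] + lo[[2]] * tc + theta * ((up[[1]] + up[[2]] * tc) -
                                            (lo[[1]] + lo[[2]] * tc))
  b <- fit_baselines(melt_curve(tc, fl, 300e-9))
  expect_equal(b$upper, up, tolerance = 1e-9)
  expect_equal(b$lower, lo, tolerance = 1e-9)
  # flat baselines come back flat
  flf <- 20 + theta * 80
  bf <- fit_baselines(melt_curve(tc, flf, 300e-9))
  expect_equal(bf$upper[["slope"]], 0, tolerance = 1e-9)
  expect_equal(bf$lower[["slope"]], 0, tolerance = 1e-9)
})

test_that("baselines on generated two-state curves match at plateau level", {
  # residual dissociation in the cool window caps agreement near 1e-3
  p <- melt_test_params()
  cv <- generate_melt_curve(p$dH_yz, p$dS_yz, noise = zero_noise())
  b <- fit_baselines(cv)
  for (tc in c(32, 37)) {
    expect_equal(eval_bl(b$upper, tc), 110 - 0.2 * tc, tolerance = 1e-3)
  }
  for (tc in c(88, 93)) {
    expect_equal(eval_bl(b$lower, tc), 25 - 0.05 * tc, tolerance = 1e-3)
  }
})

test_that("noisy baseline values stay within a few standard errors", {
  p <- melt_test_params()
  cv <- generate_melt_curve(p$dH_yz, p$dS_yz,
                            noise = noise_model(seed = 17))
  b <- fit_baselines(cv)
  # melt_fluor_sd = 0.01 of the ~85-unit span, ~10 points per window:
  # baseline values inside the windows are good to ~3 x 0.3 units
  expect_lt(abs(eval_bl(b$upper, 35) - (110 - 0.2 * 35)), 1)
  expect_lt(abs(eval_bl(b$lower, 90) - (25 - 0.05 * 90)), 1)
})

test_that("hybridization yield interpolates between the baselines", {
  p <- melt_test_params()
  cv <- generate_melt_curve(p$dH_yz, p$dS_yz, noise = zero_noise())
  bl <- known_baselines()
  theta <- hybridization_yield(cv, bl)
  expect_true(all(theta >= 1e-4 & theta <= 1 - 1e-4))
  # a point exactly midway maps to 0.5
  cv2 <- cv
  cv2$fluorescence[10] <- mean(c(110 - 0.2 * cv$temperature_celsius[10],
                                 25 - 0.05 * cv$temperature_celsius[10]))
  expect_equal(hybridization_yield(cv2, bl)[10], 0.5, tolerance = 1e-12)
  # a point on the upper baseline clips to 1 - eps
  cv2$fluorescence[10] <- 110 - 0.2 * cv$temperature_celsius[10] + 5
  expect_equal(hybridization_yield(cv2, bl)[10], 1 - 1e-4)
  # noiseless two-state theta matches the generating sigmoid
  tk <- cv$temperature_celsius + 273.15
  keq <- exp(-(p$dH_yz - tk * p$dS_yz) / (R_KCAL * tk))
  truth <- nativedg:::two_state_theta(keq, p$strand_total)
  expect_equal(theta, pmin(pmax(truth, 1e-4), 1 - 1e-4), tolerance = 1e-6)
})

test_that("yield converts to the bimolecular association constant", {
  expect_equal(keq_from_yield(0.5, 300e-9), 6666666.666666667,
               tolerance = 1e-9)
  # dilute limit: Keq -> theta / c
  th <- 1e-5
  expect_equal(keq_from_yield(th, 300e-9), th / 300e-9, tolerance = 1e-4)
  expect_error(keq_from_yield(0, 300e-9), "inside")
  expect_error(keq_from_yield(1, 300e-9), "inside")
  # round-trip with the generating model
  keq <- 2e7
  th2 <- nativedg:::two_state_theta(keq, 300e-9)
  expect_equal(keq_from_yield(th2, 300e-9), keq, tolerance = 1e-9)
})

test_that("melting temperature matches the closed form and shifts with it", {
  p <- melt_test_params()
  cv <- generate_melt_curve(p$dH_yz, p$dS_yz, noise = zero_noise())
  tm_closed <- two_state_tm(p$dH_yz, p$dS_yz, p$strand_total)
  expect_equal(tm_closed, 62, tolerance = 1e-9)
  expect_equal(melting_temperature(cv, known_baselines()), tm_closed,
               tolerance = 0.05)
  # shifting the curve by +2 C shifts Tm by +2 C
  cv2 <- melt_curve(cv$temperature_celsius + 2, cv$fluorescence,
                    cv$strand_total)
  bl2 <- known_baselines(
    upper = c(intercept = 110 + 0.2 * 2, slope = -0.2),
    lower = c(intercept = 25 + 0.05 * 2, slope = -0.05))
  expect_equal(melting_temperature(cv2, bl2), tm_closed + 2,
               tolerance = 0.05)
  # a curve that never dissociates has no Tm
  flat <- melt_curve(seq(95, 30), rep(100, 66), 300e-9)
  expect_error(melting_temperature(flat, known_baselines()), "crosses 0.5")
})

test_that("identical curves give a zero motif dG", {
  p <- melt_test_params()
  cv <- generate_melt_curve(p$dH_yz, p$dS_yz, noise = zero_noise())
  est <- motif_dg_from_melt_pair(cv, cv, cond25)
  expect_equal(est$value, 0, tolerance = 1e-12)
})

test_that("noiseless melt pair recovers the motif dG", {
  p <- melt_test_params(motif_dg25 = -0.22)
  cxz <- generate_melt_curve(p$dH_xz, p$dS_xz, noise = zero_noise(),
                             label = "XZ")
  cyz <- generate_melt_curve(p$dH_yz, p$dS_yz, noise = zero_noise(),
                             label = "YZ")
  # full pipeline with fitted baselines
  est <- motif_dg_from_melt_pair(cxz, cyz, cond25)
  expect_lt(abs(est$value + 0.22), 1e-3)
  # with the true baselines the chain is exact
  bl <- known_baselines()
  est_k <- motif_dg_from_melt_pair(cxz, cyz, cond25,
                                   baselines_xz = bl, baselines_yz = bl)
  expect_equal(est_k$value, -0.22, tolerance = 1e-9)
})

test_that("noiseless per-curve van't Hoff recovers the generating dH and dS", {
  p <- melt_test_params()
  cv <- generate_melt_curve(p$dH_yz, p$dS_yz, noise = zero_noise())
  vh <- nativedg:::vant_hoff_from_curve(cv, known_baselines())
  expect_equal(vh[["dH"]], p$dH_yz, tolerance = 1e-6)
  expect_equal(vh[["dS"]], p$dS_yz, tolerance = 1e-6)
})

test_that("melt-derived dG is far noisier than catalysis-derived dG", {
  p <- melt_test_params(motif_dg25 = -0.22)
  melt_vals <- sapply(1:3, function(s) {
    cxz <- generate_melt_curve(p$dH_xz, p$dS_xz,
                               noise = noise_model(seed = 2 * s), label = "XZ")
    cyz <- generate_melt_curve(p$dH_yz, p$dS_yz,
                               noise = noise_model(seed = 2 * s + 1),
                               label = "YZ")
    motif_dg_from_melt_pair(cxz, cyz, cond25)$value
  })
  gel_vals <- sapply(1:3, function(s) {
    gel_delta_g(generate_gel_experiment(-0.22,
                                        noise = noise_model(seed = s)))$value
  })
  expect_gt(stats::sd(melt_vals) / stats::sd(gel_vals), 1)
})

test_that("curve validation catches malformed inputs", {
  expect_error(melt_curve(1:10, 1:10, 3e-7), "20 points")
  expect_error(melt_curve(1:30, 1:29, 3e-7), "equal length")
  expect_error(melt_curve(1:30, 1:30, 0), "> 0")
  p <- melt_test_params()
  cv <- generate_melt_curve(p$dH_yz, p$dS_yz, noise = zero_noise())
  expect_error(fit_baselines(cv, window = 0.6), "overlap")
})
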