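# Consensus statistics, subtraction, score expectations, van't Hoff fit.

test_that("fluorophore subtraction adds variances", {
  r1 <- dg_estimate(-0.22, 0.038, 12L, cond25, "fluor")
  r2 <- dg_estimate(-0.90, 0.050, 4L, cond25, "fluor+dangle")
  d <- subtract_fluorophore(r2, r1)
  expect_equal(d$value, -0.68)
  expect_equal(d$sd, sqrt(0.038^2 + 0.05^2), tolerance = 1e-12)
  expect_equal(d$sd, 0.0628, tolerance = 1e-3)
  p <- subtract_fluorophore(dg_estimate(0, 0.03, 1L, cond25),
                            dg_estimate(0, 0.04, 1L, cond25))
  expect_equal(p$sd, 0.05)  # 3-4-5
  expect_equal(p$value, 0)
  expect_error(subtract_fluorophore(r2, dg_estimate(-0.2, 0.04, 1L,
                                                    thermo_condition(37))),
               "different conditions")
})

test_that("consensus score hits its defining landmarks", {
  s <- 0.05
  pair <- function(delta) {
    consensus_and_cs(dg_estimate(-0.3, s, 1L, cond25, "ROX"),
                     dg_estimate(-0.3 + delta, s, 1L, cond25, "Alexa532"))
  }
  expect_equal(pair(0)$cs, 10)
  expect_equal(pair(2 * s)$cs, 8)            # each input 1 sd from consensus
  expect_equal(pair(2 * sqrt(5) * s)$cs, 0)  # each input 2.236 sd away
  expect_equal(pair(2 * s)$consensus$value, -0.3 + s)
})

test_that("consensus equals the brute-force sum-of-squared-z minimiser", {
  set.seed(19)
  for (i in 1:5) {
    v <- stats::rnorm(2, -0.3, 0.2)
    s <- stats::runif(2, 0.02, 0.15)
    res <- consensus_and_cs(dg_estimate(v[1], s[1], 1L, cond25, "a"),
                            dg_estimate(v[2], s[2], 1L, cond25, "b"))
    expect_equal(res$consensus$value, oracle_consensus(v, s),
                 tolerance = 2e-6)
    # closed-form CS identity
    expect_equal(res$cs, 10 - (v[1] - v[2])^2 / sum(s^2), tolerance = 1e-9)
    # consensus lies between the inputs; swapping inputs changes nothing
    expect_gte(res$consensus$value, min(v))
    expect_lte(res$consensus$value, max(v))
    swapped <- consensus_and_cs(dg_estimate(v[2], s[2], 1L, cond25, "b"),
                                dg_estimate(v[1], s[1], 1L, cond25, "a"))
    expect_equal(swapped$consensus$value, res$consensus$value)
    expect_equal(swapped$cs, res$cs)
  }
})

test_that("consensus generalises to more than two measurements", {
  ests <- list(dg_estimate(-0.25, 0.05, 1L, cond25, "a"),
               dg_estimate(-0.20, 0.10, 1L, cond25, "b"),
               dg_estimate(-0.31, 0.04, 1L, cond25, "c"))
  res <- consensus_and_cs(ests)
  w <- 1 / c(0.05, 0.10, 0.04)^2
  expect_equal(res$consensus$value,
               sum(w * c(-0.25, -0.20, -0.31)) / sum(w), tolerance = 1e-12)
  expect_equal(res$consensus$sd, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_lte(res$cs, 10)
  expect_error(consensus_and_cs(ests[[1]],
                                dg_estimate(-0.2, 0, 1L, cond25)),
               "positive sd")
})

test_that("Gaussian expectation of consensus-score failures", {
  expect_equal(expected_cs_failures(160, 0), 4.055570988394948,
               tolerance = 1e-9)
  expect_lt(abs(expected_cs_failures(160, 0) / 160 - 0.025), 0.001)
  expect_equal(expected_cs_failures(160, 10), 160)  # z* = 0 boundary
  expect_equal(expected_cs_failures(160, 8), 50.769681258066264,
               tolerance = 1e-9)
  expect_error(expected_cs_failures(160, 11), "exceed")
})

test_that("seeded simulation reproduces the 2.5% failure rate", {
  frac <- simulate_cs_fraction(n_pairs = 10000L, sigma = 0.05, seed = 123)
  expect_lt(abs(frac - 0.025), 0.005)
  # invariant to the reported sigma
  expect_equal(simulate_cs_fraction(2000L, sigma = 0.4, seed = 5),
               simulate_cs_fraction(2000L, sigma = 0.01, seed = 5))
})

test_that("precision ratio and experiment multiplier", {
  cmp <- precision_comparison(0.54, 0.038)
  expect_equal(round(cmp$ratio), 14)
  expect_equal(round(cmp$ratio)^2, 196)
  expect_equal(cmp$experiment_multiplier, cmp$ratio^2)
})

test_that("van't Hoff fit interpolates two points exactly", {
  ests <- list(dg_estimate(-0.25, 0.03, 1L, thermo_condition(10)),
               dg_estimate(-0.20, 0.05, 1L, thermo_condition(45)))
  fit <- vant_hoff_fit(ests)
  expect_equal(fit$sum_sq_z, 0, tolerance = 1e-9)
  for (e in ests) {
    expect_equal(delta_g_at_temperature(fit, e$condition), e$value,
                 tolerance = 1e-9)
  }
})

test_that("noiseless four-temperature data recover the printed fit values", {
  truth <- enthalpy_entropy_fit(dH = -0.81, dS = entropy_cal_to_kcal(-1.89))
  ests <- lapply(c(10, 25, 37, 45), function(tc) {
    cond <- thermo_condition(tc)
    dg_estimate(delta_g_at_temperature(truth, cond), 1e-9, 1L, cond)
  })
  fit <- vant_hoff_fit(ests)
  expect_equal(fit$dH, -0.81, tolerance = 1e-6)
  expect_equal(entropy_kcal_to_cal(fit$dS), -1.89, tolerance = 1e-6)
})

test_that("weighted fit equals the 2-D grid-search oracle", {
  set.seed(31)
  tk <- c(10, 25, 37, 45) + 273.15
  mu <- -0.8 + tk * 1.9e-3 + stats::rnorm(4, 0, 0.05)
  sig <- stats::runif(4, 0.02, 0.12)
  ests <- mapply(function(m, s, t) dg_estimate(m, s, 1L,
                                               thermo_condition(t - 273.15)),
                 mu, sig, tk, SIMPLIFY = FALSE)
  fit <- vant_hoff_fit(ests)
  ora <- oracle_vant_hoff(tk, mu, sig)
  expect_equal(fit$dH, ora[["dH"]], tolerance = 1e-3)
  expect_equal(fit$dS, ora[["dS"]], tolerance = 1e-3)
})

test_that("equal-sigma weighted fit reduces to ordinary least squares", {
  tk <- c(10, 25, 37, 45) + 273.15
  mu <- c(-0.26, -0.24, -0.225, -0.21)
  ests <- mapply(function(m, t) dg_estimate(m, 0.05, 1L,
                                            thermo_condition(t - 273.15)),
                 mu, tk, SIMPLIFY = FALSE)
  fit <- vant_hoff_fit(ests)
  ols <- stats::coef(stats::lm(mu ~ I(-tk)))
  expect_equal(fit$dH, unname(ols[1]), tolerance = 1e-9)
  expect_equal(fit$dS, unname(ols[2]), tolerance = 1e-9)
})

test_that("degenerate van't Hoff inputs are rejected", {
  e1 <- dg_estimate(-0.2, 0.05, 1L, cond25)
  expect_error(vant_hoff_fit(list(e1)), "distinct temperatures")
  expect_error(vant_hoff_fit(list(e1, dg_estimate(-0.3, 0.05, 1L, cond25))),
               "distinct temperatures")
  expect_error(vant_hoff_fit(list(e1, dg_estimate(-0.3, NA, 1L,
                                                  thermo_condition(37)))),
               "positive sd")
})
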