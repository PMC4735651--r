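# Band tables -> concentrations -> per-lane dG, and replicate aggregation.

test_that("band-table write/read round-trips a six-lane experiment", {
  exp <- generate_gel_experiment(-0.22, noise = noise_model(seed = 3))
  roles <- vapply(exp$lanes, `[[`, character(1), "role")
  expect_equal(as.integer(table(roles)[c("control_XZ", "control_X",
                                         "uncatalysed", "catalysed")]),
               c(1L, 1L, 2L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_band_table(exp, path)
  back <- read_band_table(path)
  expect_equal(length(back$lanes), length(exp$lanes))
  for (id in names(exp$lanes)) {
    expect_equal(back$lanes[[id]]$initials, exp$lanes[[id]]$initials)
    expect_equal(back$lanes[[id]]$bands, exp$lanes[[id]]$bands)
    expect_equal(back$lanes[[id]]$role, exp$lanes[[id]]$role)
  }
  expect_equal(back$truth$truth_dg, exp$truth$truth_dg)
  expect_equal(back$condition$temperature_celsius,
               exp$condition$temperature_celsius)
})

test_that("malformed band tables are rejected with row locations", {
  exp <- generate_gel_experiment(-0.22, noise = noise_model(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_band_table(exp, path)
  lines <- readLines(path)
  neg <- sub("^(([^,]*,){4}).*$", "\\1-5", grep("^5,", lines, value = TRUE)[1])
  bad <- lines
  bad[grep("^5,", bad)[1]] <- neg
  writeLines(bad, path)
  expect_error(read_band_table(path), "negative band intensity at line")

  dup <- c(lines, lines[length(lines)])
  writeLines(dup, path)
  expect_error(read_band_table(path), "duplicate lane x species")

  no_ctrl <- lines[!grepl("control_X,", lines, fixed = TRUE)]
  writeLines(no_ctrl, path)
  expect_error(read_band_table(path), "control lanes")
})

test_that("lane normalization is invariant to a common band scale", {
  exp <- generate_gel_experiment(-0.4, noise = noise_model(seed = 9))
  lane <- exp$lanes[["5"]]
  base <- normalize_lane(lane, exp)
  lane$bands <- lane$bands * 1.3
  expect_equal(normalize_lane(lane, exp), base, tolerance = 1e-12)
  # conservation of labelled material holds by construction
  expect_equal(sum(base), sum(lane$initials[c("X", "XZ")]),
               tolerance = 1e-12)
})

test_that("normalization undoes a known quantum-yield ratio exactly", {
  exp <- generate_gel_experiment(-0.7, noise = zero_noise(),
                                 yield_ratio = 0.8)
  lane <- exp$lanes[["5"]]
  conc <- normalize_lane(lane, exp)
  # noiseless: recover the true equilibrium concentrations to 1e-9
  truth_net <- species_network(
    c(XZ = exp$truth$dg_xz, YZ = exp$truth$dg_yz),
    c(X = 1, Y = 1, Z = 1) * exp$truth$total_1x_M, exp$condition)
  st <- solve_equilibrium(truth_net)$concentrations / exp$truth$total_1x_M
  expect_equal(conc[["XZ"]], st[["XZ"]], tolerance = 1e-9)
  expect_equal(conc[["X"]], st[["X"]], tolerance = 1e-9)
})

test_that("mass-balance inference recovers the full species vector", {
  ini <- c(X = 0, Y = 1, XZ = 1, YZ = 0)
  sym <- infer_concentrations(0.5, ini)
  expect_equal(unname(sym[c("X", "Y", "XZ", "YZ")]), c(0.5, 0.5, 0.5, 0.5))
  shifted <- infer_concentrations(0.6, ini)
  expect_equal(unname(shifted[c("X", "Y", "XZ", "YZ")]),
               c(0.4, 0.6, 0.6, 0.4))
  keq <- (shifted[["Y"]] * shifted[["XZ"]]) /
    (shifted[["X"]] * shifted[["YZ"]])
  expect_equal(keq, 2.25, tolerance = 1e-12)
  expect_equal(delta_g_from_keq(keq, cond25), -0.480463946287133,
               tolerance = 1e-9)
  # X-derived and XZ-derived inferences agree
  expect_equal(infer_concentrations(0.4, ini, observed_species = "X"),
               shifted)
  expect_error(infer_concentrations(1.2, ini), "feasible interval")
  # small overshoot is clipped to the boundary
  clipped <- infer_concentrations(1.01, ini)
  expect_equal(clipped[["XZ"]], 1)
})

test_that("noiseless lanes recover the generating reaction dG to 1e-9", {
  for (truth in c(-0.22, 0.9)) {
    exp <- generate_gel_experiment(truth, noise = zero_noise())
    for (id in c("5", "6")) {
      est <- lane_delta_g(exp$lanes[[id]], exp)
      expect_equal(est$value, truth, tolerance = 1e-9)
      expect_equal(est$n_measurements, 1L)
    }
  }
})

test_that("dG is only inferred from equilibrated lanes", {
  exp <- generate_gel_experiment(-0.22, noise = zero_noise())
  expect_error(lane_delta_g(exp$lanes[["3"]], exp), "catalysed")
  expect_error(lane_delta_g(exp$lanes[["1"]], exp), "catalysed")
})

test_that("complete conversion errors instead of returning a number", {
  exp <- generate_gel_experiment(-0.22, noise = zero_noise())
  lane <- exp$lanes[["5"]]
  lane$bands <- c(X = 0, XZ = 80)  # all labelled material in the duplex
  expect_error(lane_delta_g(lane, exp), "complete conversion")
})

test_that("replicate aggregation follows the Gaussian error model", {
  mk <- function(v) dg_estimate(v, NA_real_, 1L, cond25, "rep")
  same <- aggregate_estimates(lapply(c(-0.2, -0.2, -0.2), mk))
  expect_equal(same$value, -0.2)
  expect_equal(same$sd, 0)
  two <- aggregate_estimates(lapply(c(0, 1), mk))
  expect_equal(two$value, 0.5)
  expect_equal(two$sd, 0.5)  # sample sd 1/sqrt(2), sd of mean 0.5
  expect_equal(two$n_measurements, 2L)
  mixed <- list(mk(0), dg_estimate(0, NA_real_, 1L, thermo_condition(37)))
  expect_error(aggregate_estimates(mixed), "different conditions")
})

test_that("12 seeded replicates pin the mean near the truth", {
  vals <- withr::with_seed(21, stats::rnorm(12, -0.21, 0.13))
  est <- aggregate_estimates(lapply(vals, dg_estimate, sd = NA_real_,
                                    n_measurements = 1L, condition = cond25,
                                    label = "sim"))
  expect_lt(abs(est$value + 0.21), 3 * 0.13 / sqrt(12))
  expect_equal(est$n_measurements, 12L)
})

test_that("aggregation sd shrinks as 1/sqrt(n) on synthetic replicates", {
  draw_sd <- function(n, seed) {
    vals <- withr::with_seed(seed, stats::rnorm(n, -0.2, 0.1))
    aggregate_estimates(lapply(vals, dg_estimate, sd = NA_real_,
                               n_measurements = 1L, condition = cond25))$sd
  }
  sds <- sapply(1:40, function(s) c(draw_sd(5, s), draw_sd(45, 1000 + s)))
  ratio <- mean(sds[1, ]) / mean(sds[2, ])
  expect_equal(ratio, 3, tolerance = 0.25)  # sqrt(45/5) = 3
})
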