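# Seeded synthetic-data generators with known ground truth: gel
# experiments, melt curves, dangle-length series. Every generator embeds
# its truth and seed in the output metadata and draws noise from one seeded
# source without touching the caller's RNG state.

#' Noise model for synthetic gel and melt data
#'
#' The error structure the analysis assumes: per-lane loading error
#' (lognormal, from pipetting the sample into the well), multiplicative
#' band-quantitation noise, relative stoichiometry error on every initial
#' concentration (sample prep), and additive melt fluorescence noise in
#' units of the plateau span. Temperature error and oligonucleotide
#' synthesis error are not modelled.
#'
#' @param lane_loading_sd lognormal sigma of the per-lane loading factor.
#' @param band_quant_cv multiplicative Gaussian CV per band.
#' @param stoichiometry_sd relative Gaussian error on initial
#'   concentrations.
#' @param melt_fluor_sd additive melt noise, units of the plateau span.
#' @param seed integer seed; `NULL` draws from the current RNG state.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(lane_loading_sd = 0.05, band_quant_cv = 0.02,
                        stoichiometry_sd = 0.03, melt_fluor_sd = 0.01,
                        seed = NULL) {
  vals <- c(lane_loading_sd, band_quant_cv, stoichiometry_sd, melt_fluor_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("noise magnitudes must be finite and >= 0")
  }
  structure(list(lane_loading_sd = lane_loading_sd,
                 band_quant_cv = band_quant_cv,
                 stoichiometry_sd = stoichiometry_sd,
                 melt_fluor_sd = melt_fluor_sd, seed = seed),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
zero_noise <- function(seed = NULL) noise_model(0, 0, 0, 0, seed = seed)

# Run expr under the noise model's seed (if any) without disturbing the
# caller's RNG state.
with_noise_seed <- function(noise, expr) {
  if (is.null(noise$seed)) expr else withr::with_seed(noise$seed, expr)
}

#' Generate a six-lane synthetic gel experiment with known truth
#'
#' Emulates the standard fluorescent PAGE layout: lane 1 a pre-annealed XZ
#' control, lane 2 an X-only control, lanes 3-4 the two uncatalysed
#' direction setups (XZ0 + Y0 and YZ0 + X0) integrated kinetically for the
#' incubation time (far from equilibrium at the direct-exchange rate),
#' lanes 5-6 the same setups with catalyst, taken at the solved
#' equilibrium. Concentrations become band intensities via a per-state
#' quantum-yield factor and the 100-units-per-1x single-strand scale, then
#' lane loading, band quantitation and stoichiometry noise are applied.
#'
#' The generated reaction has `dG(XZ) = duplex_dg + truth_dg` and
#' `dG(YZ) = duplex_dg`, so the net exchange free energy — the quantity
#' [lane_delta_g()] recovers — is exactly `truth_dg`. By default no CZ
#' intermediate is included (the catalyst is assumed to leave no
#' significant bound species, the same working assumption the inference
#' makes); a finite `cz_offset` adds CZ at `max(dG_XZ, dG_YZ) + cz_offset`
#' and thereby injects the catalyst-sequestration bias studied by
#' [bias_scan()].
#'
#' @param truth_dg net reaction standard free energy, kcal mol^-1.
#' @param condition a [thermo_condition()].
#' @param noise a [noise_model()].
#' @param duplex_dg formation dG of the reference duplex YZ (kcal mol^-1).
#' @param cz_offset CZ destabilisation offset (kcal mol^-1); `Inf` omits CZ.
#' @param catalyst_fraction catalyst amount in x units (default 0.1).
#' @param yield_ratio dsDNA/ssDNA fluorophore quantum-yield ratio.
#' @param rates a [rate_model()] for the uncatalysed lanes.
#' @param incubation_seconds uncatalysed reaction time (default 3 h).
#' @param total_1x the 1x reference concentration in M.
#' @param fluorophore,motif_id labels recorded in the experiment.
#' @return A [gel_experiment()] whose `truth` field records every
#'   generating parameter (including the seed).
#' @export
generate_gel_experiment <- function(truth_dg,
                                    condition = thermo_condition(25, "TE 12.5 mM Mg2+"),
                                    noise = noise_model(),
                                    duplex_dg = -30,
                                    cz_offset = Inf,
                                    catalyst_fraction = 0.1,
                                    yield_ratio = 0.8,
                                    rates = rate_model(),
                                    incubation_seconds = 3 * 3600,
                                    total_1x = 300e-9,
                                    fluorophore = "ROX",
                                    motif_id = "motif") {
  stopifnot(is.finite(truth_dg), inherits(noise, "noise_model"))
  dgxz <- duplex_dg + truth_dg
  dgyz <- duplex_dg
  has_cz <- is.finite(cz_offset) && catalyst_fraction > 0
  dgcz <- if (has_cz) max(dgxz, dgyz) + cz_offset else NA_real_

  with_noise_seed(noise, {
    perturb <- function(x) {
      pmax(x * (1 + stats::rnorm(length(x), 0, noise$stoichiometry_sd)), 0)
    }
    # physical equilibrium / endpoint concentrations (x units) of X and XZ
    # for a lane, given the actual strand totals mixed into it
    lane_physics <- function(role, actual) {
      if (role == "control_XZ") {
        # annealed calibration standard: quantitatively duplexed
        c(X = 0, XZ = actual[["XZ"]])
      } else if (role == "control_X") {
        c(X = actual[["X"]], XZ = 0)
      } else if (role == "uncatalysed") {
        net <- species_network(c(XZ = dgxz, YZ = dgyz),
                               c(X = 1, Y = 1, Z = 1) * total_1x, condition)
        init <- c(X = actual[["X"]], Y = actual[["Y"]],
                  XZ = actual[["XZ"]], YZ = actual[["YZ"]]) * total_1x
        tr <- simulate_timecourse(net, rates, init,
                                  t_grid = c(0, incubation_seconds))
        last <- tr[nrow(tr), ]
        c(X = last$X, XZ = last$XZ) / total_1x
      } else {  # catalysed
        xt <- actual[["X"]] + actual[["XZ"]]
        yt <- actual[["Y"]] + actual[["YZ"]]
        zt <- actual[["XZ"]] + actual[["YZ"]]
        ct <- actual[["C"]]
        cdg <- c(XZ = dgxz, YZ = dgyz)
        totals <- c(X = xt, Y = yt, Z = zt) * total_1x
        if (has_cz) {
          cdg <- c(cdg, CZ = dgcz)
          totals <- c(totals, C = ct * total_1x)
        }
        st <- solve_equilibrium(species_network(cdg, totals, condition))$concentrations
        c(X = st[["X"]], XZ = st[["XZ"]]) / total_1x
      }
    }
    make_lane <- function(lane_id, role, nominal) {
      actual <- perturb(nominal)
      names(actual) <- names(nominal)
      conc <- lane_physics(role, actual)
      loading <- exp(stats::rnorm(1, 0, noise$lane_loading_sd))
      band_noise <- 1 + stats::rnorm(2, 0, noise$band_quant_cv)
      bands <- c(X = 100 * loading * conc[["X"]] * band_noise[1L],
                 XZ = 100 * yield_ratio * loading * conc[["XZ"]] * band_noise[2L])
      gel_lane(lane_id, role, initials = nominal, bands = pmax(bands, 0))
    }
    cf <- catalyst_fraction
    lanes <- list(
      make_lane("1", "control_XZ", c(X = 0, Y = 0, XZ = 1, YZ = 0)),
      make_lane("2", "control_X", c(X = 1, Y = 0, XZ = 0, YZ = 0)),
      make_lane("3", "uncatalysed", c(X = 0, Y = 1, XZ = 1, YZ = 0)),
      make_lane("4", "uncatalysed", c(X = 1, Y = 0, XZ = 0, YZ = 1)),
      make_lane("5", "catalysed", c(X = 0, Y = 1, XZ = 1, YZ = 0, C = cf)),
      make_lane("6", "catalysed", c(X = 1, Y = 0, XZ = 0, YZ = 1, C = cf))
    )
    truth <- list(truth_dg = truth_dg, duplex_dg = duplex_dg,
                  dg_xz = dgxz, dg_yz = dgyz, dg_cz = dgcz,
                  cz_offset = cz_offset, catalyst_fraction = catalyst_fraction,
                  yield_ratio = yield_ratio, total_1x_M = total_1x,
                  incubation_seconds = incubation_seconds,
                  lane_loading_sd = noise$lane_loading_sd,
                  band_quant_cv = noise$band_quant_cv,
                  stoichiometry_sd = noise$stoichiometry_sd,
                  seed = noise$seed %||% NA_real_)
    gel_experiment(lanes, condition, fluorophore = fluorophore,
                   motif_id = motif_id, truth = truth)
  })
}

#' Reaction free energy recovered from one synthetic (or real) gel
#'
#' Convenience wrapper: runs [lane_delta_g()] on every catalysed lane and
#' aggregates. With two catalysed lanes this mirrors the two per-gel
#' direction setups.
#'
#' @param exp a [gel_experiment()].
#' @return A [dg_estimate()] (aggregated over the catalysed lanes).
#' @export
gel_delta_g <- function(exp) {
  roles <- vapply(exp$lanes, `[[`, character(1), "role")
  cat_lanes <- exp$lanes[roles == "catalysed"]
  if (!length(cat_lanes)) stop("experiment has no catalysed lanes")
  ests <- lapply(cat_lanes, lane_delta_g, exp = exp)
  aggregate_estimates(ests, label = paste0(exp$motif_id, "/", exp$fluorophore))
}

#' Generate a two-state melt curve with linear baselines
#'
#' The duplex fraction theta(T) follows the bimolecular two-state model
#' with equal strand totals (`Keq(T) = exp(-(dH - T dS)/RT)` in M^-1,
#' theta the physical root of `Keq c (1-theta)^2 = theta`), and the
#' fluorescence is `lower(T) + theta (upper(T) - lower(T))` plus additive
#' Gaussian noise scaled by the mean plateau span. The default grid mirrors
#' a melt ramp from 95 to 30 degrees C in 1-degree steps.
#'
#' @param dH,dS duplex formation enthalpy (kcal mol^-1) and entropy
#'   (kcal mol^-1 K^-1).
#' @param strand_total per-strand total in M.
#' @param temperatures temperature grid in degrees C.
#' @param upper,lower baselines as `c(intercept, slope)` in fluorescence
#'   units.
#' @param noise a [noise_model()] (only `melt_fluor_sd` and `seed` used).
#' @param label curve label.
#' @return A [melt_curve()] with full truth metadata.
#' @export
generate_melt_curve <- function(dH, dS, strand_total = 300e-9,
                                temperatures = seq(95, 30, by = -1),
                                upper = c(intercept = 110, slope = -0.2),
                                lower = c(intercept = 25, slope = -0.05),
                                noise = noise_model(), label = "XZ") {
  stopifnot(is.finite(dH), is.finite(dS), inherits(noise, "noise_model"))
  tk <- temperatures + 273.15
  keq <- exp(-(dH - tk * dS) / (R_KCAL * tk))
  theta <- two_state_theta(keq, strand_total)
  up <- upper[[1L]] + upper[[2L]] * temperatures
  lo <- lower[[1L]] + lower[[2L]] * temperatures
  span <- mean(up - lo)
  fl <- with_noise_seed(noise, {
    lo + theta * (up - lo) +
      stats::rnorm(length(temperatures), 0, noise$melt_fluor_sd * span)
  })
  melt_curve(temperatures, fl, strand_total, label = label,
             truth = list(dH = dH, dS = dS, strand_total = strand_total,
                          upper = upper, lower = lower,
                          melt_fluor_sd = noise$melt_fluor_sd,
                          seed = noise$seed %||% NA_real_))
}

# Physical root of Keq * c * (1 - theta)^2 = theta for equal strand totals.
two_state_theta <- function(keq, strand_total) {
  kc <- keq * strand_total
  ifelse(kc < 1e-12, kc,
         (2 * kc + 1 - sqrt(4 * kc + 1)) / (2 * kc))
}

#' Closed-form two-state melting temperature
#'
#' Temperature at which theta = 0.5 for the bimolecular equal-totals
#' convention: `Tm = dH / (dS - R log(2 / c))` (Kelvin), returned in
#' degrees C.
#'
#' @inheritParams generate_melt_curve
#' @return Tm in degrees C.
#' @export
two_state_tm <- function(dH, dS, strand_total) {
  dH / (dS - R_KCAL * log(2 / strand_total)) - 273.15
}

#' Generate a dangle-length dG series from the saturating model
#'
#' `dG(L) = base_dg + length_correction(L) + N(0, per_point_sd)` per
#' replicate; replicates are aggregated per length via
#' [aggregate_estimates()] when `n_rep > 1` (the recorded `sd` is then the
#' sample s.d. of the mean; with a single replicate the nominal
#' `per_point_sd` is recorded).
#'
#' @param model a [dangle_length_model()] providing A and lambda.
#' @param base_dg dG of the single-nucleotide dangle reference.
#' @param lengths dangle lengths (subset of 1..21 by convention).
#' @param per_point_sd Gaussian noise per replicate, kcal mol^-1.
#' @param n_rep replicates per length.
#' @param seed integer seed.
#' @return data.frame with columns `L`, `dg`, `sd`, `n`, plus truth
#'   metadata in attribute `"truth"`.
#' @export
generate_dangle_series <- function(model = dangle_length_model(A = 0.56, lambda = 2),
                                   base_dg = -0.3, lengths = 1:21,
                                   per_point_sd = 0.07, n_rep = 1L,
                                   seed = NULL) {
  stopifnot(inherits(model, "dangle_length_model"), per_point_sd >= 0,
            n_rep >= 1L)
  if (any(lengths < 1) || any(lengths > 21)) {
    stop("'lengths' must lie within 1..21")
  }
  cond <- thermo_condition(25)
  run <- function() {
    rows <- lapply(lengths, function(L) {
      truth <- base_dg + length_correction(L, model)
      vals <- truth + stats::rnorm(n_rep, 0, per_point_sd)
      if (n_rep > 1L) {
        agg <- aggregate_estimates(lapply(vals, dg_estimate, sd = NA_real_,
                                          n_measurements = 1L,
                                          condition = cond,
                                          label = paste0("L", L)))
        data.frame(L = L, dg = agg$value, sd = agg$sd, n = n_rep)
      } else {
        data.frame(L = L, dg = vals, sd = per_point_sd, n = 1L)
      }
    })
    do.call(rbind, rows)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "truth") <- list(A = model$A, lambda = model$lambda,
                             base_dg = base_dg, per_point_sd = per_point_sd,
                             n_rep = n_rep, seed = seed %||% NA_real_)
  out
}
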