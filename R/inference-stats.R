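# Statistical layer: two-reaction subtraction, inverse-variance consensus
# with consensus score, Gaussian expectation of score failures, and the
# z-score-weighted van't Hoff fit.

#' Subtract the fluorophore reaction from the fluorophore-plus-dangle reaction
#'
#' The dangle is characterised indirectly: reaction 2 queries fluorophore +
#' dangle, reaction 1 queries the fluorophore alone, and the difference
#' isolates the dangle. Errors are independent, so variance is additive;
#' the systematic catalyst-intermediate bias common to both reactions
#' cancels in the subtraction.
#'
#' @param rxn2 [dg_estimate()] of the fluorophore + motif reaction.
#' @param rxn1 [dg_estimate()] of the fluorophore-only reaction.
#' @param label provenance label for the difference.
#' @return A [dg_estimate()] with `value = rxn2 - rxn1` and
#'   `sd = sqrt(sd1^2 + sd2^2)`.
#' @export
subtract_fluorophore <- function(rxn2, rxn1, label = NULL) {
  stopifnot(inherits(rxn2, "dg_estimate"), inherits(rxn1, "dg_estimate"))
  if (!same_condition(rxn2$condition, rxn1$condition)) {
    stop("cannot subtract estimates from different conditions (",
         rxn2$condition$temperature_celsius, " C ", rxn2$condition$buffer,
         " vs ", rxn1$condition$temperature_celsius, " C ",
         rxn1$condition$buffer, ")")
  }
  sd <- if (is.na(rxn1$sd) || is.na(rxn2$sd)) NA_real_ else
    sqrt(rxn1$sd^2 + rxn2$sd^2)
  dg_estimate(rxn2$value - rxn1$value, sd = sd,
              n_measurements = min(rxn1$n_measurements, rxn2$n_measurements),
              condition = rxn2$condition,
              label = label %||% paste0(rxn2$label, " - ", rxn1$label))
}

#' Inverse-variance consensus of independent dG measurements, with score
#'
#' The consensus is the maximum-likelihood value minimising the sum of
#' squared z scores, i.e. the inverse-variance weighted mean, with
#' `sd = (sum 1/sigma_i^2)^(-1/2)`. The consensus score is
#' `CS = 10 - sum z_i^2`; for two measurements this reduces to
#' `10 - (mu1 - mu2)^2 / (sigma1^2 + sigma2^2)`. CS = 10 means perfect
#' agreement; CS >= 8 means the consensus lies within 1 s.d. of both
#' inputs; CS >= 0 within ~2.24 s.d. The definition extends unchanged to
#' k > 2 measurements.
#'
#' @param ... two or more [dg_estimate()] objects (or a single list of
#'   them), each with a strictly positive `sd`, sharing one condition.
#' @return Object of class `consensus_result`: list with `consensus` (a
#'   [dg_estimate()]), `cs`, and `z` (per-input z scores about the
#'   consensus).
#' @examples
#' cond <- thermo_condition(25)
#' a <- dg_estimate(-0.30, 0.05, 10, cond, "ROX")
#' b <- dg_estimate(-0.20, 0.05, 10, cond, "Alexa532")
#' consensus_and_cs(a, b)
#' @export
consensus_and_cs <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && !inherits(inputs[[1L]], "dg_estimate")) {
    inputs <- inputs[[1L]]
  }
  if (length(inputs) < 2L) stop("consensus needs at least two estimates")
  ok <- vapply(inputs, inherits, logical(1), "dg_estimate")
  if (!all(ok)) stop("all inputs must be dg_estimate objects")
  sds <- vapply(inputs, `[[`, numeric(1), "sd")
  if (any(is.na(sds)) || any(sds <= 0)) {
    stop("every input needs a strictly positive sd (z scores are ",
         "undefined at sd = 0)")
  }
  cond <- inputs[[1L]]$condition
  if (!all(vapply(inputs, function(e) same_condition(e$condition, cond),
                  logical(1)))) {
    stop("estimates measured under different conditions cannot form a consensus")
  }
  vals <- vapply(inputs, `[[`, numeric(1), "value")
  w <- 1 / sds^2
  mu <- sum(w * vals) / sum(w)
  z <- (vals - mu) / sds
  names(z) <- vapply(inputs, `[[`, character(1), "label")
  consensus <- dg_estimate(mu, sd = 1 / sqrt(sum(w)),
                           n_measurements = sum(vapply(inputs, `[[`,
                                                       integer(1),
                                                       "n_measurements")),
                           condition = cond, label = "consensus")
  structure(list(consensus = consensus, cs = 10 - sum(z^2), z = z),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> dG = %.4f (sd %.4f) kcal/mol, CS = %.2f\n",
              x$consensus$value, x$consensus$sd, x$cs))
  invisible(x)
}

#' Expected number of low consensus scores under Gaussian errors
#'
#' Under the Gaussian error model, a measurement pair fails `CS <=
#' cs_threshold` when each measurement sits `z* = sqrt((10 -
#' cs_threshold)/2)` standard deviations from the consensus. Treating that
#' per-measurement z score as standard normal, the expected failure count
#' among `n_params` parameters is `n_params * 2 * (1 - Phi(z*))` — e.g. ~4
#' of 160 (2.5%) at threshold 0. See [simulate_cs_fraction()] for the
#' matching Monte Carlo and the vignette for the approximation involved.
#'
#' @param n_params number of parameters (pairs), >= 1.
#' @param cs_threshold score threshold, <= 10 (default 0).
#' @return Expected count of parameters with CS <= `cs_threshold`.
#' @examples
#' expected_cs_failures(160, 0)  # ~4.06
#' @export
expected_cs_failures <- function(n_params, cs_threshold = 0) {
  if (!is.numeric(n_params) || n_params < 1) stop("'n_params' must be >= 1")
  if (cs_threshold > 10) stop("'cs_threshold' cannot exceed the maximum score 10")
  z_star <- sqrt((10 - cs_threshold) / 2)
  n_params * 2 * stats::pnorm(z_star, lower.tail = FALSE)
}

#' Monte Carlo fraction of low consensus scores
#'
#' Samples measurement pairs from the error model underlying
#' [expected_cs_failures()]: each pair is displaced symmetrically about its
#' consensus by `±z * sigma` with `z ~ N(0,1)` (the per-measurement z score
#' about the consensus is standard normal), and the CS of each pair is
#' computed through [consensus_and_cs()]. The fraction with
#' `CS <= cs_threshold` estimates the analytic tail; at threshold 0 it
#' reproduces ~2.5%.
#'
#' @param n_pairs number of simulated pairs (default 10000).
#' @param sigma reported per-measurement sd (kcal mol^-1); the fraction is
#'   invariant to it.
#' @param cs_threshold score threshold (default 0).
#' @param seed integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @return Fraction of pairs with CS at or below the threshold.
#' @export
simulate_cs_fraction <- function(n_pairs = 10000L, sigma = 0.05,
                                 cs_threshold = 0, seed = 1L) {
  stopifnot(n_pairs >= 1, sigma > 0)
  cond <- thermo_condition(25)
  frac <- withr::with_seed(seed, {
    z <- stats::rnorm(n_pairs)
    cs <- vapply(z, function(zi) {
      a <- dg_estimate(zi * sigma, sigma, 1L, cond, "a")
      b <- dg_estimate(-zi * sigma, sigma, 1L, cond, "b")
      consensus_and_cs(a, b)$cs
    }, numeric(1))
    mean(cs <= cs_threshold)
  })
  frac
}

#' Precision comparison between two measurement techniques
#'
#' Given the parameter s.d. of a reference technique and of a candidate,
#' returns the s.d. ratio and its square — the factor by which the
#' experiment count of the noisier technique must grow to reach the same
#' s.d. of the mean.
#'
#' @param sd_reference parameter s.d. of the noisier technique.
#' @param sd_candidate parameter s.d. of the more precise technique.
#' @return List with `ratio` and `experiment_multiplier` (= ratio^2).
#' @examples
#' precision_comparison(0.54, 0.038)  # ~14-fold, ~196-fold
#' @export
precision_comparison <- function(sd_reference, sd_candidate) {
  stopifnot(sd_reference > 0, sd_candidate > 0)
  r <- sd_reference / sd_candidate
  list(ratio = r, experiment_multiplier = r^2)
}

#' Weighted van't Hoff fit of dH and dS from dG measurements
#'
#' Fits the temperature-invariant model `dG(T) = dH - T dS` to mean dG
#' values measured at two or more temperatures, minimising the sum of
#' squared z scores `((dH - T_i dS - mu_i)/sigma_i)^2` — weighted linear
#' least squares in the design `(1, -T)`, solved in closed form via the
#' normal equations. Parameter s.d.'s come from the inverse normal matrix
#' (measurement sigmas taken as known). The weighted residual sum of
#' squares is reported as `sum_sq_z`; no goodness-of-fit p-value is
#' attached — fits of real motif data are often poor, possibly reflecting
#' temperature-dependent dH/dS, and interpretation is left to the user.
#'
#' @param estimates list of [dg_estimate()] objects at >= 2 distinct
#'   temperatures, each with strictly positive sd.
#' @return An [enthalpy_entropy_fit()] (dS in kcal mol^-1 K^-1).
#' @export
vant_hoff_fit <- function(estimates) {
  if (!length(estimates) ||
      !all(vapply(estimates, inherits, logical(1), "dg_estimate"))) {
    stop("'estimates' must be a list of dg_estimate objects")
  }
  tk <- vapply(estimates, function(e) e$condition$kelvin, numeric(1))
  y <- vapply(estimates, `[[`, numeric(1), "value")
  s <- vapply(estimates, `[[`, numeric(1), "sd")
  if (any(is.na(s)) || any(s <= 0)) {
    stop("every estimate needs a strictly positive sd")
  }
  if (length(unique(round(tk, 9))) < 2L) {
    stop("van't Hoff fit needs >= 2 distinct temperatures")
  }
  X <- cbind(dH = 1, dS = -tk)
  w <- 1 / s^2
  xtwx <- crossprod(X, X * w)
  beta <- solve(xtwx, crossprod(X, y * w))
  covm <- solve(xtwx)
  resid_z <- (y - as.vector(X %*% beta)) / s
  enthalpy_entropy_fit(dH = beta[["dH", 1]], dS = beta[["dS", 1]],
                       dH_sd = sqrt(covm["dH", "dH"]),
                       dS_sd = sqrt(covm["dS", "dS"]),
                       sum_sq_z = sum(resid_z^2))
}
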