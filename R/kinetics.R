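# Mass-action kinetics of the exchange network: why equilibration needs
# the catalyst. Direct strand exchange is ~1 M^-1 s^-1 (half-life ~100 days
# at 100 nM); the toehold-mediated catalytic pathway is ~3e5 M^-1 s^-1.

#' Rate model for the exchange network
#'
#' Forward rate constants for the elementary (coarse-grained) steps; every
#' reverse rate is set by detailed balance from the formation free energies,
#' so the kinetics are thermodynamically consistent with
#' [solve_equilibrium()] by construction.
#'
#' The catalysed pathway is coarse-grained to second-order toehold binding
#' followed by fast displacement: once a catalyst (or invader) binds a
#' toehold, branch migration and dissociation (first-order, `k_branch`,
#' ~1 s^-1) are much faster than the bimolecular encounter at sub-uM
#' concentrations, so each exchange step is rate-limited by `k_toehold_on`
#' and `k_branch` does not appear in the coarse-grained rate law.
#'
#' @param k_uncat direct (uncatalysed) strand exchange rate, M^-1 s^-1.
#' @param k_toehold_on toehold-mediated binding rate used for the catalytic
#'   exchange steps and for strand hybridization, M^-1 s^-1.
#' @param k_branch first-order displacement rate once bound, s^-1 (kept for
#'   reporting; see Details).
#' @return Object of class `rate_model`.
#' @export
rate_model <- function(k_uncat = 1, k_toehold_on = 3e5, k_branch = 1) {
  vals <- c(k_uncat = k_uncat, k_toehold_on = k_toehold_on,
            k_branch = k_branch)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all rate constants must be finite and >= 0")
  }
  structure(as.list(vals), class = "rate_model")
}

# Build the elementary reaction list for a network: hybridization of every
# two-strand complex, the direct exchange, and the two catalytic steps when
# a CZ intermediate is declared. Reverse rates follow detailed balance.
build_reactions <- function(net, rates) {
  RT <- net$condition$RT
  dg <- net$complex_dg
  comp <- net$composition
  if (any(rowSums(comp) > 2)) {
    stop("kinetic model covers two-strand complexes only; remove ",
         paste(rownames(comp)[rowSums(comp) > 2], collapse = ", "))
  }
  rxns <- list()
  add <- function(react, prod, kf, dg_step) {
    kr <- if (kf == 0) 0 else kf * exp(dg_step / RT)  # kf/kr = exp(-dG/RT)
    rxns[[length(rxns) + 1L]] <<- list(react = react, prod = prod,
                                       kf = kf, kr = kr)
  }
  # hybridization A + B <-> AB for every declared duplex
  for (cx in rownames(comp)) {
    parts <- rep(colnames(comp), comp[cx, ])
    add(parts, cx, rates$k_toehold_on, dg[[cx]])
  }
  has <- function(s) s %in% rownames(comp)
  if (has("XZ") && has("YZ")) {
    add(c("X", "YZ"), c("Y", "XZ"), rates$k_uncat, dg[["XZ"]] - dg[["YZ"]])
  }
  if (has("CZ") && has("YZ")) {
    add(c("C", "YZ"), c("Y", "CZ"), rates$k_toehold_on, dg[["CZ"]] - dg[["YZ"]])
  }
  if (has("CZ") && has("XZ")) {
    add(c("X", "CZ"), c("C", "XZ"), rates$k_toehold_on, dg[["XZ"]] - dg[["CZ"]])
  }
  rxns
}

#' Simulate the mass-action time course of the exchange network
#'
#' Integrates the coupled ODEs of the network's elementary steps with a
#' stiff implicit integrator ([deSolve::ode()], `lsoda`). Trajectories are
#' non-negative, conserve per-strand totals, and converge to the
#' [solve_equilibrium()] state as t grows.
#'
#' @param net a [species_network()] (totals are ignored; the initial state
#'   sets the totals).
#' @param rates a [rate_model()].
#' @param initials named vector of initial concentrations in M over free
#'   strands and complexes; unnamed species start at 0.
#' @param t_grid increasing vector of output times in seconds.
#' @param rtol,atol integrator tolerances (defaults 1e-8 and 1e-12 x 300 nM).
#' @return A data.frame: `time` plus one column per species, in M.
#' @export
simulate_timecourse <- function(net, rates, initials, t_grid,
                                rtol = 1e-8, atol = 1e-12 * 300e-9) {
  stopifnot(inherits(net, "species_network"), inherits(rates, "rate_model"))
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("'t_grid' must be strictly increasing")
  }
  species <- c(names(net$totals), rownames(net$composition))
  y0 <- stats::setNames(numeric(length(species)), species)
  if (length(initials)) {
    if (is.null(names(initials)) || !all(names(initials) %in% species)) {
      stop("'initials' must be named by declared species")
    }
    if (any(initials < 0)) stop("initial concentrations must be >= 0")
    y0[names(initials)] <- initials
  }
  rxns <- build_reactions(net, rates)
  # stoichiometry matrix: species x reactions
  S <- matrix(0, length(species), length(rxns),
              dimnames = list(species, NULL))
  for (j in seq_along(rxns)) {
    for (s in rxns[[j]]$react) S[s, j] <- S[s, j] - 1
    for (s in rxns[[j]]$prod) S[s, j] <- S[s, j] + 1
  }
  kf <- vapply(rxns, `[[`, numeric(1), "kf")
  kr <- vapply(rxns, `[[`, numeric(1), "kr")
  react_idx <- lapply(rxns, function(r) match(r$react, species))
  prod_idx <- lapply(rxns, function(r) match(r$prod, species))
  derivs <- function(t, y, parms) {
    v <- vapply(seq_along(rxns), function(j) {
      kf[j] * prod(y[react_idx[[j]]]) - kr[j] * prod(y[prod_idx[[j]]])
    }, numeric(1))
    list(as.vector(S %*% v))
  }
  sol <- deSolve::ode(y = y0, times = t_grid, func = derivs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    stop("stiff integration failed; consider loosening rtol/atol ",
         "(current rtol = ", rtol, ", atol = ", atol, ")")
  }
  out <- as.data.frame(sol)
  names(out)[1L] <- "time"
  out
}

#' Equal-concentration second-order half-life
#'
#' For A + B -> products with `[A]0 = [B]0 = c0`, the half-life is
#' `1 / (k c0)`. At the literature direct-exchange rate of ~1 M^-1 s^-1 and
#' 100 nM this is 1e7 s (~116 days), which is why uncatalysed equilibration
#' is impractical.
#'
#' @param k second-order rate constant, M^-1 s^-1; must be > 0.
#' @param c0 initial concentration, M; must be > 0.
#' @return Half-life in seconds.
#' @examples
#' second_order_half_life(1, 100e-9) / 86400  # ~115.7 days
#' @export
second_order_half_life <- function(k, c0) {
  if (!is.numeric(k) || any(k <= 0) || any(!is.finite(k))) {
    stop("'k' must be finite and > 0")
  }
  if (!is.numeric(c0) || any(c0 <= 0) || any(!is.finite(c0))) {
    stop("'c0' must be finite and > 0")
  }
  1 / (k * c0)
}
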