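# Coupled mass-action equilibrium for the strand-exchange network
# X + YZ <-> Y + XZ with optional catalyst intermediates.

#' Define a strand/complex network with formation free energies
#'
#' Species are single strands (one-letter ids, typically X, Y, Z and the
#' catalyst C) and declared complexes whose composition is spelled by their
#' name (e.g. `"XZ"` is one X plus one Z, `"CXZ"` a three-strand complex).
#' Each complex carries a standard free energy of formation from its free
#' strands (kcal mol^-1, 1 M standard state). Activity coefficients are 1
#' (ideal dilute solution; the working regime is ~300 nM).
#'
#' @param complex_dg named numeric vector of formation dGs; names spell
#'   compositions from the strand letters, e.g.
#'   `c(XZ = -15.2, YZ = -15.0, CZ = -14.0)`.
#' @param totals named numeric vector of total strand concentrations in M,
#'   e.g. `c(X = 3e-7, Y = 3e-7, Z = 3e-7, C = 3e-8)`. Strands with zero
#'   total are allowed (their complexes are dropped from the solve).
#' @param condition a [thermo_condition()].
#' @return Object of class `species_network`.
#' @examples
#' net <- species_network(c(XZ = -15, YZ = -15),
#'                        c(X = 3e-7, Y = 3e-7, Z = 3e-7),
#'                        thermo_condition(25))
#' @export
species_network <- function(complex_dg, totals, condition) {
  if (!is_thermo_condition(condition)) stop("'condition' must be a thermo_condition")
  if (is.null(names(complex_dg)) || any(!nzchar(names(complex_dg)))) {
    stop("'complex_dg' must be a named vector; names spell compositions")
  }
  if (is.null(names(totals)) || any(nchar(names(totals)) != 1L)) {
    stop("'totals' must be named by one-letter strand ids")
  }
  if (any(!is.finite(totals)) || any(totals < 0)) {
    stop("strand totals must be finite and >= 0")
  }
  if (any(!is.finite(complex_dg))) stop("complex formation dGs must be finite")
  strands <- names(totals)
  comp <- t(vapply(strsplit(names(complex_dg), ""), function(parts) {
    if (!all(parts %in% strands)) {
      stop("complex '", paste(parts, collapse = ""),
           "' uses undeclared strands: ",
           paste(setdiff(parts, strands), collapse = ", "))
    }
    vapply(strands, function(s) sum(parts == s), numeric(1))
  }, numeric(length(strands))))
  dimnames(comp) <- list(names(complex_dg), strands)
  structure(
    list(complex_dg = complex_dg, totals = totals, composition = comp,
         condition = condition),
    class = "species_network"
  )
}

#' @export
print.species_network <- function(x, ...) {
  cat("<species_network>\n  strands (total M): ",
      paste(sprintf("%s=%.3g", names(x$totals), x$totals), collapse = ", "),
      "\n  complexes (dG kcal/mol): ",
      paste(sprintf("%s=%.3g", names(x$complex_dg), x$complex_dg),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Solve the coupled dilute-solution equilibrium of a network
#'
#' Finds the unique composition minimising the ideal-dilute Gibbs free
#' energy subject to per-strand mass balance. The solve is a damped Newton
#' iteration on the mass-balance residuals in log free-strand-concentration
#' coordinates (the stationarity conditions of the strictly convex free
#' energy), with a line search on the squared relative residual.
#'
#' @param net a [species_network()].
#' @param tol convergence tolerance on the largest relative mass-balance
#'   residual (default 1e-12).
#' @param max_iter maximum Newton iterations (default 200).
#' @return Object of class `equilibrium_state`: list with `concentrations`
#'   (named vector, M, free strands then complexes) and `condition`.
#' @export
solve_equilibrium <- function(net, tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(net, "species_network"))
  totals <- net$totals
  if (any(totals < 0)) stop("negative strand totals rejected")
  strands <- names(totals)
  cx_names <- rownames(net$composition)
  conc <- stats::setNames(numeric(length(strands) + length(cx_names)),
                          c(strands, cx_names))
  active <- totals > 0
  if (!any(active)) {
    return(structure(list(concentrations = conc, condition = net$condition),
                     class = "equilibrium_state"))
  }
  # complexes involving only active strands participate; the rest stay 0
  inactive_cols <- net$composition[, !active, drop = FALSE]
  keep <- rowSums(inactive_cols) == 0
  A <- net$composition[keep, active, drop = FALSE]
  K <- exp(-net$complex_dg[keep] / net$condition$RT)
  tot <- totals[active]
  ns <- length(tot)

  mu <- log(tot / 2)
  eval_resid <- function(mu) {
    free <- exp(mu)
    cc <- if (nrow(A)) K * exp(as.vector(A %*% mu)) else numeric(0)
    bound <- if (nrow(A)) as.vector(t(A) %*% cc) else 0
    list(free = free, cc = cc, resid = free + bound - tot)
  }
  # damped multiplicative pre-phase: globally stable, brings strongly bound
  # systems (K ~ 1e20 M^-1) into the Newton basin
  for (it in seq_len(400L)) {
    st <- eval_resid(mu)
    if (max(abs(st$resid) / tot) < 1e-4) break
    supply <- st$resid + tot   # free + bound
    mu <- mu + 0.5 * (log(tot) - log(supply))
  }
  st <- eval_resid(mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rel <- max(abs(st$resid) / tot)
    if (rel < tol) { converged <- TRUE; break }
    J <- diag(st$free, ns)
    if (nrow(A)) J <- J + t(A) %*% (A * st$cc)
    step <- tryCatch(solve(J, -st$resid), error = function(e) {
      ridge <- diag(1e-10 * max(abs(J)), ns)
      tryCatch(solve(J + ridge, -st$resid),
               error = function(e2) stop("equilibrium Newton step failed ",
                                         "(singular Jacobian): ",
                                         conditionMessage(e2)))
    })
    m <- max(abs(step))
    if (m > 4) step <- step * (4 / m)   # damp large log-steps
    f0 <- sum((st$resid / tot)^2)
    alpha <- 1
    for (ls in 1:50) {
      cand <- eval_resid(mu + alpha * step)
      if (sum((cand$resid / tot)^2) < f0) break
      alpha <- alpha / 2
    }
    mu <- mu + alpha * step
    st <- cand
  }
  if (!converged) {
    rel <- max(abs(st$resid) / tot)
    stop(sprintf(paste0("equilibrium solve did not reach relative mass-balance ",
                        "tolerance %g within %d iterations (residual %g)"),
                 tol, max_iter, rel))
  }
  conc[names(tot)] <- st$free
  if (nrow(A)) conc[rownames(A)] <- st$cc
  structure(list(concentrations = conc, condition = net$condition),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("<equilibrium_state> (M)\n")
  print(signif(x$concentrations, 6))
  invisible(x)
}

#' Reaction quotient of the strand exchange X + YZ <-> Y + XZ
#'
#' @param state an `equilibrium_state` (or any named vector of
#'   concentrations containing X, Y, XZ, YZ).
#' @return Dimensionless `([Y][XZ]) / ([X][YZ])`.
#' @export
exchange_quotient <- function(state) {
  conc <- if (inherits(state, "equilibrium_state")) state$concentrations else state
  (conc[["Y"]] * conc[["XZ"]]) / (conc[["X"]] * conc[["YZ"]])
}

#' Apparent reaction free energy inferred while ignoring catalyst intermediates
#'
#' Solves the full network (including any CZ/CXZ/CYZ species), then applies
#' the catalyst-blind mass-balance algebra an experimenter uses on a gel
#' lane — [infer_concentrations()] driven by the true equilibrium
#' concentration of the labelled duplex XZ — and converts the resulting
#' apparent equilibrium constant to a dG. Because intermediates sequester Z,
#' the apparent dG systematically overestimates the true reaction dG; the
#' returned `bias` is `apparent - true` and is >= 0.
#'
#' @param net a [species_network()] whose totals describe the lane contents.
#' @param lane_initials named vector (same concentration unit as the network
#'   totals) of the nominal initial concentrations X, Y, XZ, YZ the
#'   experimenter believes were mixed.
#' @return List with `apparent_dg`, `true_dg` (both kcal mol^-1) and `bias`.
#' @export
apparent_delta_g <- function(net, lane_initials) {
  state <- solve_equilibrium(net)
  obs <- state$concentrations[["XZ"]]
  inferred <- infer_concentrations(obs, lane_initials,
                                   observed_species = "XZ",
                                   overshoot_tol = 0.02)
  keq <- (inferred[["Y"]] * inferred[["XZ"]]) /
    (inferred[["X"]] * inferred[["YZ"]])
  apparent <- delta_g_from_keq(keq, net$condition)
  true_dg <- net$complex_dg[["XZ"]] - net$complex_dg[["YZ"]]
  list(apparent_dg = apparent, true_dg = true_dg, bias = apparent - true_dg)
}

#' Scan the catalyst-intermediate bias over motif and CZ stability grids
#'
#' For each combination of true motif dG, CZ stability offset and catalyst
#' fraction, builds the standard measurement lane ([XZ]0 = 1x, [Y]0 = 1x,
#' catalyst at the given fraction of 1x), solves the full equilibrium with
#' the CZ intermediate present, and records the overestimation incurred by
#' the CZ-ignoring inference. The CZ formation dG is placed `cz_offset`
#' kcal mol^-1 above (less stable than) the less stable of the two product
#' duplexes, so `cz_offset >= 1` encodes "at least 1 kcal/mol less stable
#' than either duplex".
#'
#' @param motif_dg numeric grid of true reaction (motif) dGs, kcal mol^-1.
#' @param cz_offset numeric grid of CZ destabilisation offsets, kcal mol^-1.
#' @param catalyst_fraction catalyst totals as fractions of 1x (default 0.1).
#' @param duplex_dg formation dG of the reference duplex YZ (kcal mol^-1).
#' @param total_1x the 1x reference concentration in M (default 300 nM).
#' @param condition a [thermo_condition()].
#' @return A data.frame with one row per grid point (`motif_dg`,
#'   `cz_offset`, `catalyst_fraction`, `apparent_dg`, `true_dg`, `bias`),
#'   with attributes `max_bias` and `argmax` (the maximising row).
#' @export
bias_scan <- function(motif_dg = seq(-2, 2, by = 0.5),
                      cz_offset = c(1, 1.5, 2, 3),
                      catalyst_fraction = 0.1,
                      duplex_dg = -20,
                      total_1x = 300e-9,
                      condition = thermo_condition(25)) {
  if (!length(motif_dg) || !length(cz_offset) || !length(catalyst_fraction)) {
    stop("scan grids must be non-empty")
  }
  grid <- expand.grid(motif_dg = motif_dg, cz_offset = cz_offset,
                      catalyst_fraction = catalyst_fraction,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$motif_dg[i]; off <- grid$cz_offset[i]; cf <- grid$catalyst_fraction[i]
    dgxz <- duplex_dg + m
    dgyz <- duplex_dg
    lane <- c(X = 0, Y = total_1x, XZ = total_1x, YZ = 0)
    if (cf > 0) {
      dgcz <- max(dgxz, dgyz) + off
      net <- species_network(
        c(XZ = dgxz, YZ = dgyz, CZ = dgcz),
        c(X = total_1x, Y = total_1x, Z = total_1x, C = cf * total_1x),
        condition)
    } else {
      net <- species_network(
        c(XZ = dgxz, YZ = dgyz),
        c(X = total_1x, Y = total_1x, Z = total_1x),
        condition)
    }
    out <- apparent_delta_g(net, lane)
    c(apparent_dg = out$apparent_dg, true_dg = out$true_dg, bias = out$bias)
  })
  res <- do.call(rbind, res)
  ans <- cbind(grid, as.data.frame(res))
  imax <- which.max(ans$bias)
  attr(ans, "max_bias") <- ans$bias[imax]
  attr(ans, "argmax") <- ans[imax, , drop = FALSE]
  ans
}
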