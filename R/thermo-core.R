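# Core free-energy algebra: conditions, estimates, dG <-> Keq conversions.

#' Universal gas constant in kcal mol^-1 K^-1
#'
#' CODATA-derived value used for every conversion between standard free
#' energies and equilibrium constants in this package. Energies are always
#' kcal mol^-1 internally; entropies kcal mol^-1 K^-1 (the conventional
#' cal-based entropy unit is handled only at report formatting, see
#' [entropy_kcal_to_cal()]).
#'
#' @export
R_KCAL <- 1.98720425e-3

#' Thermodynamic condition (temperature and buffer)
#'
#' Fixes the thermal scale `RT` used by every dG/Keq conversion. Temperature
#' is given in degrees Celsius at the interface (the natural experimental
#' unit) and converted to Kelvin once.
#'
#' @param temperature_celsius temperature in degrees C; must exceed -273.15.
#' @param buffer free-text buffer label, e.g. `"PBS"` or
#'   `"TE 12.5 mM Mg2+"`. Measurements are native per buffer; the package
#'   never extrapolates a dG across buffers.
#' @return An object of class `thermo_condition` with fields
#'   `temperature_celsius`, `buffer`, `kelvin` and `RT` (kcal mol^-1).
#' @examples
#' cond <- thermo_condition(25, "PBS")
#' cond$RT
#' @export
thermo_condition <- function(temperature_celsius, buffer = "PBS") {
  if (!is.numeric(temperature_celsius) || length(temperature_celsius) != 1L ||
      !is.finite(temperature_celsius)) {
    stop("'temperature_celsius' must be a single finite number, got: ",
         deparse(temperature_celsius))
  }
  if (temperature_celsius <= -273.15) {
    stop("temperature ", temperature_celsius, " C is at or below absolute zero")
  }
  kelvin <- temperature_celsius + 273.15
  structure(
    list(temperature_celsius = temperature_celsius,
         buffer = as.character(buffer)[1L],
         kelvin = kelvin,
         RT = R_KCAL * kelvin),
    class = "thermo_condition"
  )
}

#' @export
print.thermo_condition <- function(x, ...) {
  cat(sprintf("<thermo_condition> %.2f C (%.2f K) in %s; RT = %.6f kcal/mol\n",
              x$temperature_celsius, x$kelvin, x$buffer, x$RT))
  invisible(x)
}

is_thermo_condition <- function(x) inherits(x, "thermo_condition")

# Two conditions are interchangeable when temperature and buffer agree.
same_condition <- function(a, b, tol = 1e-9) {
  abs(a$temperature_celsius - b$temperature_celsius) <= tol &&
    identical(a$buffer, b$buffer)
}

#' A standard free energy estimate with uncertainty and provenance
#'
#' The atomic result of the pipeline: one dG value (kcal mol^-1) with a
#' standard deviation of the mean, the number of underlying independent
#' measurements, the condition it was measured in and a provenance label
#' (motif id, fluorophore or lane id).
#'
#' @param value dG in kcal mol^-1; must be finite.
#' @param sd standard deviation (of the mean) in kcal mol^-1, `NA` when a
#'   single measurement carries no internal spread estimate.
#' @param n_measurements number of independent measurements behind `value`.
#' @param condition a [thermo_condition()].
#' @param label free-text provenance tag.
#' @return An object of class `dg_estimate`.
#' @export
dg_estimate <- function(value, sd = NA_real_, n_measurements = 1L,
                        condition, label = "") {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("dG 'value' must be a single finite number, got: ", deparse(value))
  }
  if (!is.na(sd) && (!is.numeric(sd) || sd < 0)) {
    stop("'sd' must be >= 0 or NA, got: ", deparse(sd))
  }
  n_measurements <- as.integer(n_measurements)
  if (is.na(n_measurements) || n_measurements < 1L) {
    stop("'n_measurements' must be an integer >= 1")
  }
  if (!is_thermo_condition(condition)) stop("'condition' must be a thermo_condition")
  structure(
    list(value = as.numeric(value), sd = as.numeric(sd),
         n_measurements = n_measurements, condition = condition,
         label = as.character(label)[1L]),
    class = "dg_estimate"
  )
}

#' @export
print.dg_estimate <- function(x, ...) {
  sd_txt <- if (is.na(x$sd)) "sd NA" else sprintf("sd %.4f", x$sd)
  cat(sprintf("<dg_estimate> %s: %.4f kcal/mol (%s, n = %d) at %.1f C in %s\n",
              if (nzchar(x$label)) x$label else "dG", x$value, sd_txt,
              x$n_measurements, x$condition$temperature_celsius,
              x$condition$buffer))
  invisible(x)
}

#' Equilibrium constant from a standard free energy
#'
#' `Keq = exp(-dG / RT)`. Strictly positive and strictly decreasing in `dg`.
#'
#' @param dg standard free energy in kcal mol^-1 (vectorised).
#' @param cond a [thermo_condition()].
#' @return Dimensionless equilibrium constant(s).
#' @examples
#' keq_from_delta_g(0, thermo_condition(25))      # 1
#' keq_from_delta_g(-0.22, thermo_condition(25))  # ~1.45
#' @export
keq_from_delta_g <- function(dg, cond) {
  if (!is_thermo_condition(cond)) stop("'cond' must be a thermo_condition")
  if (!is.numeric(dg) || any(!is.finite(dg))) {
    bad <- if (is.numeric(dg)) dg[!is.finite(dg)][1L] else dg
    stop("non-finite dG rejected: ", deparse(bad))
  }
  exp(-dg / cond$RT)
}

#' Standard free energy from an equilibrium constant
#'
#' `dG = -RT log(Keq)`; the exact inverse of [keq_from_delta_g()].
#'
#' @param keq dimensionless equilibrium constant(s), strictly positive.
#' @param cond a [thermo_condition()].
#' @return dG in kcal mol^-1.
#' @export
delta_g_from_keq <- function(keq, cond) {
  if (!is_thermo_condition(cond)) stop("'cond' must be a thermo_condition")
  if (!is.numeric(keq) || any(!is.finite(keq)) || any(keq <= 0)) {
    stop("'keq' must be finite and > 0, got: ",
         deparse(keq[!is.finite(keq) | keq <= 0][1L]))
  }
  -cond$RT * log(keq)
}

#' Enthalpy/entropy pair from a temperature fit
#'
#' Container for a temperature-invariant (dH, dS) description of a motif:
#' `dG(T) = dH - T * dS`. Produced by [vant_hoff_fit()]; can also be built
#' directly. `dS` is stored in kcal mol^-1 K^-1; printing converts to the
#' conventional cal mol^-1 K^-1.
#'
#' @param dH enthalpy, kcal mol^-1.
#' @param dS entropy, kcal mol^-1 K^-1.
#' @param dH_sd,dS_sd parameter standard deviations (may be `NA`).
#' @param sum_sq_z weighted residual sum of squares of the generating fit.
#' @return Object of class `enthalpy_entropy_fit`.
#' @export
enthalpy_entropy_fit <- function(dH, dS, dH_sd = NA_real_, dS_sd = NA_real_,
                                 sum_sq_z = 0) {
  stopifnot(is.finite(dH), is.finite(dS), sum_sq_z >= 0)
  structure(
    list(dH = dH, dS = dS, dH_sd = dH_sd, dS_sd = dS_sd,
         sum_sq_z = sum_sq_z),
    class = "enthalpy_entropy_fit"
  )
}

#' @export
print.enthalpy_entropy_fit <- function(x, ...) {
  cat(sprintf("<enthalpy_entropy_fit> dH = %.4f kcal/mol, dS = %.4f cal/mol/K",
              x$dH, entropy_kcal_to_cal(x$dS)))
  if (!is.na(x$dH_sd)) {
    cat(sprintf(" (sd %.4f, %.4f)", x$dH_sd, entropy_kcal_to_cal(x$dS_sd)))
  }
  cat(sprintf("; sum of squared z = %.4g\n", x$sum_sq_z))
  invisible(x)
}

#' Evaluate dG(T) = dH - T dS for a fitted enthalpy/entropy pair
#'
#' @param fit an [enthalpy_entropy_fit()] (or any list with `dH`, `dS` in
#'   kcal units).
#' @param cond a [thermo_condition()] giving the evaluation temperature.
#' @return dG in kcal mol^-1.
#' @examples
#' fit <- enthalpy_entropy_fit(dH = -0.81, dS = -1.89e-3)
#' delta_g_at_temperature(fit, thermo_condition(25))  # ~ -0.2465
#' @export
delta_g_at_temperature <- function(fit, cond) {
  if (!is_thermo_condition(cond)) stop("'cond' must be a thermo_condition")
  if (is.null(fit$dH) || is.null(fit$dS)) stop("'fit' must carry dH and dS")
  fit$dH - cond$kelvin * fit$dS
}

#' Entropy unit conversions
#'
#' The field reports dS in cal mol^-1 K^-1 while all internal arithmetic is
#' in kcal; these helpers convert at the I/O boundary (lossless).
#'
#' @param x entropy value(s).
#' @return Converted entropy.
#' @export
entropy_cal_to_kcal <- function(x) x / 1000

#' @rdname entropy_cal_to_kcal
#' @export
entropy_kcal_to_cal <- function(x) x * 1000
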