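# High-resolution-melt comparison branch: fluorescence curves -> baselines
# -> hybridization yields -> Keq(T) -> van't Hoff -> motif dG.

#' A temperature-fluorescence melt curve
#'
#' @param temperature_celsius temperature grid in degrees C (>= 20 points;
#'   ascending or descending).
#' @param fluorescence fluorescence readings (arbitrary units), same length.
#' @param strand_total per-strand total concentration in M (equal totals of
#'   the two strands are assumed).
#' @param label duplex label, e.g. `"XZ"` or `"YZ"`.
#' @param truth optional generator ground-truth metadata.
#' @return Object of class `melt_curve`.
#' @export
melt_curve <- function(temperature_celsius, fluorescence, strand_total,
                       label = "XZ", truth = NULL) {
  if (length(temperature_celsius) != length(fluorescence)) {
    stop("temperature and fluorescence must have equal length")
  }
  if (length(temperature_celsius) < 20L) {
    stop("a melt curve needs at least 20 points, got ",
         length(temperature_celsius))
  }
  if (!is.numeric(strand_total) || strand_total <= 0) {
    stop("'strand_total' must be > 0")
  }
  structure(list(temperature_celsius = as.numeric(temperature_celsius),
                 fluorescence = as.numeric(fluorescence),
                 strand_total = strand_total, label = label, truth = truth),
            class = "melt_curve")
}

#' Fit linear upper and lower fluorescence baselines
#'
#' Least-squares lines `a + b T` over the coolest and warmest windows of
#' the curve (default: 15% of the temperature span each). The duplex
#' plateau at low temperature defines the upper baseline (the
#' duplex-reporting dye is brightest when hybridized), the dissociated
#' plateau at high temperature the lower baseline. The two baselines must
#' not cross inside the data range.
#'
#' @param curve a [melt_curve()].
#' @param window fraction of the temperature span used per plateau window
#'   (default 0.15).
#' @return Object of class `melt_baselines`: list with `upper` and `lower`,
#'   each `c(intercept, slope)`.
#' @export
fit_baselines <- function(curve, window = 0.15) {
  stopifnot(inherits(curve, "melt_curve"))
  if (window <= 0 || window >= 0.5) {
    stop("'window' must lie in (0, 0.5); windows may not overlap")
  }
  tc <- curve$temperature_celsius
  fl <- curve$fluorescence
  span <- max(tc) - min(tc)
  cool <- tc <= min(tc) + window * span
  warm <- tc >= max(tc) - window * span
  if (sum(cool) < 2L || sum(warm) < 2L) {
    stop("plateau windows contain fewer than 2 points")
  }
  line_fit <- function(sel) {
    co <- stats::coef(stats::lm(fl[sel] ~ tc[sel]))
    c(intercept = unname(co[1L]), slope = unname(co[2L]))
  }
  upper <- line_fit(cool)
  lower <- line_fit(warm)
  eval_u <- upper[["intercept"]] + upper[["slope"]] * tc
  eval_l <- lower[["intercept"]] + lower[["slope"]] * tc
  if (any(eval_u <= eval_l)) {
    stop("fitted baselines cross inside the data range; the curve does not ",
         "span both plateaus")
  }
  structure(list(upper = upper, lower = lower), class = "melt_baselines")
}

eval_baseline <- function(b, tc) b[["intercept"]] + b[["slope"]] * tc

#' Hybridization yield theta(T) from a melt curve and its baselines
#'
#' `theta(T) = (F(T) - lower(T)) / (upper(T) - lower(T))`, clipped to
#' `[eps, 1 - eps]` with `eps = 1e-4` so downstream logarithms stay finite.
#'
#' @param curve a [melt_curve()].
#' @param baselines a `melt_baselines` object (default: fitted from the
#'   curve).
#' @param eps clipping margin.
#' @return Numeric vector of yields aligned with the curve's temperatures.
#' @export
hybridization_yield <- function(curve, baselines = fit_baselines(curve),
                                eps = 1e-4) {
  stopifnot(inherits(curve, "melt_curve"), inherits(baselines, "melt_baselines"))
  tc <- curve$temperature_celsius
  up <- eval_baseline(baselines$upper, tc)
  lo <- eval_baseline(baselines$lower, tc)
  theta <- (curve$fluorescence - lo) / (up - lo)
  pmin(pmax(theta, eps), 1 - eps)
}

#' Bimolecular association constant from a hybridization yield
#'
#' For a non-self-complementary duplex with equal strand totals `c`, the
#' duplex fraction theta gives `Keq = theta / (c (1 - theta)^2)` (M^-1). In
#' the dilute limit theta -> 0 this reduces to `theta / c`.
#'
#' @param theta hybridization yield(s) strictly inside (0, 1).
#' @param strand_total per-strand total concentration `c` in M.
#' @return Association constant(s) in M^-1.
#' @examples
#' keq_from_yield(0.5, 300e-9)  # ~6.67e6 M^-1
#' @export
keq_from_yield <- function(theta, strand_total) {
  if (any(theta <= 0) || any(theta >= 1)) {
    stop("'theta' must lie strictly inside (0, 1)")
  }
  if (strand_total <= 0) stop("'strand_total' must be > 0")
  theta / (strand_total * (1 - theta)^2)
}

# van't Hoff regression of one curve: OLS of ln K on 1/T over the
# transition region (theta inside theta_range, where yields are not
# baseline-dominated). Returns c(dH, dS) in kcal units.
vant_hoff_from_curve <- function(curve, baselines, theta_range = c(0.15, 0.85)) {
  theta <- hybridization_yield(curve, baselines)
  sel <- theta >= theta_range[1L] & theta <= theta_range[2L]
  if (sum(sel) < 2L) {
    stop("fewer than 2 points fall in the transition region theta in [",
         theta_range[1L], ", ", theta_range[2L], "]")
  }
  tk <- curve$temperature_celsius[sel] + 273.15
  lnk <- log(keq_from_yield(theta[sel], curve$strand_total))
  co <- stats::coef(stats::lm(lnk ~ I(1 / tk)))
  # ln K = -dH/R * (1/T) + dS/R
  c(dH = -unname(co[2L]) * R_KCAL, dS = unname(co[1L]) * R_KCAL)
}

#' Motif free energy from a pair of melt curves
#'
#' The labelled duplex XZ and the unlabelled reference duplex YZ differ
#' only by the motif, so the difference of their van't Hoff lines isolates
#' it: each curve yields `ln K(T)` over its transition region, an
#' unweighted linear fit gives per-duplex (dH, dS), and the differences
#' `dH_XZ - dH_YZ`, `dS_XZ - dS_YZ` evaluate the motif dG at the requested
#' temperature. Replicate pairs can be pooled afterwards with
#' [aggregate_estimates()].
#'
#' @param curve_xz,curve_yz [melt_curve()] objects for the two duplexes.
#' @param cond a [thermo_condition()] giving the reporting temperature.
#' @param baselines_xz,baselines_yz optional pre-computed baselines
#'   (defaults: fitted from each curve).
#' @param theta_range transition window used for the fits.
#' @return A [dg_estimate()] (single pair, so `sd = NA`, n = 1).
#' @export
motif_dg_from_melt_pair <- function(curve_xz, curve_yz, cond,
                                    baselines_xz = NULL, baselines_yz = NULL,
                                    theta_range = c(0.15, 0.85)) {
  if (!is_thermo_condition(cond)) stop("'cond' must be a thermo_condition")
  fx <- vant_hoff_from_curve(curve_xz, baselines_xz %||% fit_baselines(curve_xz),
                             theta_range)
  fy <- vant_hoff_from_curve(curve_yz, baselines_yz %||% fit_baselines(curve_yz),
                             theta_range)
  d_dH <- fx[["dH"]] - fy[["dH"]]
  d_dS <- fx[["dS"]] - fy[["dS"]]
  dg_estimate(d_dH - cond$kelvin * d_dS, sd = NA_real_, n_measurements = 1L,
              condition = cond,
              label = paste0("melt:", curve_xz$label, "-", curve_yz$label))
}

#' Melting temperature from a melt curve
#'
#' Linear interpolation of the temperature at which the hybridization yield
#' crosses 0.5.
#'
#' @param curve a [melt_curve()].
#' @param baselines optional `melt_baselines` (default: fitted).
#' @return Melting temperature in degrees C.
#' @export
melting_temperature <- function(curve, baselines = fit_baselines(curve)) {
  theta <- hybridization_yield(curve, baselines)
  ord <- order(curve$temperature_celsius)
  tc <- curve$temperature_celsius[ord]
  th <- theta[ord]
  d <- th - 0.5
  cross <- which(d[-length(d)] * d[-1L] <= 0 & (d[-length(d)] != d[-1L]))
  if (!length(cross)) stop("hybridization yield never crosses 0.5")
  i <- cross[1L]
  tc[i] + (0.5 - th[i]) * (tc[i + 1L] - tc[i]) / (th[i + 1L] - th[i])
}
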