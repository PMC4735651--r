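# From gel band-intensity tables to per-lane dG estimates: quantum-yield
# calibration, per-lane loading correction, mass-balance inference,
# replicate aggregation.

LANE_ROLES <- c("control_XZ", "control_X", "uncatalysed", "catalysed")

#' A single gel lane
#'
#' @param lane_id lane identifier.
#' @param role one of `"control_XZ"`, `"control_X"`, `"uncatalysed"`,
#'   `"catalysed"`.
#' @param initials named vector of nominal initial concentrations in x units
#'   (1x = 300 nM) over X, Y, XZ, YZ (and C).
#' @param bands named vector of raw band intensities (arbitrary fluorescence
#'   units) for the visible, fluorophore-bearing species X and XZ.
#' @return Object of class `gel_lane`.
#' @export
gel_lane <- function(lane_id, role, initials, bands) {
  role <- match.arg(role, LANE_ROLES)
  if (any(!is.finite(initials)) || any(initials < 0)) {
    stop("lane ", lane_id, ": initial concentrations must be finite and >= 0")
  }
  if (any(!is.finite(bands)) || any(bands < 0)) {
    stop("lane ", lane_id, ": band intensities must be finite and >= 0")
  }
  if (!all(names(bands) %in% c("X", "XZ"))) {
    stop("lane ", lane_id, ": only the labelled species X and XZ carry bands")
  }
  structure(list(lane_id = as.character(lane_id), role = role,
                 initials = initials, bands = bands),
            class = "gel_lane")
}

#' A gel experiment: lanes plus calibration context
#'
#' @param lanes list of [gel_lane()] objects; must include the two control
#'   lanes (`control_XZ` and `control_X`) used to calibrate per-state
#'   fluorophore quantum yields.
#' @param condition a [thermo_condition()].
#' @param fluorophore fluorophore label, e.g. `"ROX"` or `"Alexa532"`.
#' @param motif_id identifier of the motif the net reaction queries.
#' @param truth optional list of generator ground-truth metadata (see
#'   [generate_gel_experiment()]); `NULL` for real data.
#' @return Object of class `gel_experiment`.
#' @export
gel_experiment <- function(lanes, condition, fluorophore = "ROX",
                           motif_id = "motif", truth = NULL) {
  if (!is_thermo_condition(condition)) stop("'condition' must be a thermo_condition")
  roles <- vapply(lanes, `[[`, character(1), "role")
  if (!all(c("control_XZ", "control_X") %in% roles)) {
    stop("gel experiment must contain both control lanes ",
         "(control_XZ and control_X) for yield calibration")
  }
  ids <- vapply(lanes, `[[`, character(1), "lane_id")
  if (anyDuplicated(ids)) stop("duplicate lane ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(lanes) <- ids
  structure(list(lanes = lanes, condition = condition,
                 fluorophore = fluorophore, motif_id = motif_id,
                 truth = truth),
            class = "gel_experiment")
}

#' @export
print.gel_experiment <- function(x, ...) {
  cat(sprintf("<gel_experiment> %s / %s at %.1f C in %s; %d lanes (%s)\n",
              x$motif_id, x$fluorophore, x$condition$temperature_celsius,
              x$condition$buffer, length(x$lanes),
              paste(vapply(x$lanes, `[[`, character(1), "role"),
                    collapse = ", ")))
  invisible(x)
}

BAND_TABLE_COLS <- c("lane_id", "role", "species", "initial_conc_x",
                     "band_intensity")

#' Read / write gel band-intensity tables
#'
#' The on-disk format is a plain CSV with columns
#' `lane_id,role,species,initial_conc_x,band_intensity` (one row per lane x
#' species; `band_intensity` is empty for unlabelled species), preceded by
#' `# key: value` comment lines holding the experiment metadata
#' (temperature, buffer, fluorophore, motif id and, for synthetic data, the
#' generator ground truth). Write followed by read is lossless.
#'
#' @param path file path.
#' @return `read_band_table` returns a [gel_experiment()];
#'   `write_band_table` returns `path` invisibly.
#' @export
read_band_table <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  }
  body_lines <- which(!is_meta & nzchar(trimws(lines)))
  df <- utils::read.csv(text = lines[!is_meta], stringsAsFactors = FALSE)
  missing_cols <- setdiff(BAND_TABLE_COLS, names(df))
  if (length(missing_cols)) {
    stop("band table ", path, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$initial_conc_x <- as.numeric(df$initial_conc_x)
  df$band_intensity <- suppressWarnings(as.numeric(df$band_intensity))
  # data row i of df came from file line body_lines[i + 1] (header first)
  row_line <- function(i) body_lines[i + 1L]
  bad <- which(!is.na(df$band_intensity) & df$band_intensity < 0)
  if (length(bad)) {
    stop("negative band intensity at line ", row_line(bad[1L]),
         " of ", path)
  }
  key <- paste(df$lane_id, df$species)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate lane x species entry at line ", row_line(d), " of ",
         path, " (", key[d], ")")
  }
  lanes <- lapply(split(df, factor(df$lane_id, levels = unique(df$lane_id))),
                  function(ld) {
    role <- unique(ld$role)
    if (length(role) != 1L) {
      stop("lane ", ld$lane_id[1L], " has inconsistent roles: ",
           paste(role, collapse = ", "))
    }
    has_band <- !is.na(ld$band_intensity)
    gel_lane(ld$lane_id[1L], role,
             initials = stats::setNames(ld$initial_conc_x, ld$species),
             bands = stats::setNames(ld$band_intensity[has_band],
                                     ld$species[has_band]))
  })
  tc <- as.numeric(meta$temperature_C %||% 25)
  cond <- thermo_condition(tc, meta$buffer %||% "PBS")
  truth <- NULL
  truth_keys <- grep("^truth_", names(meta), value = TRUE)
  if (length(truth_keys)) {
    truth <- lapply(meta[truth_keys], function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    })
    names(truth) <- sub("^truth_", "", truth_keys)
  }
  gel_experiment(unname(lanes), cond,
                 fluorophore = meta$fluorophore %||% "ROX",
                 motif_id = meta$motif_id %||% "motif",
                 truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_band_table
#' @param exp a [gel_experiment()].
#' @export
write_band_table <- function(exp, path) {
  stopifnot(inherits(exp, "gel_experiment"))
  fmt <- function(x) sprintf("%.17g", x)
  hdr <- c(
    sprintf("# temperature_C: %s", fmt(exp$condition$temperature_celsius)),
    sprintf("# buffer: %s", exp$condition$buffer),
    sprintf("# fluorophore: %s", exp$fluorophore),
    sprintf("# motif_id: %s", exp$motif_id))
  if (!is.null(exp$truth)) {
    hdr <- c(hdr, vapply(names(exp$truth), function(k) {
      v <- exp$truth[[k]]
      sprintf("# truth_%s: %s", k, if (is.numeric(v)) fmt(v) else as.character(v))
    }, character(1)))
  }
  rows <- unlist(lapply(exp$lanes, function(lane) {
    vapply(names(lane$initials), function(sp) {
      band <- if (sp %in% names(lane$bands)) fmt(lane$bands[[sp]]) else ""
      paste(lane$lane_id, lane$role, sp, fmt(lane$initials[[sp]]), band,
            sep = ",")
    }, character(1))
  }), use.names = FALSE)
  writeLines(c(hdr, paste(BAND_TABLE_COLS, collapse = ","), rows), path)
  invisible(path)
}

# Per-state quantum-yield calibration from the two control lanes:
# intensity per x-unit for ssDNA (from control_X) and dsDNA (control_XZ).
yield_calibration <- function(exp) {
  roles <- vapply(exp$lanes, `[[`, character(1), "role")
  ctrl_x <- exp$lanes[[which(roles == "control_X")[1L]]]
  ctrl_xz <- exp$lanes[[which(roles == "control_XZ")[1L]]]
  cal_ss <- ctrl_x$bands[["X"]] / ctrl_x$initials[["X"]]
  cal_ds <- ctrl_xz$bands[["XZ"]] / ctrl_xz$initials[["XZ"]]
  if (!is.finite(cal_ss) || cal_ss <= 0 || !is.finite(cal_ds) || cal_ds <= 0) {
    stop("control lanes give a non-positive yield calibration")
  }
  c(ss = cal_ss, ds = cal_ds)
}

#' Convert a lane's band intensities to concentrations
#'
#' Two corrections, in order: (1) each band is divided by the per-state
#' intensity-per-concentration factor calibrated from the control lanes
#' (fluorophore quantum yield differs between ssDNA and dsDNA); (2) a
#' single per-lane scale factor enforces conservation of labelled material,
#' `[X] + [XZ] = [X]0 + [XZ]0`, absorbing pipetting differences in the
#' amount of sample loaded. The output is therefore invariant to any common
#' scaling of the lane's bands.
#'
#' @param lane a [gel_lane()].
#' @param exp the [gel_experiment()] providing the control lanes.
#' @return Named vector `c(X = , XZ = )` of concentrations in x units.
#' @export
normalize_lane <- function(lane, exp) {
  cal <- yield_calibration(exp)
  ix <- if ("X" %in% names(lane$bands)) lane$bands[["X"]] else 0
  ixz <- if ("XZ" %in% names(lane$bands)) lane$bands[["XZ"]] else 0
  cx <- ix / cal[["ss"]]
  cxz <- ixz / cal[["ds"]]
  tot <- cx + cxz
  if (tot <= 0) stop("lane ", lane$lane_id, ": zero total labelled intensity")
  labelled0 <- sum(lane$initials[c("X", "XZ")], na.rm = TRUE)
  s <- labelled0 / tot
  c(X = s * cx, XZ = s * cxz)
}

#' Infer all four equilibrium concentrations from one observed species
#'
#' Given the nominal initial concentrations and the observed equilibrium
#' concentration of X or XZ, the three per-strand mass balances
#' `[X]+[XZ]`, `[Y]+[YZ]` and `[XZ]+[YZ]` determine the full vector
#' `([X],[Y],[XZ],[YZ])`. Observations may overshoot the feasible interval
#' by at most `overshoot_tol` (fractional, default 2% — band-quantitation
#' noise) and are clipped to the boundary; beyond that the call errors and
#' reports the interval.
#'
#' @param observed observed equilibrium concentration (any consistent unit).
#' @param initials named vector with X, Y, XZ, YZ initial concentrations in
#'   the same unit.
#' @param observed_species `"XZ"` (default) or `"X"`.
#' @param overshoot_tol allowed fractional overshoot before erroring.
#' @return Named vector with components X, Y, XZ, YZ (all >= 0).
#' @export
infer_concentrations <- function(observed, initials,
                                 observed_species = c("XZ", "X"),
                                 overshoot_tol = 0.02) {
  observed_species <- match.arg(observed_species)
  need <- c("X", "Y", "XZ", "YZ")
  if (!all(need %in% names(initials))) {
    stop("'initials' must name X, Y, XZ and YZ")
  }
  x0 <- initials[["X"]]; y0 <- initials[["Y"]]
  xz0 <- initials[["XZ"]]; yz0 <- initials[["YZ"]]
  t_lab <- x0 + xz0    # labelled strand X total
  t_z <- xz0 + yz0     # Z total
  t_y <- y0 + yz0      # Y total
  if (t_lab <= 0) stop("labelled total [X]0 + [XZ]0 must be > 0")
  xz <- if (observed_species == "XZ") observed else t_lab - observed
  lo <- max(0, t_z - t_y)
  hi <- min(t_lab, t_z)
  slack <- overshoot_tol * t_lab
  if (xz < lo - slack || xz > hi + slack) {
    stop(sprintf(paste0("observed [%s] = %.6g implies [XZ] = %.6g outside the ",
                        "feasible interval [%.6g, %.6g] (tolerance %.3g)"),
                 observed_species, observed, xz, lo, hi, slack))
  }
  xz <- min(max(xz, lo), hi)
  out <- c(X = t_lab - xz, Y = t_y - (t_z - xz), XZ = xz, YZ = t_z - xz)
  pmax(out, 0)
}

#' Reaction free energy from one catalysed gel lane
#'
#' Normalizes the lane ([normalize_lane()]), infers the full concentration
#' vector from the observed XZ ([infer_concentrations()]) and converts the
#' exchange equilibrium constant to a dG. Because the conservation-enforcing
#' lane scale makes the X-derived and XZ-derived inferences identical, a
#' single estimate is emitted per lane.
#'
#' @param lane a [gel_lane()] with role `"catalysed"`.
#' @param exp the enclosing [gel_experiment()].
#' @return A [dg_estimate()] with `n_measurements = 1` (its `sd` is `NA`;
#'   spread comes from replicate aggregation, see [aggregate_estimates()]).
#' @export
lane_delta_g <- function(lane, exp) {
  stopifnot(inherits(lane, "gel_lane"), inherits(exp, "gel_experiment"))
  if (lane$role != "catalysed") {
    stop("lane ", lane$lane_id, " has role '", lane$role,
         "'; dG is only inferred from catalysed (equilibrated) lanes")
  }
  conc <- normalize_lane(lane, exp)
  inferred <- infer_concentrations(conc[["XZ"]], lane$initials,
                                   observed_species = "XZ")
  if (inferred[["X"]] <= 0 || inferred[["YZ"]] <= 0 ||
      inferred[["Y"]] <= 0 || inferred[["XZ"]] <= 0) {
    stop("lane ", lane$lane_id, ": complete conversion leaves the ",
         "equilibrium constant undefined (a zero concentration)")
  }
  keq <- (inferred[["Y"]] * inferred[["XZ"]]) /
    (inferred[["X"]] * inferred[["YZ"]])
  dg_estimate(delta_g_from_keq(keq, exp$condition),
              sd = NA_real_, n_measurements = 1L,
              condition = exp$condition,
              label = paste0(exp$motif_id, "/", exp$fluorophore,
                             "/lane", lane$lane_id))
}

#' Combine replicate dG estimates into a single mean estimate
#'
#' Gaussian replicate model: value is the arithmetic mean, `sd` the sample
#' standard deviation divided by sqrt(k) (the s.d. of the mean), and
#' `n_measurements` the summed count. All inputs must share one condition.
#'
#' @param estimates list of [dg_estimate()] objects (k >= 2 for a nonzero
#'   sd).
#' @param label provenance label of the aggregate (defaults to the first
#'   input's label).
#' @return A [dg_estimate()].
#' @export
aggregate_estimates <- function(estimates, label = NULL) {
  if (inherits(estimates, "dg_estimate")) estimates <- list(estimates)
  if (!length(estimates)) stop("no estimates to aggregate")
  ok <- vapply(estimates, inherits, logical(1), "dg_estimate")
  if (!all(ok)) stop("all inputs must be dg_estimate objects")
  cond <- estimates[[1L]]$condition
  same <- vapply(estimates, function(e) same_condition(e$condition, cond),
                 logical(1))
  if (!all(same)) {
    stop("estimates measured under different conditions cannot be pooled")
  }
  vals <- vapply(estimates, `[[`, numeric(1), "value")
  k <- length(vals)
  sd_mean <- if (k >= 2L) stats::sd(vals) / sqrt(k) else NA_real_
  dg_estimate(mean(vals), sd = sd_mean,
              n_measurements = sum(vapply(estimates, `[[`, integer(1),
                                          "n_measurements")),
              condition = cond,
              label = label %||% estimates[[1L]]$label)
}
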