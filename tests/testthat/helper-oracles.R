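# Shared fixtures and independent brute-force oracles. The oracles never
# call the code paths they check: the equilibrium oracle scans the
# reaction-extent plane for the Gibbs minimum, the consensus oracle scans
# candidate means, the van't Hoff oracle scans the (dH, dS) plane.

cond25 <- thermo_condition(25)
cond25_mg <- thermo_condition(25, "TE 12.5 mM Mg2+")

# Ideal-dilute Gibbs free energy (kcal/mol per litre, additive constant
# irrelevant) of a composition of the X/Y/Z + XZ/YZ network.
gibbs_xyz <- function(a, b, totals, dg_xz, dg_yz, RT) {
  # a = [XZ], b = [YZ] in M
  x <- totals[["X"]] - a
  y <- totals[["Y"]] - b
  z <- totals[["Z"]] - a - b
  conc <- c(x, y, z, a, b)
  if (any(conc < 0)) return(Inf)
  dg <- c(0, 0, 0, dg_xz, dg_yz)
  xlogx <- ifelse(conc > 0, conc * (log(conc) - 1), 0)
  sum(conc * dg + RT * xlogx)
}

# Nested grid scan of the two reaction extents; refines to ~1e-6 of the
# feasible range, well below the 1e-5 comparison resolution.
oracle_equilibrium_xyz <- function(totals, dg_xz, dg_yz, RT,
                                   n_grid = 61L, passes = 4L) {
  lo_a <- 0; hi_a <- min(totals[["X"]], totals[["Z"]])
  lo_b <- 0; hi_b <- min(totals[["Y"]], totals[["Z"]])
  best <- c(a = NA_real_, b = NA_real_)
  for (p in seq_len(passes)) {
    as <- seq(lo_a, hi_a, length.out = n_grid)
    bs <- seq(lo_b, hi_b, length.out = n_grid)
    gv <- outer(as, bs, Vectorize(function(a, b)
      gibbs_xyz(a, b, totals, dg_xz, dg_yz, RT)))
    idx <- arrayInd(which.min(gv), dim(gv))
    best <- c(a = as[idx[1L]], b = bs[idx[2L]])
    da <- if (n_grid > 1) diff(as[1:2]) else 0
    db <- if (n_grid > 1) diff(bs[1:2]) else 0
    lo_a <- max(0, best[["a"]] - da); hi_a <- min(min(totals[["X"]], totals[["Z"]]), best[["a"]] + da)
    lo_b <- max(0, best[["b"]] - db); hi_b <- min(min(totals[["Y"]], totals[["Z"]]), best[["b"]] + db)
  }
  c(X = totals[["X"]] - best[["a"]], Y = totals[["Y"]] - best[["b"]],
    Z = totals[["Z"]] - best[["a"]] - best[["b"]],
    XZ = best[["a"]], YZ = best[["b"]])
}

# 1-D scan for the value minimising the sum of squared z scores.
oracle_consensus <- function(values, sds, resolution = 1e-6) {
  lo <- min(values) - 1e-3
  hi <- max(values) + 1e-3
  grid <- seq(lo, hi, by = resolution)
  ssz <- sapply(grid, function(m) sum(((values - m) / sds)^2))
  grid[which.min(ssz)]
}

# Nested 2-D scan for the (dH, dS) minimising the weighted sum of squares.
# The scan runs over (dH, dG at 300 K) — an axis-aligned parameterisation of
# the strongly correlated (dH, dS) valley — and converts back at the end.
oracle_vant_hoff <- function(tk, mu, sigma, passes = 6L, n_grid = 41L) {
  lo <- c(dH = -50, g300 = -5)
  hi <- c(dH = 50, g300 = 5)
  best <- c(dH = 0, g300 = 0)
  for (p in seq_len(passes)) {
    hs <- seq(lo[["dH"]], hi[["dH"]], length.out = n_grid)
    gs <- seq(lo[["g300"]], hi[["g300"]], length.out = n_grid)
    obj <- outer(hs, gs, Vectorize(function(h, g) {
      s <- (h - g) / 300
      sum(((h - tk * s - mu) / sigma)^2)
    }))
    idx <- arrayInd(which.min(obj), dim(obj))
    best <- c(dH = hs[idx[1L]], g300 = gs[idx[2L]])
    dh <- 2 * diff(hs[1:2]); dg <- 2 * diff(gs[1:2])
    lo <- best - c(dh, dg); hi <- best + c(dh, dg)
  }
  c(dH = best[["dH"]], dS = (best[["dH"]] - best[["g300"]]) / 300)
}

# Canonical melt test duplex: a ~20-bp reference duplex (dH ~ -140
# kcal/mol) with Tm 62 C at 300 nM equal strand totals, and a labelled
# partner differing by a -0.22 kcal/mol motif at 25 C.
melt_test_params <- function(motif_dg25 = -0.22, dH_motif = -0.81,
                             dH_ref = -140, tm_ref = 62,
                             strand_total = 300e-9) {
  dS_ref <- dH_ref / (tm_ref + 273.15) + R_KCAL * log(2 / strand_total)
  dS_motif <- (dH_motif - motif_dg25) / 298.15
  list(dH_xz = dH_ref + dH_motif, dS_xz = dS_ref + dS_motif,
       dH_yz = dH_ref, dS_yz = dS_ref, strand_total = strand_total)
}

eval_bl <- function(b, tc) b[["intercept"]] + b[["slope"]] * tc

known_baselines <- function(upper = c(intercept = 110, slope = -0.2),
                            lower = c(intercept = 25, slope = -0.05)) {
  structure(list(upper = upper, lower = lower), class = "melt_baselines")
}

toy_motif_path <- function() {
  system.file("extdata", "toy_motifs_synthetic.tsv", package = "nativedg",
              mustWork = TRUE)
}
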