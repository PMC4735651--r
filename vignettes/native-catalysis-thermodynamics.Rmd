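---
title: "Measuring DNA motif free energies by catalysed strand exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring DNA motif free energies by catalysed strand exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativedg)
```

## The measurement principle

The standard model of nucleic-acid hybridization is local: the standard
free energy of formation of a complex is the sum of the dG contributions
of its motifs — helix initiation, nearest-neighbour base stacks, terminal
dangles, terminal labels. Most tabulated motif parameters come from melt
curves run far from the conditions in which oligonucleotides are actually
used, and per-motif values must be disentangled from aggregate melt
thermodynamics by linear-algebra decomposition.

`nativedg` implements the alternative strategy of measuring one motif at a
time, isothermally, in the buffer of interest. A strand-exchange reaction

$$X + YZ \rightleftharpoons Y + XZ$$

is designed so that the product duplex XZ differs from the reactant duplex
YZ by only the motif of interest. Then
$\Delta G^\circ_{rxn} = \Delta G^\circ_{XZ} - \Delta G^\circ_{YZ} \approx
\Delta G^\circ_{motif}$ (the free strands X and Y are designed without
secondary structure so their own free energies cancel), and

$$K_{eq} = \frac{[Y][XZ]}{[X][YZ]}, \qquad
\Delta G^\circ = -RT \ln K_{eq}.$$

Measuring the equilibrium concentration of any one species — here the
fluorophore-labelled X and XZ on a non-denaturing gel — determines all
four through mass balance, hence $K_{eq}$ and the motif dG.

Direct strand exchange is impractically slow (second-order rate constant
around 1 M$^{-1}$s$^{-1}$; half-life $1/(k c_0) \approx 10^7$ s at 100 nM,
about 116 days). A substoichiometric non-covalent DNA catalyst C opens a
fast toehold-mediated pathway through the intermediate CZ
($C + YZ \rightleftharpoons Y + CZ$, $X + CZ \rightleftharpoons C + XZ$)
without changing the equilibrium constant, so the reaction equilibrates
within a 3 h incubation.

## Package layout

The modules mirror the stages of the measurement:

* `thermo_core` (`thermo_condition()`, `keq_from_delta_g()`,
  `delta_g_from_keq()`, `delta_g_at_temperature()`) — the dG/Keq algebra,
  with $R = 1.98720425\times10^{-3}$ kcal mol$^{-1}$K$^{-1}$. All internal
  energies are kcal mol$^{-1}$ and entropies kcal mol$^{-1}$K$^{-1}$; the
  conventional cal-based entropy appears only at the I/O boundary
  (`entropy_cal_to_kcal()`).
* `equilibrium_network` (`species_network()`, `solve_equilibrium()`,
  `apparent_delta_g()`, `bias_scan()`) — coupled mass-action equilibrium
  of the exchange network with optional catalyst intermediates.
* `kinetics_sim` (`rate_model()`, `simulate_timecourse()`,
  `second_order_half_life()`) — why the catalyst is necessary.
* `gel_pipeline` (`read_band_table()`, `normalize_lane()`,
  `infer_concentrations()`, `lane_delta_g()`, `aggregate_estimates()`) —
  band intensities to dG estimates.
* `inference_stats` (`subtract_fluorophore()`, `consensus_and_cs()`,
  `expected_cs_failures()`, `vant_hoff_fit()`) — the statistical layer.
* `melt_hrm` (`fit_baselines()`, `hybridization_yield()`,
  `keq_from_yield()`, `motif_dg_from_melt_pair()`,
  `melting_temperature()`) — the high-resolution-melt comparison branch.
* `dangle_model` (`duplex_delta_g()`, `length_correction()`,
  `fit_length_model()`) — the motif-sum prediction model and the
  saturating multinucleotide-dangle correction.
* `synthetic_data` (`noise_model()`, `generate_gel_experiment()`,
  `generate_melt_curve()`, `generate_dangle_series()`) — seeded
  generators with embedded ground truth.

The exported functions are the interface; `scripts/acceptance.R`
demonstrates a complete scripted run.

## The equilibrium solver

`solve_equilibrium()` finds the unique minimiser of the ideal-dilute Gibbs
free energy over mass-balanced compositions. Because the free energy is
strictly convex, the stationarity conditions — one mass-balance equation
per strand, with every complex concentration given by mass action,
$[c] = e^{-\Delta G^\circ_c/RT}\prod_s [s]^{n_{sc}}$ — have a unique root.
The solver runs a damped Newton iteration on these equations in
log-free-strand coordinates. This parameterisation (rather than
reaction-extent coordinates) keeps every iterate strictly positive and
handles duplex association constants of $10^{20}$ M$^{-1}$ and beyond; a
damped multiplicative pre-phase brings strongly bound systems into the
Newton basin, and a line search on the squared relative residual
guarantees progress. Convergence is declared at a relative mass-balance
residual of $10^{-12}$ (default), within 200 Newton iterations.
Activity coefficients are 1 throughout: the working regime is
$1\times = 300$ nM, far below where nonideality matters.

Three-strand intermediates (CXZ, CYZ) can be declared as species, but the
default configuration omits them: on gels they leave no visible band, and
they are short-lived. The two-strand intermediate CZ is the one that
matters for bias (below).

## Catalyst bias

The gel analysis ignores C-containing species. At equilibrium some Z is
sequestered as CZ, so the inferred $[YZ]$ (computed as
$Z_{tot} - [XZ]$) overshoots and the apparent dG overestimates the truth —
always in the same direction. `bias_scan()` quantifies this: with 0.1x
catalyst and CZ at least 1 kcal mol$^{-1}$ less stable than either product
duplex, the maximum overestimation over motif dG in $[-2, 2]$ is about
0.036 kcal mol$^{-1}$, comfortably below the 0.2 kcal mol$^{-1}$ worst-case
bound. The bound itself corresponds to a more extreme corner: if the full
0.1x of catalyst were clamped as CZ regardless of equilibrium, the
symmetric lane would read $K_{eq} = 0.45^2/0.55^2$ and a bias of
+0.24 kcal mol$^{-1}$; an equilibrium-consistent CZ never gets close to
full sequestration under the stated stability constraint. Two-reaction
motif measurements (below) cancel this bias entirely, since both
reactions share it.

```{r bias}
scan <- bias_scan(motif_dg = seq(-2, 2, by = 1), cz_offset = c(1, 2),
                  catalyst_fraction = 0.1)
attr(scan, "max_bias")
```

## From gel bands to dG

A gel experiment is six lanes: two controls (annealed XZ; X alone) that
calibrate the fluorophore's different quantum yield in duplex and
single-strand states, two uncatalysed lanes (the two direction setups,
which stay far apart after 3 h — the kinetic demonstration), and two
catalysed lanes at equilibrium. `normalize_lane()` divides each band by
the per-state yield factor estimated from the controls, then rescales the
lane so labelled material is conserved
($[X]+[XZ]=[X]_0+[XZ]_0$), absorbing per-lane loading differences. A
consequence of this conservation-enforcing scale is that the X-derived
and XZ-derived inferences coincide exactly, so `lane_delta_g()` emits a
single estimate per lane; we read the "correct for pipetting differences"
step as exactly this reconciliation. Observed concentrations may overshoot
the feasible mass-balance interval by up to 2% (band-quantitation noise)
and are clipped; larger violations raise an error, as does complete
conversion (which leaves $K_{eq}$ undefined).

Replicates aggregate under a Gaussian error model
(`aggregate_estimates()`): mean, s.d. of the mean, summed counts.
Dangle-type motifs are measured indirectly as the difference of two
reactions (fluorophore+dangle minus fluorophore), with additive variance
(`subtract_fluorophore()`).

## Consensus score and its Gaussian expectation

Each dangle parameter is measured twice — once with ROX, once with
Alexa532, on independently synthesised strands. The consensus is the
inverse-variance weighted mean (the minimiser of the summed squared z
scores; its s.d. is $(\sum \sigma_i^{-2})^{-1/2}$), and agreement is
summarised by the consensus score

$$CS = 10 - \sum_i z_i^2
     = 10 - \frac{(\mu_1-\mu_2)^2}{\sigma_1^2+\sigma_2^2},$$

so CS = 10 means perfect agreement, CS ≥ 8 puts the consensus within 1
s.d. of both measurements, and CS = 0 within $\sqrt{5} \approx 2.24$ s.d.
The definition extends unchanged to $k > 2$ measurements (the package
accepts any number); the two-fluorophore case is the one used in
practice.

`expected_cs_failures()` computes the expected number of CS ≤ 0 outcomes
under the Gaussian error model as $n \cdot 2(1-\Phi(\sqrt{5}))$, i.e.
treating each measurement's z score about the consensus as standard
normal — about 4 of 160, or 2.5%. One modelling note: for two
measurements the two z scores are perfectly anticorrelated and each has
variance $\tfrac12$ when the reported s.d.'s are the whole story, which
would put the CS ≤ 0 rate at $P(\chi^2_1 \ge 10) \approx 0.16\%$. The
2.5% figure corresponds to each measurement's deviation from the
consensus being a full standard normal — equivalently, to each
measurement carrying an independent systematic component comparable to
its statistical s.d., which is the realistic reading for independently
synthesised strand sets. `simulate_cs_fraction()` samples exactly that
model (pairs displaced symmetrically about their consensus by
$\pm z\sigma$, $z \sim N(0,1)$) and reproduces the 2.5% tail; both the
expectation and the Monte Carlo are exposed so the distinction stays
visible.

## Temperature dependence

`vant_hoff_fit()` fits the temperature-invariant model
$\Delta G^\circ(T) = \Delta H^\circ - T\Delta S^\circ$ to mean dG values
at several temperatures by weighted linear least squares in the design
$(1, -T)$, minimising the summed squared z scores; the normal equations
are solved in closed form and parameter s.d.'s come from the inverse
normal matrix (measurement sigmas treated as known). The weighted residual
sum of squares is reported as `sum_sq_z` without a p-value: linear fits of
real motif data are often poor, plausibly because motif dH/dS are
themselves temperature dependent, and the package deliberately fits only
the invariant model and surfaces the statistic.

## The melt-curve comparison branch

The comparison method infers duplex formation from dye fluorescence
during a melt ramp (the generator emulates 95 → 30 °C in 1 °C steps).
Linear baselines are fitted to the coolest and warmest 15% of the
temperature span (the windows are configurable; nothing in the method
fixes them), the hybridization yield is
$\theta(T) = (F - lower)/(upper - lower)$ clipped to
$[10^{-4}, 1-10^{-4}]$, and for a non-self-complementary duplex at equal
strand totals $c$, $K(T) = \theta/(c(1-\theta)^2)$ in M$^{-1}$. An
unweighted straight line of $\ln K$ against $1/T$, restricted to
$\theta \in [0.15, 0.85]$ (outside, the yield is baseline-dominated),
gives per-duplex dH/dS; differencing the XZ and YZ fits isolates the
motif.

Two numerical caveats are intrinsic and documented rather than hidden.
First, on a generated two-state curve the plateaus are never exactly
flat — residual dissociation in the cool window is at the $10^{-3}$ level
for a ~20-bp duplex — so fitted baselines reproduce the generating ones
only to about that accuracy; supplying the true baselines makes the whole
chain exact to numerical precision, which is how the exact-recovery
property is stated. Second, the melting temperature from
`melting_temperature()` is a linear interpolation of $\theta$ across 0.5
on the measured grid and matches the closed-form two-state
$T_m = \Delta H^\circ / (\Delta S^\circ - R\ln(2/c))$ to better than
0.05 °C at 1 °C spacing.

On matched synthetic truth the melt branch is roughly an order of
magnitude noisier than the catalysis branch (per-pair s.d. near 1.4 vs
0.14 kcal mol$^{-1}$ at the default noise models), reproducing the
direction and magnitude class of the headline precision comparison; the
in-paper arithmetic itself (s.d. 0.54 vs 0.038: a 14-fold ratio, hence
196-fold more experiments for equal precision) is exposed as
`precision_comparison()`.

## Multinucleotide dangles

The first dangle nucleotide stacks on the closing pair (stabilising);
every further nucleotide adds electrostatic repulsion with diminishing
reach. The package models the net destabilisation relative to the
single-nucleotide dangle as a saturating exponential

$$\Delta\Delta G^\circ(L) = A\,(1 - e^{-(L-1)/\lambda}),$$

zero at $L = 1$ by construction, approaching the plateau $A$ (the
measured long-dangle asymptote is +0.56 kcal mol$^{-1}$, reached by
roughly 8 nt). The empirical length table behind that asymptote is not
redistributable here, so the parametric curve stands in for the lookup;
$\lambda = 2$ nt puts 97% of the plateau at $L = 8$, consistent with the
reported saturation length. `fit_length_model()` fits $(base, A,
\lambda)$ by weighted Levenberg–Marquardt least squares with $A \ge 0$;
standard errors come from the Jacobian at the optimum, switching to a
pseudo-inverse when $A$ sits on its zero bound (where $\lambda$ is
unidentified). Only homopolymer dangle tails are accepted by
`duplex_delta_g()` — a heterogeneous tail could fold back and would break
the motif-sum assumptions.

```{r dangle}
fit <- fit_length_model(generate_dangle_series(per_point_sd = 0.07,
                                               seed = 1))
fit
```

## What the synthetic data emulate — and what they do not

`generate_gel_experiment()` reproduces the six-lane layout with the noise
structure the analysis assumes: lognormal per-lane loading error (sigma
0.05), multiplicative band-quantitation noise (CV 0.02), relative
stoichiometry error on every initial concentration (sigma 0.03), and a
dsDNA/ssDNA quantum-yield ratio (default 0.8) that the control lanes must
calibrate away. Uncatalysed lanes are produced by actually integrating
the mass-action kinetics for the 3 h incubation — reproducing the
direction asymmetry of the two setups mechanistically rather than by
assumption — and catalysed lanes by solving the equilibrium. The noise
magnitudes are a calibration, not a measurement: at these defaults a
single gel's dG spread is ~0.13 kcal mol$^{-1}$, so ~12 lane measurements
give an s.d. of the mean near 0.04, matching the precision class reported
for fluorophore parameters (all below 0.15 kcal mol$^{-1}$). Temperature
error and oligonucleotide synthesis error are not modelled — no defensible
generative mechanism exists for them at this level — so passing recovery
tests says nothing about those two error sources in real data.

Two idealisations matter for interpretation. The control lanes are
modelled as quantitatively converted calibration standards (annealed XZ,
pure X). And by default the generator omits the CZ intermediate — the
same working assumption the inference makes — so that zero-noise
round-trips are exact to $10^{-9}$ and recovery tests isolate the
inference machinery; setting a finite `cz_offset` injects the
sequestration bias deliberately, and `bias_scan()` is the tool that
studies it. The default reference duplex is $-30$ kcal mol$^{-1}$
(a 20+ bp duplex), strong enough that free Z is physically negligible, as
the mass-balance algebra assumes.

Problem sizes used by the shipped tests and the acceptance script were
chosen to exercise every pathway at comfortable precision: 20 zero-noise
truths on $[-2,2]$; 3 parameters × 5 gels (10 lane measurements) for the
noisy-precision check; 300 seeded gels for the spread calibration; a
10 000-pair consensus-score simulation; 85 grid points for the bias scan;
20 seeded dangle series of 21 lengths each.

## Known limitations

* Formation dGs are inputs: the solver and generators take per-complex
  free energies as given; `duplex_delta_g()` predicts them from a motif
  table but does no secondary-structure or partition-function
  calculation, and declares no coaxial-stacking terms.
* Catalysed kinetics are coarse-grained to second-order toehold binding
  plus fast resolution; individual branch-migration steps (tens of
  microseconds) are far below the time resolution that matters here, and
  no literature value pins the catalysed rate constant — the default
  $3\times10^5$ M$^{-1}$s$^{-1}$ is a representative toehold-mediated
  rate and is configurable.
* No salt-correction model: every estimate is native to its buffer, and
  the package never extrapolates a dG across buffers.
* The consensus s.d. is the inverse-variance (maximum-likelihood) one;
  no multiple-testing correction is applied across a parameter panel.
* Only the temperature-invariant dH/dS model is fitted; curvature in
  real van't Hoff plots shows up as a large `sum_sq_z`, not as a model
  extension.
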