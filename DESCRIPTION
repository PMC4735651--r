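Package: nativedg
Title: Isothermal Measurement of DNA Motif Free Energies via Catalysed
    Strand Exchange
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the standard free energy of DNA motifs
    (terminal fluorophores, single- and multi-nucleotide dangles) in native
    isothermal conditions from catalysed strand-displacement equilibria.
    Provides a coupled mass-action equilibrium solver and kinetic
    time-course simulator for the X + YZ <-> Y + XZ exchange network with a
    non-covalent DNA catalyst, inference of equilibrium concentrations and
    reaction free energies from fluorescent gel band-intensity tables,
    inverse-variance consensus statistics with a consensus score,
    z-score-weighted van't Hoff enthalpy/entropy fitting, a
    high-resolution-melt analysis branch for precision comparison, a
    nearest-neighbour motif-sum duplex free-energy model with a saturating
    multinucleotide-dangle length correction, and seeded synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
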