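Package: co2mea
Title: Classical Force-Field Modelling of CO2 Capture by Monoethanolamine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained classical molecular-mechanics toolkit for carbon
    dioxide and monoethanolamine (MEA). Implements harmonic bonded terms, 6-12
    Lennard-Jones dispersion-repulsion with arithmetic/geometric combining
    rules, and bond-centered dipole-dipole electrostatics with smooth cutoff
    tapers; analytic forces; constrained geometry optimization and
    finite-difference normal modes; parameter calibration against reference
    dimer energetics by nonlinear least squares; velocity-Verlet molecular
    dynamics with Berendsen temperature and pressure coupling, periodic boxes
    and spherical confinement; and trajectory analyses (fluctuation heat
    capacity, radial distribution functions, intramolecular hydrogen-bond
    histograms). Structure builders generate monomers, hydrogen-bonded dimers,
    clusters, liquid boxes and a gas-liquid interfacial composite
    programmatically.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
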