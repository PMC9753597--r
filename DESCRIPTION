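Package: curvib
Title: Anharmonic Vibrational Spectroscopy by Second-Order Perturbation
    Theory in Curvilinear Internal Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generalized second-order vibrational perturbation theory
    (GVPT2) for anharmonic vibrational transition energies of molecules,
    formulated either in Cartesian normal coordinates (with Coriolis
    couplings) or in curvilinear internal coordinates with a perturbatively
    expanded kinetic-energy operator.  Provides primitive internal
    coordinate detection with analytic Wilson B, B', G and G' tensors, the
    Wilson GF harmonic analysis, finite-difference assembly of quartic
    force fields and kinetic-metric derivatives from pluggable
    electronic-structure adapters, Fermi-resonance detection by the
    extended Martin test with deperturbation and polyad variational
    correction, dual-level (additive and substitution) composition of
    harmonic and anharmonic levels, coupling-order-restricted
    reduced-dimensionality variants, and analytic model potentials with
    sum-over-states and variational oracles for engine-free validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
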