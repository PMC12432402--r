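Package: fidascreen
Title: Flow-Induced Dispersion Analysis for Protein Binder Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of flow-induced dispersion analysis (FIDA)
    experiments for screening designed protein binders. Provides a physical
    model of Taylor dispersion in pressure-driven capillary flow, a forward
    simulator for raw Taylorgrams and whole lysate screening campaigns,
    Gaussian dispersion fitting to extract hydrodynamic radii (including
    two-species fits with a locked free-label radius and viscosity
    normalization from retention times), 1:1 binding isotherm fitting with
    ligand depletion for dissociation constants, hit calling by fixed
    threshold or Dunnett many-to-one testing against a preculture control,
    and structure- or sequence-based prediction of expected hydrodynamic
    radii.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    mvtnorm
Config/testthat/edition: 3
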