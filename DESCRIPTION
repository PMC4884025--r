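Package: btbiodyn
Title: Biodynamic Model of Bacillus thuringiensis Batch Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and nonlinear least-squares estimation of a coupled
    Gompertz-based kinetic model for Bacillus thuringiensis batch culture.
    Four key compounds (biomass, poly-beta-hydroxybutyrate, dipicolinic acid
    and Cry protein) track the vegetative, transition and sporulation phases;
    yield coefficients couple endospore and Cry formation to biomass decline
    and PHB consumption. Includes a synthetic-kinetics generator with
    replicate averaging and detection-limit censoring, phase-timing and
    stoichiometric yield analyses, and cross-fermentation regressions of
    kinetic parameters on initial glucose.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
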