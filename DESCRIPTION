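Package: amorphotrack
Title: Relaxation, Crystallization and Dissolution Analysis for Amorphous Drugs in Mesoporous Confinement
Version: 0.1.0
Authors@R: person("Amorphotrack", "Developers", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for the physical-stability workflow applied to amorphous
    active pharmaceutical ingredients in bulk and confined in mesoporous
    matrices: Havriliak-Negami deconvolution of broadband dielectric spectra
    with a dc-conductivity term, one-sided Fourier transform of the
    Kohlrausch-Williams-Watts function, relaxation maps with
    Vogel-Fulcher-Tammann and Arrhenius fits, glass-transition temperatures at
    a 100 s relaxation time, detection of the confinement-induced crossover in
    the temperature dependence of the structural relaxation time, coupling-model
    Johari-Goldstein tests, parallel-capacitor composition and deconvolution of
    heterogeneous (pore-filled) dielectrics, nonisothermal DSC event extraction
    with Kissinger activation-energy analysis, and dissolution-profile model
    fitting and classification. Includes a synthetic-data generator with known
    ground truth so the whole chain is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
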