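Package: modeswitch
Title: Discovering and Classifying Transport-Mode Switching in Multidrug
    Efflux Pumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for small molecules that switch a proton-coupled
    multidrug efflux pump between resistance and susceptibility modes.
    Implements differential phenotype-microarray hit scoring of paired
    functional/nonfunctional transporter strains, quadratic (ligand-depletion)
    binding-isotherm fitting of fluorescence-quench titrations,
    solid-supported-membrane electrophysiology (SSME) current-trace integration
    with transport-mode classification (antiport, symport, drug uniport,
    drug-gated proton uniport), Michaelis-Menten gating kinetics, sigmoid IC50
    dose-response comparison, and checkerboard MIC/FIC synergy analysis.  A
    synthetic-data module generates every input with planted ground truth so
    the full chain is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
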