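Package: plmox
Title: Two-Photon Phosphorescence Lifetime Analysis of Capillary Oxygen
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for two-photon phosphorescence lifetime
    microscopy (2PLM) measurements of oxygen partial pressure (Po2) in
    brain capillaries with the PtP-C343 sensor. Provides temperature-indexed
    Stern-Volmer sensor calibration, gated photon-decay accumulation and
    Poisson maximum-likelihood lifetime fitting, erythrocyte-associated
    transient (EAT) decomposition of capillary Po2 into RBC-border and
    inter-RBC pools, RBC flux extraction, Radon-style line-scan velocimetry,
    and Hill-equation hemoglobin saturation. A synthetic acquisition
    generator with known ground truth makes every stage verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
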