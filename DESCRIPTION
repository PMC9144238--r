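Package: cdftools
Title: Conceptual DFT Reactivity Descriptors and Koopmans-Compliance
    Diagnostics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes global and local Conceptual Density Functional Theory
    (CDFT) chemical-reactivity descriptors from frontier molecular-orbital
    energies: electronegativity, chemical potential, global hardness and
    softness, the electrophilicity index, the nucleophilicity index with a
    calibratable tetracyanoethylene reference, electrodonating and
    electroaccepting powers and net electrophilicity, together with
    electrophile/nucleophile classification on the standard scales.
    Validates the underlying model chemistry with the "Koopmans in DFT"
    (KID) compliance diagnostics built from ground-state energies of the
    N-1, N and N+1 electron systems, predicts pKa from global hardness via
    a linear QSAR, and evaluates finite-difference Fukui functions and the
    dual descriptor on electron-density grids read from and written to
    Gaussian cube files. Ships a reference set of seven marine
    cyclodepsipeptides (apratoxins A-G) and a fully deterministic synthetic
    data generator so every pipeline stage is testable without
    quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'units.R'
    'AllClasses.R'
    'AllGenerics.R'
    'energy-records.R'
    'log-parser.R'
    'cube-io.R'
    'kid.R'
    'global-descriptors.R'
    'local-fields.R'
    'pka.R'
    'synthetic.R'
    'fixtures.R'
    'pipeline.R'
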