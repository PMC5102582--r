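Package: p97nmr
Title: Methyl-NMR Analysis of p97/VCP N-Terminal Domain Dynamics and
    Adaptor Binding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the conformational dynamics of the
    N-terminal domain (NTD) of the AAA+ ATPase p97/VCP from solution-NMR
    observables.  Implements two-state fast-exchange population estimation
    from methyl chemical shifts, rotational correlation-time estimation
    from methyl 1H triple-quantum buildup curves and backbone 15N
    relaxation (reduced spectral density mapping with Lipari-Szabo
    model-free fitting), and a six-species conformational-selection plus
    two-pronged-binding equilibrium model for the UBXD1-N adaptor,
    including exact speciation, macroscopic dissociation constants and
    global titration fitting.  A deterministic synthetic-data generator
    produces inputs with the statistical structure each analysis assumes,
    so every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'scheme.R'
    'titration.R'
    'populations.R'
    'buildup.R'
    'nitrogen15.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
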