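Package: gfapsim
Title: Dynamic Serum Biomarker Kinetics for Brain Tumour Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates serum glial fibrillary acidic protein (GFAP) kinetics
    during glioblastoma growth. Tumour and necrotic-core volumes follow
    Gompertzian growth laws; necrosis releases GFAP into interstitial fluid,
    and a saturable (Hill-type) blood-brain-barrier transfer fraction feeds a
    one-compartment serum model with first-order elimination. Built on top of
    the forward model are detection-time and detection-volume analysis against
    serum cut-off thresholds, concentration-to-volume inversion, steady-state
    detection boundaries in the (transfer fraction, production rate) plane,
    local and constrained-global parameter sensitivity sweeps, and a seeded
    virtual-patient cohort sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
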