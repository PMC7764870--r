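Package: filmrheo
Title: Dilatational Rheology and Isotherm Analytics for Interfacial Films
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of Langmuir-trough measurements on interfacial films
    such as the tear film lipid layer. Converts stress-relaxation transients
    recorded after a small rapid area step into the complex dilatational
    viscoelasticity modulus E*(v) by one-sided Fourier transformation,
    builds Cole-Cole plots and counts relaxation processes, fits
    multi-exponential-plus-plateau relaxation models and maps them onto
    generalized Maxwell elements. Also processes repeated
    compression-expansion pi-A isotherm cycles (cycle splitting,
    stationarity, replicate averaging, condition-vs-control pressure shifts,
    squeeze-out pressure detection, hysteresis area) and extracts
    penetration-kinetics features from post-injection surface-pressure
    traces. Includes seeded synthetic-data generators emulating the
    statistical structure of trough recordings, so every pipeline stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
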