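Package: osteowave
Title: Mechanochemical Waves of Osteoblast Differentiation in Calvarial Bone Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a one-dimensional mechanochemical model of
    calvarial (skull-cap) bone expansion, in which a viscous tissue of
    osteoblasts and undifferentiated mesenchyme develops a self-propagating
    differentiation wave through feedback between cell-type-dependent tissue
    stiffness and stiffness-dependent differentiation. Provides the continuum
    solver (pressure/viscous/friction force balance with density-dependent
    growth and differentiation), wavefront detection and Lagrangian tracer
    analysis, in-silico perturbation scenarios (bone-center excision,
    collagen-crosslinking inhibition), a live-imaging quantification toolbox
    (mean squared displacement, velocity correlations, circular statistics of
    division orientation, intensity-profile alignment and slope, bone-area
    segmentation, regional proliferation fractions), synthetic-data generators
    for every input modality, and single-parameter model fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
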