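Package: ringcrf
Title: Ring-Model and Conductance-Based Simulations of V1 Contrast Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how threshold power-law transfer functions
    shape orientation tuning and contrast-response functions (CRFs) in a
    model hypercolumn of primary visual cortex. Implements a ring rate
    model with analytic self-consistency solutions, conditions on the
    recurrent projection widths that make orientation tuning exactly
    contrast invariant, a closed-form criterion for supersaturating CRFs,
    and linear stability analysis; a conductance-based spiking hypercolumn
    (Hodgkin-Huxley-type neurons with adaptation, double-exponential
    conductance synapses, orientation-tuned LGN drive) with an effective
    rate-model reduction based on leak-conductance threshold shifts; and a
    fitting layer for threshold power laws, periodic-Gaussian tuning
    curves and hyperbolic-ratio (Naka-Rushton) CRFs, including saturation
    classification, invariance metrics, heterogeneous-population
    experiments and parameter-correlation diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
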