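Package: ieplast
Title: Homeostatic Plasticity of Intrinsic Excitability: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify activity-dependent plasticity of intrinsic
    excitability in CA1 pyramidal neurons. Provides a conductance-based
    neuron simulator (exponential integrate-and-fire with I_h and a slowly
    inactivating D-type potassium current) driven by current-step and
    theta-burst stimulation protocols, extraction of intrinsic-excitability
    features from current-clamp sweeps (series and input resistance, sag
    ratio, spike threshold by dV/dt criterion, afterhyperpolarization,
    first-spike latency, burst index, membrane-potential variance),
    input-output curve normalization and group plasticity statistics, and a
    place-cell rate-map module (in/out-of-field firing by lap, session
    thirds, lap-by-lap correlations, stability, spatial information) with
    population-level tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
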