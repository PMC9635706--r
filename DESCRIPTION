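Package: pulserig
Title: Closed-Loop Hemodynamic Circuit Simulation and Pulse Wave Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A lumped-parameter (0D) closed-loop model of a coupled left
    atrium - left ventricle - aortic hydraulic circuit, discretized as an
    R-L-C transmission-line ladder with one-way smoothed valves, a two-chamber
    Windkessel afterload and a venous reservoir, together with the analysis
    chain used in experimental and clinical hemodynamics: beat detection by
    the intersecting-tangent rule, systolic/diastolic/mean pressures, form
    factor, augmentation index, dp/dt max, left ventricular end-diastolic
    pressure, stroke volume, cardiac output, total peripheral resistance,
    static compliance by incremental inflation, aortic input impedance
    spectra, wave intensity with forward/backward peak labeling, and
    foot-to-foot pulse wave velocity. Ships a scenario-preset grid covering
    heart rate, cardiac output, contractility, aortic stiffness, peripheral
    resistance and preload interventions, a self-describing waveform CSV
    dialect, JSON analysis reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rlang,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
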