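Package: stnmer
Title: Microelectrode-Recording Analysis of Subthalamic Nucleus Beta Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative microelectrode recordings (MER)
    acquired along deep-brain-stimulation trajectories through the subthalamic
    nucleus (STN). Computes spiking-band (300-6000 Hz) root-mean-square depth
    profiles normalized to an internal-capsule baseline, envelope power spectra
    of the rectified multi-unit signal at 1/3 Hz resolution, left-to-right
    decoding of STN entry, motor (DLOR) to non-motor (VMNR) transition and exit,
    depth-normalized group profiles and spectrograms, per-trajectory oscillation
    metrics (beta ratio, band power fractions, NRMS peak and AUC), and the group
    statistics used to contrast Parkinson's disease with essential tremor
    cohorts. Includes a synthetic-MER cohort generator emulating the assumed
    signal structure so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
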