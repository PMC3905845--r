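Package: halodyn
Title: Quantitative Live-Cell Imaging of Archaeal DNA-Repair Protein Dynamics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for quantitative fluorescence microscopy of
    haloarchaeal cells expressing GFP-tagged DNA-repair proteins under
    replication arrest. Provides focus detection and per-cell quantification
    in calibrated image stacks, normalization and mono-/bi-exponential
    kinetic fitting of fluorescence recovery after photobleaching (FRAP)
    traces, per-pixel number-and-brightness (N&B) fluctuation analysis of
    photon-counting time series, sedimentation-derived hydrodynamics
    (s20,w correction, frictional-ratio radius, oligomer stoichiometry),
    and a synthetic-data generator with recorded ground truth so that every
    stage of the pipeline is testable without experimental data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
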