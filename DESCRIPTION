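Package: burstmanifold
Title: Transcriptional Bursting Noise Analysis with the Two-State Telegraph Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and moment-based inference for transcriptional bursting
    from single-cell data. Implements exact Gillespie simulation of the two-state
    (random telegraph) promoter model with mRNA and protein stages, a truncated
    chemical-master-equation solver for the stationary mRNA distribution,
    burst-size and burst-frequency estimation from smFISH mRNA counts (Fano
    factor) and from calibrated flow-cytometry fluorescence (MESF), scatter-based
    sub-gating to remove extrinsic noise, autofluorescence correction, and
    analysis of the CV-squared-versus-mean relationship along hyperbolic
    constant-burst-size manifolds, including contraction and containment tests
    under burst-frequency perturbations. A synthetic clone-panel generator
    emulates isoclonal reporter populations with distinct burst parameters.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
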