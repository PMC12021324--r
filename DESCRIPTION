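Package: girfute
Title: Gradient System Transfer Function Estimation and 4D UTE
    Reconstruction for MR-Linac Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes the first-order gradient system transfer function
    (GSTF) of an MRI gradient chain from thin-slice triangular-pulse
    acquisitions, applies it to correct center-out UTE stack-of-stars k-space
    trajectories, and reconstructs motion-averaged and respiratory-resolved
    (4D) multi-echo UTE images via k-space-center self-navigation, overlapped
    respiratory binning and iterative compressed-sensing reconstruction.
    Includes an analytic linear-time-invariant simulator of the gradient chain
    and a breathing digital phantom with multi-coil stack-of-stars sampling so
    that every pipeline stage can be validated against ground truth without
    scanner access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
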