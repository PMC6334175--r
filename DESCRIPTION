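Package: mbverse
Title: Time-Optimal Multiband RF Pulse Design with Realistic Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of simultaneous-multislice (multiband) RF
    refocusing pulses with time-variable slice-select gradients. Implements
    Shinnar-Le Roux (SLR) pulse design (linear, minimum and quadratic phase),
    time-optimal VERSE with peak-B1, gradient and slew-rate constraints, the
    two orderings of VERSE and multiband modulation (MBv and vMB), root-flipped
    non-linear-phase multiband design by genetic search, PINS and MultiPINS
    pulses, spin-domain Bloch simulation, and prediction of slice-profile
    distortion caused by the finite temporal bandwidth of a gradient chain via
    its gradient impulse response function (GIRF).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
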