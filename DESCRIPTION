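Package: edipeaks
Title: Two-Stage Peak Detection and Neural Breathing Analysis for
    Diaphragm Electrical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects inspiratory peaks in the electrical activity of the
    diaphragm (Edi) recorded at 100 Hz during neurally adjusted ventilatory
    assist, using a two-stage approach: deliberate over-detection of candidate
    peaks by a centered local-maximum rule, followed by pruning with a
    one-dimensional grouped-convolution residual network trained to separate
    true inspiratory peaks from artifact maxima. From the final peaks the
    package segments neural breaths (inspiration onset to expiration end via a
    windowed-minimum rule), estimates respiratory rate, and flags
    patient-ventilator asynchrony (double triggering and autotriggering)
    against the airway-pressure channel. Includes two classical baseline
    detectors (first-derivative with adaptive threshold; two moving averages
    with dynamic threshold), a tolerance-window event-based evaluation
    protocol with interpatient cross-validation, and a synthetic neonatal
    Edi/pressure generator with ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    zoo,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
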