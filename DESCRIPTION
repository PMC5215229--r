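Package: apri
Title: Automatic Pre-Processing of Raman Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes the two dominant contaminants of micro-Raman imaging
    data sets: slowly varying fluorescence baselines and narrow cosmic-ray
    spikes. Baselines are estimated per spectrum by adaptive iteratively
    reweighted penalized least squares (airPLS) built on a sparse Whittaker
    smoother; spikes are detected and repaired by a principal-component
    most-similar-spectrum method that regresses each spectrum on its nearest
    neighbour in score space, thresholds the standardized residuals per
    channel, and replaces affected windows with the fitted reference. Includes
    a synthetic Raman-image generator with full ground truth, quantitative
    evaluation metrics, principal-component score maps, delimited and MAT v5
    matrix input/output, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
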