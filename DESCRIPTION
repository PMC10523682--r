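Package: heartmorph
Title: Cardiomyocyte Morphometry and Capillary Quantification from Cardiac Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomated quantification of cardiac histology images.
    Segments cardiomyocytes in brightfield (Gomori silver) or fluorescence
    (wheat germ agglutinin membrane) images with a tolerance-controlled
    marker-based watershed, classifies instances into cardiomyocytes, their
    nuclei and capillaries using colour, size and containment rules, measures
    calibrated morphometrics (area, maximum and minimum Feret diameter),
    counts capillary contacts per cardiomyocyte, and quantifies per-cell
    marker expression. Includes a seedable synthetic-tissue generator with
    exact ground truth, overlay rendering, CSV reporting, a manual-correction
    loop, and command-line entry points for batch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
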