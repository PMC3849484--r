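Package: ihcquant
Title: Automated Quantification of Immunostained Nuclei with Background
    Discrimination
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multistep analysis of brightfield immunohistochemistry (IHC)
    images that quantifies DAB-stained (brown) positive nuclei while
    discriminating diffuse spurious background staining. Positive objects are
    selected in up to four color/morphology passes over the RGB image; the
    ratio of two brown background areas routes each image to the macro suited
    to its background level (none, low, high). Object areas are converted to
    nucleus counts by area-based cluster splitting. Includes a synthetic IHC
    scene generator with ground truth and agreement statistics (Bland-Altman
    limits of agreement, empirical survival curves of paired count
    differences) for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
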