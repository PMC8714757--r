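Package: macvasc
Title: Macular Vascular Geometry Morphometry and Eye-Clustered Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the geometry of the macular vascular network from
    binarized fundus-photograph vessel maps. Builds fovea-centered ETDRS
    sector grids (1/3/6 mm circles split into quadrants), skeletonizes
    vessel masks into centerline segment graphs, and computes per-sector
    box-counting fractal dimension, vessel area rate, mean vessel diameter
    and subdivision-based tortuosity. Ships a synthetic generator for
    branching macular vessel trees and for paired-eye cohorts with
    configurable sex and age effects, and an exchangeable-correlation
    Gaussian generalized estimating equation (GEE) fitter with robust
    sandwich variance for analysing two correlated eyes per subject,
    together with the demographic test battery (summary-statistic t tests,
    chi-square sex-ratio test, Shapiro-Wilk) and baseline tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
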