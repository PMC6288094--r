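Package: fragcrit
Title: Critical Fragmentation Diagnostics for Forest Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects proximity to the critical fragmentation (percolation)
    threshold in forest landscapes from percent tree-cover rasters. Extracts
    Moore-neighbourhood forest patches across cover thresholds, fits and
    compares heavy-tailed patch-size distributions by maximum likelihood
    (power law with KS-estimated lower bound, power law with exponential
    cut-off, log-normal, exponential; AICc, Akaike weights, likelihood-ratio
    tests, BCa bootstrap intervals), computes largest-patch time-series
    diagnostics (RSmax, fluctuation distributions, Hartigan dip test,
    quantile-regression variance trends, skewness), and combines the criteria
    into a near-critical verdict. Bundled lattice simulators (site
    percolation, contact process) provide percolation-theory ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    quantreg,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    jsonlite
Config/testthat/edition: 3
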