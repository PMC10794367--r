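Package: recombmap
Title: Building, Rescaling and Evaluating Population-Specific Recombination Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assembling LD-based, population-scaled recombination
    estimates (rho = 4*Ne*r) into genetic maps: stitching overlapping
    estimation windows, estimating 4Ne by regression against a reference
    map, and rescaling to cM/Mb.  Includes mask construction for
    low-marker-density regions, multi-resolution landscape correlation and
    hotspot-sharing comparisons, IBD-segment merging and kinship
    estimation, local-ancestry and imputation-accuracy concordance
    metrics, and an EHH/iHS selection scan with frequency-bin
    normalization and a same-map permutation null.  A synthetic-data
    module generates every input the pipeline consumes, including a
    Wright-Fisher forward simulator with map-specified recombination and
    optional selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
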