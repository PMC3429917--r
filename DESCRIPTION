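Package: ldtqtl
Title: Location-Dependent Empirical Thresholds for QTL Genome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Permutation-based significance thresholds and adjusted P-values
    for single-marker QTL genome scans in two-genotype crosses (backcross and
    doubled haploid). Implements the classical constant genome-wide threshold
    obtained from the marginal null distribution of the maximum LOD score, and
    a location-dependent threshold that conditions on the marker at which the
    maximum is attained, controlling the genome-wide Type-I error rate while
    holding the local (per-marker) error rate constant. Includes a cross
    simulator with Haldane map-function support, chi-squared diagnostics for
    location bias, a recombination-sweep experiment, and readers and writers
    for R/qtl-style CSV cross files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
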