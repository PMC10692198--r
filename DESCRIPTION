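Package: recne
Title: Recent Effective Population Size from IBD Sharing and Linkage
    Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers recent (up to ~125 generations) effective population
    size trajectories from either the length spectrum of identity-by-descent
    (IBD) segments or the decay of long-range linkage disequilibrium (LD) in
    diploid or pseudo-haploid genotype panels, including low-coverage
    ancient-DNA panels with missing data and heterogeneous sampling times.
    Trajectories are piecewise-exponential and are estimated by maximising a
    regularised power likelihood, with chromosome-arm bootstrap confidence
    bands, automatic region-level quality filters, and a cross-chromosome LD
    test for population structure.  A segment-level coalescent simulator is
    included both as a fixture generator and as a Monte-Carlo oracle for the
    model expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    vcfR
Config/testthat/edition: 3
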