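Package: wormbench
Title: Forward-Time Transmission Genetics and a Virtual Picking Bench for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded forward-time simulator of Caenorhabditis elegans
    transmission genetics (hermaphrodite selfing, crosses, balancer
    chromosomes with reciprocal-translocation segregation, X-linked
    inheritance, extrachromosomal-array transmission) together with an
    exhaustive offspring-enumeration oracle, a balancer-based linkage
    mapping pipeline built around a Linkage Index, a genomic-integration
    screen, and a virtual picking bench that executes low/mid/high-level
    laboratory protocol scripts over barcoded plates with stochastic
    picking and screening outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
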