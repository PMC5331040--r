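Package: rootmix
Title: Isotope-Based Partitioning of Root Samples into Recent Root and
    Extraneous Organic Matter Carbon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions field root samples into recent (C4) crop root
    biomass carbon and extraneous organic matter (EOM) carbon using a
    two-pool delta-13C mass-balance mixing model. Provides quantile-based
    endmember estimation for the pure-root signature, averaging-based
    estimation of the EOM signature from a reference ley dataset,
    first-order and Monte-Carlo uncertainty propagation, mass-weighted
    pooling of root size classes, factorial group summaries, and
    design-respecting permutation tests for treatment, depth, position,
    size-class and EOM-exclusion effects. A synthetic-study generator
    emulates the split sampling design of the Swiss DOK long-term field
    trial (maize 2013) so the whole pipeline can be exercised and
    validated without access to unpublished per-sample measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
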