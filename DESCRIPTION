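Package: l2unifrac
Title: Phylogeny-Aware Beta Diversity with Averageable Samples via L2-UniFrac
Version: 0.1.0
Authors@R: person("Metagenomics", "Tools", email = "tools@example.org",
    role = c("aut", "cre"))
Description: Implements the L2-UniFrac beta-diversity metric for microbial
    community profiles: a phylogeny-aware distance under which biologically
    valid averages (barycenters) of metagenomic samples exist. Provides the
    linear-time post-order aggregation transform and its exact inverse,
    L1/L2 UniFrac distances, environment barycenters (representative
    samples), signed per-edge differential-abundance flow vectors,
    clustering directly in the aggregated space, nearest-representative
    classification, taxonomic trees with reciprocal branch-length
    assignment, a synthetic cohort generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
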