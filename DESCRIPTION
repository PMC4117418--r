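Package: gatetree
Title: Automated Gating-Strategy Trees for Single-Cell Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds data-derived gating strategies for flow and mass
    cytometry. A heterogeneous single-cell population is clustered with a
    nonparametric (kernel density) EM mixture model or hierarchical
    clustering, cluster assignments are refined by iterative reassignment of
    negative-silhouette cells, and a binary conditional-inference decision
    tree over the markers is grown to classify cells into clusters. The tree
    is pruned to the smallest height at which every cluster dominates a leaf
    and purified by an iterative filter-retrain loop until all leaves are
    pure, yielding an ordered sequence of gating markers, thresholds and
    sides per target population, together with strata-bootstrap stability
    ranges for the split points. Includes a labelled synthetic-mixture
    generator, FCS and delimited-text readers, strategy export/import, and
    cross-condition signalling-induction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
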