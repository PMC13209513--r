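Package: pharmfunnel
Title: Pharmacophore Screening and Pose-Triage Toolkit for PDE1 Inhibitor
    Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open re-implementation of the decision layers of an
    integrated virtual-screening funnel for phosphodiesterase-1 (PDE1)
    inhibitors: 3D pharmacophore feature perception, consensus model
    construction, tolerance-sphere matching via correspondence-graph
    clique search with Kabsch superposition, screening validation metrics
    (enrichment factor, Goodness-of-Hit, true/false positive rates),
    geometric triage of docked poses (hydrogen bonds, pi-pi stacking,
    pocket contacts, steric clashes), trajectory stability and
    hydrogen-bond occupancy analysis, and binding-energy-window
    enrichment statistics. Ships synthetic-fixture generators and the
    published 26-compound screening table so the whole funnel is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
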