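Package: qenp
Title: Quantity-Effect Weight-Coefficient Network Pharmacology
Version: 0.1.0
Authors@R:
    person("qenp", "maintainers", email = "qenp@example.org", role = c("aut", "cre"))
Description: Offline network-pharmacology toolkit for multi-component drugs
    (essential oils, herbal extracts) that propagates a per-component
    "quantity-effect" weight -- relative content times oral bioavailability --
    through a compound-target-pathway chain to re-rank over-representation
    results. Includes Kovats retention-index computation from an n-alkane
    ladder, drug/disease target-set intersection, bipartite compound-target
    and scored protein-protein interaction network analysis with mean-degree
    hub filtering, a self-contained hypergeometric over-representation test
    with Benjamini-Hochberg adjustment over GMT collections, a disease
    activity index scoring rubric for murine colitis, seeded synthetic
    fixture generators with planted enrichment structure, and a subcommand
    CLI tying the stages together.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
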