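Package: psfsom
Title: Pathway Signal Flow Portraits with Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes pathway signal flow (PSF) activities at the sink nodes of
    signed KEGG-style pathway topologies from gene-expression fold changes,
    portrays sink activities on a self-organizing map (SOM), detects
    over- and under-expression spots, tests differential sink activity against
    healthy controls with a shrinkage t-statistic and FDR control, and groups
    sample classes by shared pathway deregulation using random-walk graph
    community detection. Includes a synthetic-data generator producing layered
    pathway graphs in KGML format and group-structured expression matrices with
    known planted deregulations, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    igraph,
    jsonlite,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
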