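Package: netpharm
Title: Network Pharmacology of Multi-Compound Herbal Remedies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale systems-pharmacology toolkit for multi-compound,
    multi-target herbal remedies, built around the Albizia lebbeck seed
    extract studied in a haloperidol-catalepsy model of Parkinson's disease.
    Screens phytochemical descriptor tables with the Lipinski rule of five
    (at most one violation), filters reverse-pharmacophore target predictions
    by probability and organism, performs hypergeometric pathway
    over-representation with Benjamini-Hochberg false-discovery-rate control,
    builds bipartite compound-target and pathway-disease networks and reports
    their topology (degree, betweenness centrality, topological coefficient,
    heterogeneity, centralization, hub calls), and inverts the oxidative
    stress assay standard curves (GSH, SOD, CAT, protein). A deterministic
    synthetic-data generator emulates every upstream web-service output so
    the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
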