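Package: aoplink
Title: Linking Occupational Chemical Exposures to Respiratory Disease
    Mechanisms via Adverse Outcome Pathways and GO Term Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven pipeline for relating occupational chemical
    exposures to respiratory disease mechanisms. Curated Adverse Outcome
    Pathway (AOP) events and disease-gene lists are converted into Gene
    Ontology Biological Process (GO BP) term sets by descendant expansion
    over the GO graph and by overrepresentation analysis; exposure
    toxicogenomics fold-change tables are converted into enriched GO BP
    sets by a weighted running-sum gene set enrichment analysis with a
    gene-set permutation null; mechanistic linkage is quantified by Venn
    counts, Jaccard indices and cross-chemical common-term signatures,
    complemented by an in vitro versus in vivo concentration (dosimetry)
    comparator. Includes seeded synthetic-data generators (toy ontology,
    annotations, AOP event mappings, disease genes, ranked fold-change
    lists with planted enrichment) so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
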