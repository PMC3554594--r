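Package: fedphewas
Title: Federated Semantic-Web Phenome-Wide Association Scans on Synthetic
    EHR-Linked Biobank Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-creation of a semantic-web PheWAS system.
    Relational clinical and genotype tables are virtualized into RDF graphs
    by a direct-mapping rule (primary and foreign keys become IRIs, each
    column a predicate, each row an rdf:type statement), with R2RML-style
    overrides by ontology terms.  The two stores are queried jointly by a
    federated SERVICE-join evaluator, the retrieved genotype-diagnosis
    bindings are clustered into mutually exclusive phenome categories in the
    style of AHRQ's Clinical Classifications Software, and each SNP of a
    scan panel is tested for association against every retained category
    (2x2 odds ratios with Woolf intervals, Fisher exact tests, multiplicity
    adjustment).  A seeded synthetic-data generator emulates an EHR-linked
    biobank cohort of five study subgroups with configurable planted
    genotype-phenotype effects, so the whole pipeline runs and is testable
    without any protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
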