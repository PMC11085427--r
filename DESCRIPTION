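Package: flavoprior
Title: Candidate-Gene Prioritization for Flavonoid and Vascular Health
    Nutrigenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates differentially expressed gene (DEG) lists from
    human flavonoid intervention studies with gene sets curated from
    genome-wide association studies (GWAS) of vascular dysfunction
    (hypertension, atherosclerosis, arterial stiffness), canonical-pathway
    placement, upstream-regulator overlap enrichment, and literature and
    variant evidence. Candidate genes are scored against six intersection
    criteria and ranked into a top-priority set for nutrigenetic study
    design. Includes hypergeometric over-representation analysis with
    Benjamini-Hochberg control, multi-set Venn partitioning of study gene
    lists, GWAS-Catalog-style export curation with trait filtering, a
    synthetic-data generator with planted ground truth for end-to-end
    validation, and a configuration-driven pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
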