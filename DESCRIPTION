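Package: koscore
Title: Reporter-Score Enrichment of KEGG Modules and Taxon-Function
    Networks for Gut-Microbiome Amino Acid Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Functional-metagenomics toolkit for two-group cohort studies of
    gut microbial amino acid metabolism. Reads stratified per-sample KEGG
    Orthology (KO) gene-family tables (HUMAnN2-style "KO|g__Genus" rows),
    performs per-KO one-tailed Mann-Whitney differential-abundance testing,
    aggregates Z-transformed p-values into KEGG-module reporter scores with a
    random-set background correction, correlates summed gene-set abundances
    with host plasma and fecal amino acid concentrations by group-stratified
    Spearman correlation, and builds annotated genus-KO-module contribution
    networks exported as GraphML. A synthetic-cohort generator with planted
    genus depletions, module-level shifts and metabolite links provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
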