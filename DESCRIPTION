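Package: fesurvey
Title: Comparative Survey of Iron and Sulfur Metabolism Genes in Archaeal Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying iron and sulfur acquisition, cofactor
    biosynthesis, cofactor-binding-motif usage, and iron storage across
    predicted proteomes of archaeal methanogens, methanotrophs, and
    alkanotrophs. Provides a cofactor-binding-motif grammar and scanner
    (heme c CXXCH-type, heme b GX(H/R)XCXGX, siroheme and [Fe-S]
    cysteine-cluster motifs), tiered classification of homology-search
    hits with an identity rescue band and operon-synteny support, pathway
    presence/absence calling, per-taxon prevalence summaries including the
    [Fe-S]-motif proteome fraction, and Jaccard dissimilarity with
    principal coordinates ordination. A synthetic proteome cohort
    generator with planted ground truth supports end-to-end validation
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
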