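Package: interflora
Title: Interspecific Molecular Interaction Networks from Metagenome
    Functional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers candidate interspecific molecular interactions in a
    microbial community by scoring pathway-adjacent KEGG Orthology (KO)
    pairs with the product of phylogenetic-profile dissimilarity and
    co-occurrence correlation. Reconstructs a merged pathway network from
    KGML files, builds genus-presence and sample-abundance profiles from
    relative-abundance tables, validates scores against metabolic boundary
    pairs and pathway-module termini, compares observed communities with
    random-genome and random-gene null models, projects interacting KO
    pairs to genus pairs, clusters donors by their genus-pair repertoires,
    and contrasts cohorts with a two-standard-deviation rule. A synthetic
    community generator with planted interactions makes the whole pipeline
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
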