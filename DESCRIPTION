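Package: wwproteome
Title: Wastewater Metaproteomics with De Novo-Guided Focused Database Searching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-processing pipeline for wastewater metaproteomics. De novo
    peptide reads are filtered by average local confidence, assigned taxa by
    lowest-common-ancestor matching against a UniRef90-style reference, and the
    identified taxonomic families drive construction of a per-sample focused
    protein database. A two-round sequence-level database search (round one
    against the focused database, round two against the round-one hits combined
    with the human reference proteome) is filtered by target-decoy false
    discovery rate estimation, with entrapment evaluation. Downstream tools
    provide protein grouping, top-3 peptide-area quantification, microbial and
    human dataset splits, taxonomic composition, Shannon and Bray-Curtis
    diversity, principal coordinate analysis, gut/pathogen categorization and
    disease-list association counts. A seeded synthetic-community generator
    emulating a two-site, five-timepoint, duplicate sampling design provides
    fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
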