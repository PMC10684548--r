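Package: phagemosaic
Title: Detection of Protein Domain Mosaicism in Bacteriophage Proteomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for quantifying protein domain mosaicism in
    bacteriophage proteomes from profile-profile (HMM-HMM) hit tables.
    Aggregates directional multi-HSP hits into symmetric pair comparisons,
    assigns simplified functional classes (PHROG-style, with antidefence
    override) and ECOD X/H/T domain architectures, detects mosaic protein
    pairs by two complementary definitions (shared-topology/unique-X-group
    and short high-identity shared fragments), clusters proteins into
    families with an in-package Markov clustering implementation, computes
    one-tailed Fisher enrichment of domains and functional classes with
    Bonferroni correction, builds mosaic functional-class networks, and
    relates mosaicism to host, taxonomy and lifestyle. Includes a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
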