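Package: mtphylo
Title: Automated Curation, Alignment and Parsimony Annotation of Mitochondrial Genome Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-driven workflow for building curated mitochondrial-DNA-style
    phylogenies from raw FASTA collections: single-sequence quality tests
    (length classes, ambiguity accounting, N-run detection, duplicate
    compression), circular start-point correction, reference-guided
    partitioned alignment with indel classification, parsimony edit
    distances with group-wise outlier detection, desk-scale tree inference
    (neighbor joining, bootstrap, majority-rule consensus, outgroup
    rooting), and generalized Fitch parsimony annotation of trees with
    mutation classification (conservation, back-mutations, ambiguity,
    indels), per-branch outlier screens and summary statistics. A seeded
    synthetic-data generator with full ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    xml2
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
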