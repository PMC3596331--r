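Package: xb3scan
Title: Annotation and Classification of Ankyrin-Repeat C3HC4 RING
    (XB3-Like) Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects tandem 33-residue ankyrin (ANK) repeats and C3HC4-type
    RING finger domains in protein sequences, classifies XB3-like family
    members into phylogenetic groups I-III from RING metal-ligand spacing
    and conserved-residue signatures and into ANK-count classes A-F,
    computes molecular weight and isoelectric point, builds
    neighbour-joining trees from protein alignments (p-distance, complete
    deletion, bootstrap support), and calls preferential and differential
    expression from qPCR Ct tables.  Ships ground-truthed synthetic data
    generators for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
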