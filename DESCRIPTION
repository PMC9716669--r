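Package: gonadnet
Title: Signed Co-Expression Network Analysis of Gonadal Development Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable reimplementation of a signed weighted
    gene co-expression workflow for bulk RNA-seq time courses of developing
    gonads, as used to dissect gonad formation, sex differentiation and
    gametogenesis in the dwarf surfclam (Mulinia lateralis). Covers raw-read
    quality filtering and TPM normalization; Spearman-based signed adjacency
    with soft thresholding and scale-free fit diagnostics; topological-overlap
    dissimilarity and module detection by hierarchical clustering; per-gene
    one-way ANOVA with Storey q-value FDR; hypergeometric module
    overrepresentation, intramodular-connectivity hub ranking, module
    eigengenes and expression-archetype classification; and a hub-marker
    clustering procedure that dates molecular sex differentiation from
    samples collected before morphological sexing is possible. A synthetic
    developmental time-course generator with full ground truth makes every
    stage testable without the original sequencing libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
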