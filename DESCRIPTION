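Package: protkmer
Title: Alignment-Free Proteome Comparison via Amino-Acid k-mer Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents whole proteomes (or functional subsets of them) as
    normalized amino-acid k-mer frequency vectors and compares organisms
    without alignment. Provides the Minkowski-family, Pearson-correlation and
    top-set intersection distances between such vectors, bottom-up
    agglomerative clustering with single/average/complete linkage from a
    distance matrix, conversion of the resulting dendrogram into the flat
    clustering that maximizes the Rand index against a reference
    classification, a random-binary-tree null model with a Student-t fit for
    significance calibration of Rand values, most-abundant-k-mer intersection
    and within/between-group distance analyses, and a generator of synthetic
    clade-structured proteomes with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    Biostrings,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
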