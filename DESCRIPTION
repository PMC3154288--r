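Package: thermoprofile
Title: Protein Thermostability Profiling from Amino Acid Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies proteins as mesostable or thermostable from primary
    sequence alone. Computes a large panel of composition-based attributes
    (amino acid and dipeptide counts and frequencies, elemental composition,
    isoelectric point, aliphatic index, extinction at 280 nm, hydropathy and
    charge classes), cleans and min-max normalizes the resulting feature
    table, ranks attributes with eleven weighting algorithms (information
    gain, gain ratio, chi-squared, Gini, symmetric uncertainty, Relief,
    OneR-based rule weighting, deviation, linear-SVM, PCA and point-biserial
    correlation), and evaluates four unsupervised clustering algorithms
    (k-means, k-medoids, support vector clustering, EM Gaussian mixtures)
    against the class labels, alongside decision-tree induction and
    feed-forward/Elman neural networks under 10-fold cross-validation.
    Includes a seeded synthetic-sequence generator with planted compositional
    class differences so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    e1071,
    kernlab,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    seqinr
Config/testthat/edition: 3
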