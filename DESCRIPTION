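Package: gaitstrings
Title: Symbolic Gait Sequence Clustering and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Syntactic pattern recognition for stride-interval gait series.
    Time series are discretised into symbol strings with the symbolic
    aggregate approximation (SAX); per-class string prototypes are learned
    with a string-grammar unsupervised possibilistic fuzzy C-medians
    clustering algorithm built on the Levenshtein distance and (modified)
    fuzzy median strings; test strings are classified against the pooled
    prototype set with a fuzzy k-nearest-neighbour rule. Includes readers
    for PhysioNet-style stride-interval records, a stratified
    cross-validation protocol with sensitivity/specificity reporting, and
    synthetic generators for gait-like series and mutated string clusters
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), mclust, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
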