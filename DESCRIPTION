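Package: gfsel
Title: Graph-Based Ensemble Feature Selection for Binary QSAR-Style Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ensemble feature selection for binary classification of
    nonnegative descriptor matrices (for example molecular fragment counts).
    Boosting rounds of a base subset selector (FAST, a minimum-spanning-tree
    feature clustering filter driven by symmetric uncertainty) are accumulated
    in an undirected co-selection graph whose vertex values count how often a
    feature was selected and whose edge values count how often two features
    were selected together.  Final subsets are extracted from the graph by
    threshold and chain strategies (variants mT, MmT, mTC, MmTC), with the
    threshold pair chosen to maximise a criterion combining Cohen's kappa and
    feature reduction, and compared against the standard vote-threshold
    baseline (T).  Includes evaluation metrics (G-Mean, kappa, reduction,
    mutual-information and correlation redundancy), a repeated double
    cross-validation benchmark harness for decision tree, random forest and
    support vector machine classifiers, multi-dataset rank statistics
    (Friedman, Iman-Davenport, Holm, Nemenyi), and a synthetic fragment-count
    data generator with planted relevant, redundant and irrelevant features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    rpart,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
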