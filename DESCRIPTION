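Package: admorph
Title: Staged Dementia Classification from Morphometric Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of disease stage (normal control, mild cognitive
    impairment, Alzheimer's disease) from tabular morphometric features such
    as FreeSurfer regional grey-matter volumes. Implements PCA feature
    selection with grid search over the number of components, kernel logistic
    regression and its sparse import vector machine variant with greedy
    forward selection of import vectors, a regularized extreme learning
    machine with an optional reliability-gated sparse-representation
    fallback, a support vector machine baseline, stratified cross-validation
    protocols (repeated 70/30 splits, repeated 10-fold, leave-one-out), and
    permutation-test significance assessment of cross-validated accuracy.
    Includes a synthetic cohort generator emulating three-class atrophy
    structure so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
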