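Package: vaforest
Title: Pairwise Random Forests with Rank-Based Cause Assignment for Verbal Autopsy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computer-coded verbal autopsy: assigns a cause of death from
    dichotomous sign/symptom interview items by training one random forest per
    unordered pair of causes (class-balanced bootstrap resamples, Gini splits
    on a Tariff-reduced item pool) and combining the pairwise vote tallies
    through a rank-normalization step that compares each test score against the
    corresponding cause column of the training score matrix. Includes
    chance-corrected concordance, partial (top-k) concordance and CSMF-accuracy
    evaluation metrics, a validation harness with cause-stratified train/test
    splits and Dirichlet resampling of the test cause composition, and a
    synthetic verbal-autopsy data generator with controllable cause
    separability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
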