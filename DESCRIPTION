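Package: emovocab
Title: Emotion-Vocabulary Development from Free-Labeling Vignette Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how children's emotion vocabulary converges
    toward adult usage in free-labeling vignette tasks. Codes raw answers
    against a curated German emotion lexicon, builds vignette-by-word
    production matrices and vignette co-naming similarity matrices,
    quantifies vocabulary growth (one-way ANOVA with Bonferroni post hocs)
    and convergence toward adult usage (Spearman correlation, Fisher
    r-to-z comparison of independent correlations), recovers semantic
    dimensions by nonmetric multidimensional scaling (SMACOF majorization,
    Kruskal stress-1), and models ease of word learning from caregiver
    input frequency and word specificity (Shannon entropy of adult usage).
    Includes a synthetic-data generator emulating the age-graded study
    design so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
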