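# emovocab

Tools for studying how children's emotion vocabulary develops toward
adult usage in free-labeling tasks: participants (four child age groups
and an adult reference sample) label 20 illustrated emotion vignettes
with whatever word they choose, and the package quantifies what that
reveals about the growth and reorganization of the emotion lexicon.

The package is aimed at developmental psycholinguists who want the full
analysis chain of such a study as reusable, tested code — from raw
answer strings to the word-learning models — together with a synthetic
generator of the whole study design, so that every stage can be
exercised and validated without access to restricted participant data.

## What it computes

* **Coding.** Raw answers are reduced to canonical word stems via a
  curated German emotion lexicon; valence-only answers ("gut",
  "schlecht") become the two *unspecific* pseudo-words; negations of
  specific emotions ("nicht traurig") map to the unspecific category of
  the opposite valence; physiological/cognitive/behavioral descriptors
  are excluded as non-emotion answers.
* **Vocabulary growth.** Distinct emotion words per participant, with a
  one-way ANOVA (F, η² = SS_between/SS_total) over age groups and
  Bonferroni-corrected pairwise t tests.
* **Production matrices and convergence.** For each group, a 20 × W
  matrix tallies how many participants produced word *w* for vignette
  *v*. Convergence of a child group toward adult usage is the Spearman
  correlation ρ between the flattened child and adult matrices
  (average ranks; the many zero cells form one tie group), and per word
  over its 20-vignette vector. Differences between independent ρs are
  tested with Fisher's r-to-z:
  `z = (atanh(r1) − atanh(r2)) / sqrt(1/(n1−3) + 1/(n2−3))`.
* **Semantic dimensions.** A vignette × vignette co-naming similarity
  matrix (same participant, same word for both vignettes) is converted
  to dissimilarities `d = 1 − s/n_pairs` and embedded in two dimensions
  by SMACOF majorization — nonmetric by default, with isotonic
  disparities and Kruskal stress-1
  `sqrt(Σ(d̂ − dist)² / Σ dist²)` — initialized from classical
  (Torgerson) scaling and oriented so positive-valence vignettes sit on
  the right of dimension 1.
* **Ease of learning.** Word specificity is the Shannon entropy of a
  word's usage distribution over vignettes in the adult sample,
  `H(w) = −Σ_v p(v) log10 p(v)` (ceiling log10 20 ≈ 1.301; undefined
  for words adults never produced), and caregiver input frequency is
  aggregated from child-directed-speech counts by stem. Standardized
  regressions predict each group's production frequency and degree of
  convergence from these measures.

## Worked example

```r
library(emovocab)
design <- default_design()                       # 20 vignettes, 150 participants
responses <- simulate_responses(design, simulation_params(seed = 1))
coded <- code_dataset(responses, design$lexicon)

vocab_stats(coded, groups = design$age_groups)
#> <vocab_stats> group means: 4-5=7.8, 6-7=10.6, 8-9=12.4, 10-11=15.1, adult=17.7
#>   F(4, 145) = 126.7, p = 2.77e-46, eta^2 = 0.78

words <- words_produced(coded)
mats <- lapply(setNames(design$age_groups, design$age_groups),
               function(g) production_matrix(coded, g, words = words))
sapply(design$age_groups[1:4], function(g)
  matrix_convergence(mats[[g]], mats[["adult"]])$rho)
#>   4-5   6-7   8-9 10-11
#> 0.733 0.749 0.809 0.803

round(fisher_z_test(0.443, 0.551, 1320, 1320)$z, 1)
#> [1] -3.7

fit <- orient_mds(smacof(to_dissimilarity(similarity_matrix(coded, "adult"))),
                  design$vignettes$valence)
fit
#> <mds_result> nonmetric, k=2, stress-1 = 0.001238 (1000 iterations)

fit_models(table2_as_measures(), "10-11",
           dv = "production_frequency", predictors = "specificity")
#> <regression_result> production_frequency ~ specificity (10-11): R2 = 0.64, F(1, 36) = 63.9, p = 1.7e-09
#>   beta[specificity] = 0.800
```

Reading the output: mean distinct-word counts rise monotonically across
the child groups toward the adult level, and the age effect is large
(η² = .78). Whole-matrix convergence ρ rises with age (adjacent steps
are noise-limited at n ≈ 30 per group). The Fisher test shows the jump
between the published ρ = .443 and ρ = .551 groups is significant
(z = −3.7). The adult co-naming structure embeds in two dimensions at
near-perfect stress, with valence separating on dimension 1. On the
packaged published word table, adult-usage entropy alone explains about
64% of the variance in how frequently 10–11-year-olds produce each word
— less specific (broader) words are used more.

`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` chains all
five analyses and writes per-analysis JSON/CSV reports plus a run log.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end on a seeded synthetic study —
coding, vocabulary ANOVA, convergence ρs with Fisher comparisons,
per-group SMACOF solutions, and the word-level regressions — prints a
run summary, and writes the JSON result file.
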