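---
title: "Methods: emotion-vocabulary development from free labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion-vocabulary development from free labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emovocab)
```

## The design being modeled

A free-labeling emotion-vocabulary study presents 20 short illustrated
vignettes, each built around a target emotion — the six basic emotions
(joy, fear, sadness, anger, disgust, surprise) plus fourteen complex
emotions subordinated to them — to four child age groups (4–5, 6–7,
8–9, 10–11 years; n ≈ 30 each) and an adult reference sample (n = 27).
Each participant produces one word per vignette. Children who give no
answer to five consecutive vignettes stop contributing (discontinue
rule). Everything downstream operates on these answers.

## Coding

Answers are matched case-insensitively against a curated lexicon:
surface forms sharing a stem collapse to the stem; valence-only answers
map to the `unspecific_positive` / `unspecific_negative`
pseudo-categories; negating a specific emotion maps to the unspecific
category of the **opposite** valence (so "nicht traurig" codes
positive); descriptors of physiological, cognitive or behavioral states
are coded `not_emotion`; empty or don't-know answers are `no_answer`.
Two open points were resolved as follows:

* Softened negations of valence words ("nicht so schlecht") also flip
  (to `unspecific_positive`). The flip rule is kept uniform rather than
  special-cased, because a principled boundary between "flipping" and
  "softening" negations cannot be drawn from a word list alone.
* Unknown strings are coded `not_emotion` with a warning rather than
  raising an error: in the original workflow a human coder resolves
  them, and an analysis pipeline should degrade gracefully on the long
  tail of free text. The packaged lexicon covers the published 38-item
  inventory plus common inflections and is extensible via
  `emotion_lexicon()`.

Stemming is lookup-table based, not algorithmic: the study domain is a
closed, curated vocabulary, and German morphological stemming would add
failure modes without adding coverage.

The two unspecific categories are treated as *words* everywhere
downstream (word list, production matrices, convergence, entropy,
regressions): they carry substantial probability mass in young
children's labeling and the published word-level table treats them as
rows like any other word.

## Matrices

The production matrix for a group tallies, per vignette × word, how
many participants produced that word there. The column universe is
**every word produced anywhere in the study** — not the thresholded
word list — so that matrices of all groups are conformable and rare
words still contribute cells; the ≥ 5-distinct-participants list (38
words in the published study) is reserved for the word-level measures
of the learning models. With the published 66-word universe this gives
20 × 66 = 1,320 cells, the N used in the correlation comparisons.

Co-naming similarity counts *events*: for each participant and each
unordered vignette pair, one count when the participant gave the same
coded word to both. Aggregate-profile overlap would be an alternative
reading, but event counting is the direct reading of "number of times
two vignettes were named with the same word", and it weights each
participant equally. Whether the two unspecific categories should be
matchable "same words" is not decidable from the published text;
the default is matchable (they behave as words everywhere else), with
`match_unspecific = FALSE` available for sensitivity analysis.

## Convergence statistics

Whole-matrix convergence is the Spearman ρ between the flattened child
and adult matrices, zero cells included, ties by average ranks — the
only reading under which all 1,320 cells enter the correlation, since
most cells are zero and form one large tie group. Per-word convergence
applies the same estimator to each word's 20-vignette vector; when a
word has zero variance in either group the correlation does not exist,
and the package reports `NA` internally (tabular output renders it
0.00, matching the published table's convention, but the distinction
is preserved in code).

Fisher's r-to-z comparison uses
`z = (atanh(r1) − atanh(r2)) / sqrt(1/(n1−3) + 1/(n2−3))`. The
one-tailed normal p is primary — the published p = .117 for z = −1.2
is the one-tailed tail — and the two-tailed value is also returned.
Post hoc vocabulary comparisons use pooled-variance t tests with the
Bonferroni factor equal to the number of pairs (10 for five groups),
capped at 1; the published analysis names only "Bonferroni corrected",
so the plain pooled-variance variant was chosen.

## Multidimensional scaling

Similarities become dissimilarities via `d = 1 − s/n_pairs`
(per-pair fraction), so groups of different sizes are comparable;
a max-count variant exists behind a flag. The embedding is authored
from scratch:

* **Initialization**: classical (Torgerson) scaling — double-centered
  squared dissimilarities, top-k eigenvectors, negative eigenvalues
  truncated at zero. Deterministic, so the whole fit is reproducible
  without random restarts.
* **Refinement**: SMACOF majorization (Guttman transform, uniform
  weights, diagonal excluded). Nonmetric mode is the default: each
  iteration refits disparities by isotonic regression of the current
  distances on the dissimilarity order (primary approach to ties,
  within-tie order by distance), because the stress benchmarks used to
  judge such solutions (< .01 near-perfect, < .05 excellent, < .1
  good) are Kruskal-style. Metric (ratio) mode is a flag.
* **Fit**: Kruskal stress-1, `sqrt(Σ(d̂ − dist)²/Σ dist²)`, computed
  from the *raw* isotonic fit so it is invariant under rotation,
  reflection, translation and uniform scaling of the configuration.
  The Guttman step itself uses norm-rescaled disparities, which keeps
  the update well scaled and the stress sequence non-increasing (a
  property the test suite asserts on every run).
* **Convergence**: stop when the stress decrease falls below 1e-9 or
  at 1000 iterations. On 20 points an iteration is trivially cheap, so
  the tight tolerance costs milliseconds.
* **Orientation**: solutions are rotated to principal axes; dimension
  1's sign makes the positive-valence centroid positive, dimension 2's
  sign makes its largest-magnitude coordinate positive. This is purely
  a reporting convention — stress is unchanged — chosen so that maps
  are comparable across age groups and the valence axis reads
  left-negative/right-positive.

Dimension 2 is deliberately left uninterpreted.

## Word-level predictors and models

Specificity is the entropy of a word's adult usage distribution over
vignettes, log base 10. Base 10 was chosen because the published
specificity ceiling (1.10 for the broadest word) is consistent with the
log10 ceiling log10(20) ≈ 1.301 and not with natural log (which allows
3.0). Entropy is undefined — `NA`, never 0 — for words adults never
produced, and flagged unreliable below 5 supporting tokens.

Regressions z-score the outcome and predictors, so single-predictor
coefficients are exactly Pearson correlations. For words lacking a
specificity value, the default is `na_action = "zero"`: re-deriving the
published model fits from the published word table shows that all of
them (R² = .64 vs .63, F = 63.9 vs 64.6 for the strongest model, and
the three other specificity-only fits, and the two-predictor youngest
group model with raw input frequency, β = .469/.476 vs .471/.478) are
reproduced only when the three entropy-less words are scored 0 and all
38 rows kept — which is also what the published df (1, 36) implies.
Complete-case exclusion (`"exclude"`) and ceiling imputation (`"max"`)
remain available; complete-case fitting gives a noticeably higher R²
(.74) on the same data, which is worth knowing when comparing to the
published numbers.

## The synthetic world

`default_design()` + `simulation_params()` state the world once:
group sizes 30/31/32/30 children and 27 adults, 20 vignettes (6 basic,
14 complex). Responses are generated per participant from a derived
seed stream, hierarchically:

| parameter | default | meaning |
|---|---|---|
| `vocab_curve` | .15/.30/.50/.70/1.00 | P(subordinate word in active vocabulary), by age |
| `basic_boost` | +.55 (capped at 1) | earlier acquisition of basic-category words |
| `dont_know_rate` | .25/.15/.08/.04/0 | no-answer probability, by age |
| `unspecific_rate` | .15 | valence-only label despite knowing the word |
| `overgeneralize_basic` | .50 | unknown word → basic word (else unspecific) |
| `salient_attractor_rate` | .50 | overgeneralization lands on sad/happy rather than the correct basic category |
| `valence_error_rate` | .02 | unspecific label with flipped valence |
| `synonym_rate` | .15 | stem surfaces as an inflected/synonymous form |
| `alternate_rate` | .20 | word realized as a semantically close stem |

The vocabulary curve and don't-know gradients encode the ordered
age structure the analyses assume; the salient-attractor component
reproduces the early dominance of *sad*/*happy* across vignettes that
the published frequency profiles show (sad ≈ 31% of the youngest
group's labels), which is what makes young children's matrices
genuinely less adult-like rather than merely sparser. Adults get
`vocab_curve = 1` and concentrated per-vignette profiles with small
alternate mass, so most adult words have low entropy. Rates without a
published anchor (synonym, alternate, unspecific, attractor) were set
once to values that give young children's profiles roughly the
published shape (unspecific categories ≈ 20% each in the youngest
group) and were not revisited.

What the generator does **not** emulate: real German free text (coding
is exercised through a synonym table, not morphology), vignette order
effects, follow-up questioning, inter-coder disagreement, and the exact
published group statistics (means 4.4–14.7, ρ .33–.55) — synthetic
convergence runs higher because the synthetic lexicon and answer
space are smaller than real children's. A green test therefore
establishes that the *estimators recover planted structure* (ordering,
separation, planted effect sizes), not that the generator reproduces
the published sample.

One operationalization deserves note: with n ≈ 30 per group the
adjacent-group differences in whole-matrix ρ are comparable to the
estimator's sampling noise — exactly as in the published middle pair,
which was not significant (z = −1.2). "Convergence increases with age"
is therefore asserted as a positive age trend and oldest > youngest in
a majority of ten seeded replicates, while the distinct-word-count
gradient, which is much larger than its noise, is asserted as a strict
ordering in a majority of seeds.

## Numerical and degenerate-input choices

* ANOVA is computed from group sums of squares; a zero total sum of
  squares (all counts identical) is flagged degenerate with `NA`
  statistics rather than 0/0, and constant-data post hoc t tests
  return `NA` rows.
* Spearman estimates delegate to `stats::cor(method = "spearman")`;
  the test suite checks them against an independent counting-based
  average-rank oracle, exhaustively on small count vectors and on
  1,000 random larger ones.
* `to_dissimilarity()` refuses off-diagonal cells with `n_pairs = 0`
  (no participant answered both vignettes) rather than imputing.
* Fisher's test refuses |r| ≥ 1 and n ≤ 3, where the transform or its
  variance degenerate.
* Fixture round-trips are byte-identical under a fixed seed; all
  randomness flows from one master seed via per-participant streams.

## Known limitations

* The lexicon is a curated table; answers outside it need a human
  pass, as in the original workflow.
* The published group-level results that depend on the archived raw
  data (exact means, ρs, per-group stress values) are not reproduced,
  only their recoverable structure is tested.
* The co-naming similarity treats one answer per vignette; designs
  allowing multiple labels per vignette would need a weighting rule.
* MDS stress benchmarks are conventions, not tests; with 20 points a
  two-dimensional nonmetric solution is flexible, and stress values
  should be compared only between runs of this package.
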