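# Study design: 20 illustrated emotion vignettes (6 basic + 14 complex
# emotions), four child age groups plus an adult reference group.

AGE_GROUPS <- c("4-5", "6-7", "8-9", "10-11", "adult")
CHILD_GROUPS <- AGE_GROUPS[1:4]

#' Construct a study design
#'
#' @param vignettes data.frame with columns `id` (1..n), `target_word`
#'   (canonical stem in the lexicon), `basic_category`, `valence` (+1/-1).
#' @param lexicon an [emotion_lexicon()].
#' @param group_sizes named integer vector, one entry per age group,
#'   ordered from youngest to oldest with the adult reference last.
#' @return An object of class `study_design`.
#' @export
study_design <- function(vignettes, lexicon, group_sizes) {
  stopifnot(is.data.frame(vignettes),
            all(c("id", "target_word", "basic_category", "valence") %in%
                  names(vignettes)))
  if (nrow(vignettes) < 1L) stop("design needs at least one vignette")
  if (!identical(as.integer(vignettes$id), seq_len(nrow(vignettes))))
    stop("vignette ids must be 1..n in order")
  if (!all(vignettes$target_word %in% lexicon$words$stem))
    stop("vignette target words must be lexicon stems")
  if (is.null(names(group_sizes)) || any(group_sizes < 1L))
    stop("group_sizes must be a named vector of counts >= 1")
  sizes <- stats::setNames(as.integer(round(group_sizes)), names(group_sizes))
  structure(list(vignettes = vignettes, lexicon = lexicon,
                 group_sizes = sizes, age_groups = names(group_sizes)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>", nrow(x$vignettes), "vignettes;",
      paste(sprintf("%s (n=%d)", x$age_groups, x$group_sizes),
            collapse = ", "), "\n")
  invisible(x)
}

#' The default vignette study design
#'
#' Twenty vignettes covering the six basic emotions (joy, fear, sadness,
#' anger, disgust, surprise) plus fourteen complex emotions subordinated
#' to them; four child groups (n = 30/31/32/30) and 27 adults. The first
#' two vignettes are joy and sadness, mirroring the fixed warm-up order
#' of the original instrument.
#'
#' @param lexicon lexicon to attach; defaults to [default_lexicon()].
#' @return A `study_design` with 20 vignettes and 150 participants.
#' @examples
#' d <- default_design()
#' nrow(d$vignettes)       # 20
#' d$group_sizes[["adult"]] # 27
#' @export
default_design <- function(lexicon = default_lexicon()) {
  v <- rbind(
    c(1,  "Freude",        "joy",       1),
    c(2,  "traurig",       "sadness",  -1),
    c(3,  "Angst",         "fear",     -1),
    c(4,  "wütend",   "anger",    -1),
    c(5,  "Ekel",          "disgust",  -1),
    c(6,  "überrascht", "surprise", 1),
    c(7,  "stolz",         "joy",       1),
    c(8,  "zufrieden",     "joy",       1),
    c(9,  "geborgen",      "joy",       1),
    c(10, "Liebe",         "joy",       1),
    c(11, "Vorfreude",     "joy",       1),
    c(12, "begierig",      "joy",       1),
    c(13, "frustriert",    "anger",    -1),
    c(14, "neidisch",      "anger",    -1),
    c(15, "eifersüchtig", "anger", -1),
    c(16, "einsam",        "sadness",  -1),
    c(17, "enttäuscht", "sadness", -1),
    c(18, "Sehnsucht",     "sadness",  -1),
    c(19, "besorgt",       "fear",     -1),
    c(20, "schuldig",      "sadness",  -1)
  )
  vignettes <- data.frame(id = as.integer(v[, 1]), target_word = v[, 2],
                          basic_category = v[, 3],
                          valence = as.integer(v[, 4]),
                          stringsAsFactors = FALSE)
  study_design(vignettes, lexicon,
               group_sizes = c("4-5" = 30L, "6-7" = 31L, "8-9" = 32L,
                               "10-11" = 30L, "adult" = 27L))
}

#' Simulation parameters for the synthetic response generator
#'
#' The defaults encode the age-graded regularities the analyses assume:
#' subordinate emotion words enter the active vocabulary with increasing
#' probability across age (`vocab_curve`), unknown words are replaced by
#' the basic-category word or a valence-only unspecific label
#' (`overgeneralize_basic`), no-answer rates fall with age
#' (`dont_know_rate`), and valence errors are rare.
#'
#' @param vocab_curve named probabilities, per age group, that a
#'   subordinate (complex-emotion) word is in the active vocabulary;
#'   must be non-decreasing from youngest to oldest.
#' @param basic_boost added to `vocab_curve` (capped at 1) for
#'   basic-category words, which are acquired earlier.
#' @param overgeneralize_basic probability that an unknown target is
#'   replaced by its basic-category word rather than an unspecific label.
#' @param unspecific_rate probability of producing a valence-only label
#'   even when the target is known.
#' @param dont_know_rate named per-group no-answer probabilities;
#'   non-increasing across the age order.
#' @param valence_error_rate probability that an unspecific label takes
#'   the wrong valence.
#' @param salient_attractor_rate when overgeneralizing, probability of
#'   reaching for the earliest-acquired valence-matched basic word
#'   ("traurig" / "fröhlich") instead of the vignette's own
#'   basic-category word; reproduces the early dominance of sad/happy
#'   over all vignettes.
#' @param synonym_rate probability a produced stem surfaces as an
#'   inflected/synonymous form rather than the stem itself.
#' @param alternate_rate probability a known word is realised as a
#'   semantically close lexicon stem instead of the target (the "small
#'   synonym mass" that spreads adult usage over a few words).
#' @param seed master integer seed; per-participant streams are derived
#'   from it deterministically.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(
    vocab_curve = c("4-5" = 0.15, "6-7" = 0.30, "8-9" = 0.50,
                    "10-11" = 0.70, "adult" = 1.00),
    basic_boost = 0.55,
    overgeneralize_basic = 0.5,
    unspecific_rate = 0.15,
    dont_know_rate = c("4-5" = 0.25, "6-7" = 0.15, "8-9" = 0.08,
                       "10-11" = 0.04, "adult" = 0.00),
    valence_error_rate = 0.02,
    salient_attractor_rate = 0.5,
    synonym_rate = 0.15,
    alternate_rate = 0.20,
    seed = 1L) {
  rates <- c(vocab_curve, overgeneralize_basic, unspecific_rate,
             dont_know_rate, valence_error_rate, salient_attractor_rate,
             synonym_rate, alternate_rate, basic_boost)
  if (any(rates < 0) || any(rates > 1))
    stop("all rates must lie in [0, 1]")
  if (is.unsorted(vocab_curve))
    stop("vocab_curve must be non-decreasing across the age order")
  if (is.unsorted(rev(dont_know_rate)))
    stop("dont_know_rate must be non-increasing across the age order")
  structure(list(vocab_curve = vocab_curve, basic_boost = basic_boost,
                 overgeneralize_basic = overgeneralize_basic,
                 unspecific_rate = unspecific_rate,
                 dont_know_rate = dont_know_rate,
                 valence_error_rate = valence_error_rate,
                 salient_attractor_rate = salient_attractor_rate,
                 synonym_rate = synonym_rate,
                 alternate_rate = alternate_rate,
                 seed = as.integer(seed)),
            class = "simulation_params")
}
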