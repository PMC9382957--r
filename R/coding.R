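# Coding scheme for free answers: stem reduction via lexicon lookup,
# valence-only labels to the two unspecific pseudo-categories, negations
# of specific emotions to the opposite-valence unspecific category,
# physiological/cognitive/behavioral descriptors to not_emotion.

UNSPECIFIC_POS <- "unspecific_positive"
UNSPECIFIC_NEG <- "unspecific_negative"
NOT_EMOTION <- "not_emotion"
NO_ANSWER <- "no_answer"

#' Non-word code labels
#'
#' The two unspecific pseudo-word categories, valence-only labels treated
#' as words throughout the analyses.
#' @return character vector of the two category labels.
#' @export
unspecific_codes <- function() c(UNSPECIFIC_POS, UNSPECIFIC_NEG)

normalize_answer <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(x))
  tolower(x)
}

strip_negation <- function(x, prefixes) {
  for (p in prefixes) {
    if (startsWith(x, paste0(p, " ")))
      return(substring(x, nchar(p) + 2L))
  }
  NA_character_
}

code_one <- function(answer, lexicon) {
  a <- normalize_answer(answer)
  if (a %in% lexicon$dont_know_markers) return(NO_ANSWER)
  # negation first: "nicht traurig" must not fall through to "traurig"
  rest <- strip_negation(a, lexicon$negation_prefixes)
  if (!is.na(rest)) {
    stem <- lexicon$synonym_map[rest]
    if (!is.na(stem)) {  # negated specific emotion -> opposite valence
      v <- lexicon$words$valence[match(stem, lexicon$words$stem)]
      return(if (v > 0) UNSPECIFIC_NEG else UNSPECIFIC_POS)
    }
    if (rest %in% lexicon$unspecific_positive_forms) return(UNSPECIFIC_NEG)
    if (rest %in% lexicon$unspecific_negative_forms) return(UNSPECIFIC_POS)
    return(NOT_EMOTION)
  }
  if (a %in% lexicon$unspecific_positive_forms) return(UNSPECIFIC_POS)
  if (a %in% lexicon$unspecific_negative_forms) return(UNSPECIFIC_NEG)
  stem <- lexicon$synonym_map[a]
  if (!is.na(stem)) return(unname(stem))
  NOT_EMOTION
}

#' Code a single raw answer
#'
#' Applies the coding scheme: surface forms sharing a stem collapse to
#' that canonical stem; valence-only descriptions ("gut", "schlecht")
#' map to the unspecific categories; a negated specific emotion ("nicht
#' traurig") maps to the unspecific category of the opposite valence;
#' physiological/cognitive/behavioral descriptors and unknown strings
#' map to `not_emotion`; empty or don't-know answers to `no_answer`.
#'
#' @param answer a free answer string.
#' @param lexicon an [emotion_lexicon()].
#' @param warn_unknown warn when an unrecognized string is coded
#'   `not_emotion` (the curated list may need extending).
#' @return A single code: a lexicon stem, `"unspecific_positive"`,
#'   `"unspecific_negative"`, `"not_emotion"`, or `"no_answer"`.
#' @examples
#' lex <- default_lexicon()
#' code_answer("traurige", lex)      # "traurig"
#' code_answer("nicht gut", lex)     # "unspecific_negative"
#' code_answer("nicht traurig", lex) # "unspecific_positive"
#' @export
code_answer <- function(answer, lexicon, warn_unknown = TRUE) {
  code <- code_one(answer, lexicon)
  if (warn_unknown && code == NOT_EMOTION) {
    a <- normalize_answer(answer)
    if (!(a %in% lexicon$non_emotion_markers))
      warning("unrecognized answer coded not_emotion: '", answer, "'",
              call. = FALSE)
  }
  code
}

#' Code a dataset of raw responses
#'
#' Order-preserving; one coded record per raw record.
#'
#' @param responses raw responses (see [simulate_responses()] /
#'   [read_fixture()]).
#' @param lexicon an [emotion_lexicon()].
#' @param design optional [study_design()]; when given, vignette ids and
#'   age-group labels are validated against it.
#' @param warn_unknown see [code_answer()].
#' @return The input data.frame with an added `code` column.
#' @export
code_dataset <- function(responses, lexicon, design = NULL,
                         warn_unknown = TRUE) {
  stopifnot(is.data.frame(responses))
  if (nrow(responses) == 0L) {
    responses$code <- character(0)
    return(responses)
  }
  if (!is.null(design)) {
    bad_v <- setdiff(unique(responses$vignette_id), design$vignettes$id)
    if (length(bad_v))
      stop("unknown vignette id(s): ", paste(bad_v, collapse = ", "))
    bad_g <- setdiff(unique(responses$age_group), design$age_groups)
    if (length(bad_g))
      stop("unknown age group(s): ", paste(bad_g, collapse = ", "))
  }
  # answers repeat heavily; code each distinct string once
  uniq <- unique(responses$answer)
  codes <- vapply(uniq, code_answer, character(1), lexicon = lexicon,
                  warn_unknown = warn_unknown, USE.NAMES = FALSE)
  responses$code <- codes[match(responses$answer, uniq)]
  responses
}

word_codes <- function(codes) {
  codes[!codes %in% c(NOT_EMOTION, NO_ANSWER)]
}

#' Emotion word list: words used by enough distinct participants
#'
#' Pools all age groups and keeps every emotion word (canonical stems and
#' the two unspecific pseudo-words) produced by at least
#' `min_participants` distinct participants. Ordered by descending total
#' token frequency, ties broken alphabetically.
#'
#' @param coded coded responses (see [code_dataset()]).
#' @param min_participants inclusion threshold (default 5, the
#'   reliability bound also used for entropy estimation).
#' @return character vector of word codes.
#' @export
build_word_list <- function(coded, min_participants = 5L) {
  stopifnot(is.data.frame(coded), nrow(coded) > 0L, "code" %in% names(coded))
  if (min_participants < 1L) stop("min_participants must be >= 1")
  keep <- !coded$code %in% c(NOT_EMOTION, NO_ANSWER)
  d <- coded[keep, c("participant_id", "code")]
  if (nrow(d) == 0L) return(character(0))
  n_part <- tapply(d$participant_id, d$code,
                   function(p) length(unique(p)))
  freq <- table(d$code)
  eligible <- names(n_part)[n_part >= min_participants]
  freq <- freq[eligible]
  eligible[order(-as.integer(freq), eligible, method = "radix")]
}

#' All emotion words produced anywhere in a coded dataset
#'
#' The full column universe for production matrices (every word produced
#' across the total sample, not just the thresholded word list).
#' Ordered by descending total frequency, ties alphabetical.
#'
#' @inheritParams build_word_list
#' @return character vector of word codes.
#' @export
words_produced <- function(coded) {
  build_word_list(coded, min_participants = 1L)
}
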