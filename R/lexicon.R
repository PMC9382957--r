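# Curated German emotion lexicon: canonical stems, surface-form synonym map,
# valence, basic-category membership, unspecific (valence-only) label forms,
# negation prefixes and non-emotion descriptor markers.

#' Construct an emotion lexicon
#'
#' An emotion lexicon maps free answer strings onto canonical emotion-word
#' stems and carries the metadata the coding scheme needs: the valence of
#' every stem, which basic emotion category (joy, fear, sadness, anger,
#' disgust, surprise) each stem belongs to, the surface forms counted as
#' valence-only "unspecific" labels, negation prefixes, and descriptors of
#' physiological/cognitive/behavioral states that are not emotion words.
#'
#' @param words data.frame with columns `stem`, `english`, `valence`
#'   (+1/-1), `basic_category`, `is_basic` (logical).
#' @param synonym_map named character vector mapping lower-cased surface
#'   forms to canonical stems. Stems themselves are always added.
#' @param alternates named list: stem -> character vector of semantically
#'   close stems a speaker may produce instead (used by the simulator).
#' @param unspecific_positive_forms,unspecific_negative_forms surface forms
#'   coded as the valence-only pseudo-words.
#' @param negation_prefixes prefixes that negate the following word
#'   (e.g. "nicht"); negating a specific emotion yields the unspecific
#'   category of the opposite valence.
#' @param non_emotion_markers surface forms describing physiological,
#'   cognitive or behavioral states, coded as non-emotion answers.
#' @param dont_know_markers surface forms (and "") coded as no answer.
#' @return An object of class `emotion_lexicon`.
#' @export
emotion_lexicon <- function(words, synonym_map = character(),
                            alternates = list(),
                            unspecific_positive_forms = character(),
                            unspecific_negative_forms = character(),
                            negation_prefixes = c("nicht", "gar nicht"),
                            non_emotion_markers = character(),
                            dont_know_markers = c("", "weiss nicht")) {
  stopifnot(is.data.frame(words),
            all(c("stem", "valence", "basic_category", "is_basic") %in%
                  names(words)))
  if (anyDuplicated(words$stem))
    stop("duplicate stems in lexicon")
  if (!all(words$valence %in% c(-1L, 1L)))
    stop("valence must be +1 or -1 for every stem")
  # every synonym must resolve to a known stem
  bad <- setdiff(unname(synonym_map), words$stem)
  if (length(bad))
    stop("synonyms map to unknown stems: ", paste(bad, collapse = ", "))
  bad_alt <- setdiff(unlist(alternates), words$stem)
  if (length(bad_alt))
    stop("alternates reference unknown stems: ", paste(bad_alt, collapse = ", "))
  # stems are synonyms of themselves (case-insensitive lookup key)
  self <- structure(words$stem, names = tolower(words$stem))
  synonym_map <- c(self, synonym_map[setdiff(names(synonym_map), names(self))])
  structure(list(
    words = words,
    synonym_map = synonym_map,
    alternates = alternates,
    unspecific_positive_forms = tolower(unspecific_positive_forms),
    unspecific_negative_forms = tolower(unspecific_negative_forms),
    negation_prefixes = tolower(negation_prefixes),
    non_emotion_markers = tolower(non_emotion_markers),
    dont_know_markers = tolower(dont_know_markers)
  ), class = "emotion_lexicon")
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  cat("<emotion_lexicon>", nrow(x$words), "stems,",
      length(x$synonym_map), "surface forms,",
      sum(x$words$is_basic), "basic-category words\n")
  invisible(x)
}

#' Stem valence lookup
#' @param lexicon an [emotion_lexicon()].
#' @param stems character vector of canonical stems.
#' @return integer vector of +1/-1.
#' @export
stem_valence <- function(lexicon, stems) {
  v <- lexicon$words$valence[match(stems, lexicon$words$stem)]
  if (anyNA(v)) stop("unknown stem(s): ",
                     paste(stems[is.na(v)], collapse = ", "))
  v
}

# The default lexicon covers the 36 word stems of the study's word
# inventory (plus the two unspecific pseudo-categories handled by the
# coder, not listed here as stems) with English glosses, valence, and
# basic-category membership following the hierarchical model of emotion
# concepts (basic emotions superordinate to complex ones).
default_lexicon_words <- function() {
  w <- rbind(
    # stem, english, valence, basic_category, is_basic
    c("Freude",        "joy",          1, "joy",      TRUE),
    c("froh",          "glad",         1, "joy",      FALSE),
    c("fröhlich", "happy",        1, "joy",      FALSE),
    c("glücklich","happy",        1, "joy",      FALSE),
    c("stolz",         "proud",        1, "joy",      FALSE),
    c("zufrieden",     "satisfied",    1, "joy",      FALSE),
    c("geborgen",      "safe",         1, "joy",      FALSE),
    c("Liebe",         "love",         1, "joy",      FALSE),
    c("begeistert",    "enthusiastic", 1, "joy",      FALSE),
    c("begierig",      "avid",         1, "joy",      FALSE),
    c("Vorfreude",     "anticipation", 1, "joy",      FALSE),
    c("aufgeregt",     "excited",      1, "joy",      FALSE),
    c("überrascht","surprised",   1, "surprise", TRUE),
    c("Angst",         "fear",        -1, "fear",     TRUE),
    c("besorgt",       "worried",     -1, "fear",     FALSE),
    c("erschrocken",   "scared",      -1, "fear",     FALSE),
    c("Grusel",        "horror",      -1, "fear",     FALSE),
    c("wütend",   "furious",     -1, "anger",    TRUE),
    c("Ärger",    "anger",       -1, "anger",    FALSE),
    c("sauer",         "angry",       -1, "anger",    FALSE),
    c("genervt",       "annoyed",     -1, "anger",    FALSE),
    c("frustriert",    "frustrated",  -1, "anger",    FALSE),
    c("neidisch",      "envious",     -1, "anger",    FALSE),
    c("eifersüchtig", "jealous", -1, "anger",    FALSE),
    c("Ekel",          "disgust",     -1, "disgust",  TRUE),
    c("traurig",       "sad",         -1, "sadness",  TRUE),
    c("unglücklich", "unhappy",  -1, "sadness",  FALSE),
    c("Kummer",        "sorrow",      -1, "sadness",  FALSE),
    c("einsam",        "lonely",      -1, "sadness",  FALSE),
    c("enttäuscht", "disappointed", -1, "sadness", FALSE),
    c("Sehnsucht",     "longing",     -1, "sadness",  FALSE),
    c("verzweifelt",   "desperate",   -1, "sadness",  FALSE),
    c("Scham",         "shame",       -1, "sadness",  FALSE),
    c("schuldig",      "guilty",      -1, "sadness",  FALSE),
    c("peinlich",      "embarrassed", -1, "sadness",  FALSE),
    c("Reue",          "remorse",     -1, "sadness",  FALSE)
  )
  data.frame(stem = w[, 1], english = w[, 2],
             valence = as.integer(w[, 3]), basic_category = w[, 4],
             is_basic = as.logical(w[, 5]), stringsAsFactors = FALSE)
}

#' The packaged default emotion lexicon
#'
#' German lexicon covering the study's 36 emotion-word stems with a
#' modest inflected/synonymous surface-form table, the valence-only
#' unspecific label forms, negation prefixes and common non-emotion
#' descriptors. Extensible: construct your own with [emotion_lexicon()].
#'
#' @return An `emotion_lexicon`.
#' @examples
#' lex <- default_lexicon()
#' stem_valence(lex, c("traurig", "Freude"))
#' @export
default_lexicon <- function() {
  syn <- c(
    # inflected / derived surface forms -> canonical stem
    "ängstlich"    = "Angst",
    "angst"             = "Angst",
    "ärgerlich"    = "Ärger",
    "ärger"        = "Ärger",
    "arger"             = "Ärger",
    "traurige"          = "traurig",
    "trauer"            = "traurig",
    "freut sich"        = "Freude",
    "freudig"           = "Freude",
    "freude"            = "Freude",
    "ekelt sich"        = "Ekel",
    "eklig"             = "Ekel",
    "ekel"              = "Ekel",
    "gruselig"          = "Grusel",
    "grusel"            = "Grusel",
    "wütende"      = "wütend",
    "wut"               = "wütend",
    "überraschung" = "überrascht",
    "stolze"            = "stolz",
    "liebe"             = "Liebe",
    "verliebt"          = "Liebe",
    "kummer"            = "Kummer",
    "sehnsucht"         = "Sehnsucht",
    "sehnsüchtig"  = "Sehnsucht",
    "vorfreude"         = "Vorfreude",
    "reue"              = "Reue",
    "reuig"             = "Reue",
    "scham"             = "Scham",
    "schämt sich"  = "Scham",
    "besorgte"          = "besorgt",
    "sorge"             = "besorgt",
    "neid"              = "neidisch",
    "eifersucht"        = "eifersüchtig",
    "frust"             = "frustriert",
    "frustiert"         = "frustriert",
    "enttäuschung" = "enttäuscht",
    "verzweiflung"      = "verzweifelt",
    "schuld"            = "schuldig",
    "peinlich berührt" = "peinlich",
    "geborgenheit"      = "geborgen",
    "zufriedenheit"     = "zufrieden",
    "begeisterung"      = "begeistert",
    "gier"              = "begierig",
    "aufregung"         = "aufgeregt",
    "genervte"          = "genervt",
    "einsamkeit"        = "einsam",
    "unglückliche" = "unglücklich"
  )
  alt <- list(
    "Freude"        = c("froh", "fröhlich", "glücklich"),
    "traurig"       = c("unglücklich", "Kummer", "verzweifelt"),
    "Angst"         = c("erschrocken", "Grusel"),
    "wütend"   = c("sauer", "Ärger", "genervt"),
    "überrascht" = c("aufgeregt"),
    "zufrieden"     = c("glücklich"),
    "Vorfreude"     = c("aufgeregt", "Freude"),
    "begierig"      = c("aufgeregt", "begeistert"),
    "frustriert"    = c("wütend", "genervt", "enttäuscht"),
    "neidisch"      = c("eifersüchtig"),
    "eifersüchtig" = c("neidisch"),
    "einsam"        = c("traurig", "verzweifelt"),
    "enttäuscht" = c("traurig"),
    "Sehnsucht"     = c("traurig", "Kummer"),
    "besorgt"       = c("Angst"),
    "schuldig"      = c("Scham", "Reue", "peinlich")
  )
  emotion_lexicon(
    words = default_lexicon_words(),
    synonym_map = syn,
    alternates = alt,
    unspecific_positive_forms = c("gut", "schön", "lustig", "toll",
                                  "super", "prima"),
    unspecific_negative_forms = c("schlecht", "böse", "blöd",
                                  "doof", "schlimm", "mies"),
    negation_prefixes = c("nicht so", "gar nicht", "nicht"),
    non_emotion_markers = c("müde", "hungrig", "durstig", "krank",
                            "nachdenklich", "unverstanden", "allein",
                            "hell", "lacht", "weint", "schreit"),
    dont_know_markers = c("", "weiss nicht", "weiß nicht",
                          "keine ahnung", "?")
  )
}

#' Write / read a lexicon as JSON
#'
#' @param lexicon an `emotion_lexicon`.
#' @param path file path.
#' @return `read_lexicon()` returns an `emotion_lexicon`;
#'   `write_lexicon()` returns `path` invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  x <- unclass(lexicon)
  x$synonym_map <- as.list(x$synonym_map)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- unlist(x$synonym_map)
  # drop self-entries; the constructor re-adds them
  emotion_lexicon(
    words = as.data.frame(x$words),
    synonym_map = syn,
    alternates = lapply(x$alternates, as.character),
    unspecific_positive_forms = x$unspecific_positive_forms,
    unspecific_negative_forms = x$unspecific_negative_forms,
    negation_prefixes = x$negation_prefixes,
    non_emotion_markers = x$non_emotion_markers,
    dont_know_markers = x$dont_know_markers
  )
}
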