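# Synthetic free-labeling sessions. Responses are generated at the
# coded-token level (lexicon stems, valence-only labels, no-answers) with
# a small surface-form layer (inflections/synonyms) so the coding module
# has real work to do. One master seed; each participant gets a derived
# stream so datasets are reproducible participant by participant.

NO_ANSWER_MARKER <- ""

participant_seed <- function(seed, idx) {
  # keep derived seeds positive and well below 2^31
  (as.integer(seed) %% 1000003L) * 2011L + 13L * idx
}

# pick a surface form for a stem: mostly the stem itself, sometimes one
# of its mapped synonyms (exercises stem reduction downstream)
surface_form <- function(stem, lexicon, synonym_rate) {
  forms <- names(lexicon$synonym_map)[lexicon$synonym_map == stem &
                                        names(lexicon$synonym_map) != tolower(stem)]
  if (length(forms) && stats::runif(1) < synonym_rate)
    sample(forms, 1L)
  else
    stem
}

unspecific_label <- function(valence, lexicon, flip_prob) {
  if (flip_prob > 0 && stats::runif(1) < flip_prob) valence <- -valence
  forms <- if (valence > 0) lexicon$unspecific_positive_forms
           else lexicon$unspecific_negative_forms
  sample(forms, 1L)
}

#' Simulate free-labeling responses for a whole study
#'
#' Generates one answer per participant x vignette, in presentation
#' order, following a hierarchical scheme: a no-answer with the group's
#' don't-know probability; otherwise a valence-only unspecific label with
#' probability `unspecific_rate`; otherwise the target word (or a close
#' alternate / inflected surface form) if it is in the participant's
#' vocabulary; otherwise an overgeneralization to the vignette's
#' basic-category word or an unspecific label. Children stop contributing
#' answers after five consecutive no-answers (discontinue rule). Word
#' knowledge is drawn once per participant, so usage is consistent across
#' vignettes sharing a target.
#'
#' @param design a [study_design()].
#' @param params a [simulation_params()].
#' @return data.frame of raw responses with columns `participant_id`,
#'   `age_group`, `vignette_id`, `answer` (`""` = no answer).
#' @examples
#' d <- default_design()
#' r <- simulate_responses(d, simulation_params(seed = 1))
#' nrow(r)  # 150 participants x 20 vignettes
#' @export
simulate_responses <- function(design, params = simulation_params()) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "simulation_params"))
  if (nrow(design$vignettes) == 0L) stop("empty design")
  missing_groups <- setdiff(design$age_groups, names(params$vocab_curve))
  if (length(missing_groups))
    stop("params lack rates for group(s): ",
         paste(missing_groups, collapse = ", "))
  lex <- design$lexicon
  vig <- design$vignettes
  targets <- unique(vig$target_word)
  basic_of <- stats::setNames(lex$words$stem[lex$words$is_basic],
                              lex$words$basic_category[lex$words$is_basic])
  out <- vector("list", sum(design$group_sizes))
  idx <- 0L
  for (g in design$age_groups) {
    is_child <- g != "adult"
    p_vocab <- params$vocab_curve[[g]]
    p_dk <- params$dont_know_rate[[g]]
    for (i in seq_len(design$group_sizes[[g]])) {
      idx <- idx + 1L
      set.seed(participant_seed(params$seed, idx))
      pid <- sprintf("%s_%02d", gsub("-", "_", g), i)
      is_basic_target <- lex$words$is_basic[match(targets, lex$words$stem)]
      p_known <- ifelse(is_basic_target,
                        pmin(1, p_vocab + params$basic_boost), p_vocab)
      known <- stats::setNames(stats::runif(length(targets)) < p_known,
                               targets)
      ans <- character(nrow(vig))
      consec_missing <- 0L
      discontinued <- FALSE
      for (v in seq_len(nrow(vig))) {
        if (discontinued || stats::runif(1) < p_dk) {
          ans[v] <- NO_ANSWER_MARKER
          consec_missing <- consec_missing + 1L
          if (is_child && consec_missing >= 5L) discontinued <- TRUE
          next
        }
        consec_missing <- 0L
        target <- vig$target_word[v]
        if (stats::runif(1) < params$unspecific_rate) {
          ans[v] <- unspecific_label(vig$valence[v], lex,
                                     params$valence_error_rate)
        } else if (known[[target]]) {
          stem <- target
          alts <- lex$alternates[[target]]
          if (length(alts) && stats::runif(1) < params$alternate_rate)
            stem <- sample(alts, 1L)
          ans[v] <- surface_form(stem, lex, params$synonym_rate)
        } else if (stats::runif(1) < params$overgeneralize_basic) {
          # young children reach for the earliest-acquired basic word of
          # matching valence (sad/happy) about as often as the correct
          # basic category
          stem <- if (stats::runif(1) < params$salient_attractor_rate) {
            if (vig$valence[v] > 0) "fröhlich" else "traurig"
          } else basic_of[[vig$basic_category[v]]]
          ans[v] <- surface_form(stem, lex, params$synonym_rate)
        } else {
          ans[v] <- unspecific_label(vig$valence[v], lex,
                                     params$valence_error_rate)
        }
      }
      out[[idx]] <- data.frame(participant_id = pid, age_group = g,
                               vignette_id = vig$id, answer = ans,
                               stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a raw-response fixture
#'
#' UTF-8 comma-delimited text with header
#' `participant_id,age_group,vignette_id,answer`; the empty string marks
#' a no-answer. Round-trips losslessly.
#'
#' @param responses data.frame as returned by [simulate_responses()].
#' @param path file path.
#' @return `write_fixture()` returns `path` invisibly; `read_fixture()`
#'   returns the responses data.frame.
#' @export
write_fixture <- function(responses, path) {
  stopifnot(is.data.frame(responses), nrow(responses) > 0L,
            all(c("participant_id", "age_group", "vignette_id",
                  "answer") %in% names(responses)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(responses[c("participant_id", "age_group",
                               "vignette_id", "answer")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  res <- utils::read.csv(path, colClasses = c(participant_id = "character",
                                              age_group = "character",
                                              vignette_id = "integer",
                                              answer = "character"),
                         na.strings = character(), encoding = "UTF-8")
  res
}
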