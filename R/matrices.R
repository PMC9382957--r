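# Production matrices (vignette x word participant tallies), frequency
# profiles, and vignette co-naming similarity matrices.

#' Build a production matrix for one age group
#'
#' Cell (v, w) counts the participants in the group whose coded answer to
#' vignette v is word w. `no_answer` and `not_emotion` codes contribute
#' nothing. The word universe (columns) must be fixed study-wide so that
#' matrices of different groups are comparable; by default it is every
#' word produced across the total coded sample ([words_produced()]).
#'
#' @param coded coded responses for the whole study.
#' @param group age-group label to tally.
#' @param words ordered character vector of word codes (columns).
#' @param vignette_ids ordered vignette ids (rows); defaults to the ids
#'   present in `coded`.
#' @return An object of class `production_matrix`: list with `age_group`,
#'   `vignette_ids`, `words`, and the integer `counts` matrix.
#' @export
production_matrix <- function(coded, group, words = words_produced(coded),
                              vignette_ids = sort(unique(coded$vignette_id))) {
  stopifnot(is.data.frame(coded), "code" %in% names(coded))
  if (!group %in% coded$age_group)
    stop("age group '", group, "' absent from data")
  d <- coded[coded$age_group == group & coded$code %in% words, ]
  counts <- matrix(0L, nrow = length(vignette_ids), ncol = length(words),
                   dimnames = list(vignette_ids, words))
  if (nrow(d)) {
    # one coded answer per participant x vignette: tabulating rows is
    # the same as counting distinct participants
    tab <- table(factor(d$vignette_id, levels = vignette_ids),
                 factor(d$code, levels = words))
    counts[] <- as.integer(tab)
  }
  structure(list(age_group = group, vignette_ids = vignette_ids,
                 words = words, counts = counts),
            class = "production_matrix")
}

#' @export
print.production_matrix <- function(x, ...) {
  cat("<production_matrix>", x$age_group, ":", nrow(x$counts),
      "vignettes x", ncol(x$counts), "words,",
      sum(x$counts), "tokens\n")
  invisible(x)
}

#' Production-frequency profile of a group
#'
#' Percentage of the group's emotion-word tokens falling on each word.
#'
#' @param matrix a [production_matrix()].
#' @return named numeric vector summing to 100.
#' @export
frequency_profile <- function(matrix) {
  stopifnot(inherits(matrix, "production_matrix"))
  tot <- sum(matrix$counts)
  if (tot == 0L) stop("no emotion-word tokens in group '",
                      matrix$age_group, "'")
  100 * colSums(matrix$counts) / tot
}

#' Vignette co-naming similarity matrix for one age group
#'
#' For every participant and unordered vignette pair (i, j), cell s[i, j]
#' is incremented when the participant gave the same coded emotion word
#' (or, by default, the same unspecific category) to both vignettes.
#' `no_answer` and `not_emotion` never match. `n_pairs[i, j]` counts the
#' participants with codable answers to both vignettes; the diagonal
#' holds the per-vignette codable-answer counts and is excluded from
#' scaling input.
#'
#' @param coded coded responses.
#' @param group age-group label.
#' @param vignette_ids ordered vignette ids.
#' @param match_unspecific should the two unspecific categories count as
#'   matchable words (default TRUE)?
#' @return An object of class `similarity_matrix` with fields
#'   `age_group`, `vignette_ids`, `s`, `n_pairs`.
#' @export
similarity_matrix <- function(coded, group,
                              vignette_ids = sort(unique(coded$vignette_id)),
                              match_unspecific = TRUE) {
  stopifnot(is.data.frame(coded), "code" %in% names(coded))
  if (!group %in% coded$age_group)
    stop("age group '", group, "' absent from data")
  d <- coded[coded$age_group == group, ]
  nv <- length(vignette_ids)
  s <- matrix(0L, nv, nv, dimnames = list(vignette_ids, vignette_ids))
  n_pairs <- matrix(0L, nv, nv, dimnames = list(vignette_ids, vignette_ids))
  uncodable <- c(NOT_EMOTION, NO_ANSWER)
  if (!match_unspecific) uncodable <- c(uncodable, unspecific_codes())
  for (pid in unique(d$participant_id)) {
    p <- d[d$participant_id == pid, ]
    code_at <- stats::setNames(rep(NA_character_, nv), vignette_ids)
    code_at[as.character(p$vignette_id)] <- p$code
    codable <- !is.na(code_at) & !code_at %in% uncodable
    n_pairs <- n_pairs + outer(codable, codable, "&")
    same <- outer(code_at, code_at, "==") & outer(codable, codable, "&")
    same[is.na(same)] <- FALSE
    s <- s + same
  }
  structure(list(age_group = group, vignette_ids = vignette_ids,
                 s = s, n_pairs = n_pairs),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- upper.tri(x$s)
  cat("<similarity_matrix>", x$age_group, ":", nrow(x$s), "vignettes;",
      "mean off-diagonal co-naming", round(mean(x$s[off]), 2), "\n")
  invisible(x)
}

#' Serialize a labeled matrix as delimited text
#'
#' @param x a `production_matrix` or `similarity_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  m <- if (inherits(x, "production_matrix")) x$counts
       else if (inherits(x, "similarity_matrix")) x$s
       else stop("unsupported object")
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
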