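# Word-level predictors of ease of learning: specificity (Shannon
# entropy of a word's usage distribution over vignettes in the adult
# reference group, log base 10) and caregiver input frequency; plus the
# standardized regressions of production frequency / degree of
# convergence on these predictors.

#' Word specificity: entropy of adult usage over vignettes
#'
#' H(w) = -sum_v p(v) log10 p(v), where p(v) is the relative frequency
#' with which adults used word w for vignette v. Words concentrated on
#' one vignette get H = 0 (maximally specific); a word used uniformly
#' over all 20 vignettes reaches the ceiling log10(20) ~ 1.301. Words
#' the adults never produced have no defined entropy (`NA`, not 0).
#' Entropy is considered unreliable when fewer than `min_tokens` tokens
#' support it (a warning is raised).
#'
#' @param adult the adult group's [production_matrix()].
#' @param stem word code (column of the matrix).
#' @param base logarithm base (10 by default).
#' @param min_tokens reliability bound (default 5).
#' @return entropy value (numeric), `NA` if the word is unused; the
#'   number of vignettes with p > 0 is attached as attribute `support`.
#' @examples
#' # a word used for exactly one vignette has entropy 0
#' @export
word_entropy <- function(adult, stem, base = 10, min_tokens = 5L) {
  stopifnot(inherits(adult, "production_matrix"))
  if (!stem %in% adult$words) stop("word '", stem, "' not in matrix")
  counts <- adult$counts[, stem]
  total <- sum(counts)
  if (total == 0L) return(structure(NA_real_, support = 0L))
  if (total < min_tokens)
    warning("entropy for '", stem, "' rests on ", total,
            " tokens (< ", min_tokens, "); unreliable", call. = FALSE)
  p <- counts[counts > 0] / total
  structure(-sum(p * log(p, base = base)), support = length(p))
}

#' Entropy table for all words of a production matrix
#'
#' @inheritParams word_entropy
#' @return data.frame with `word`, `entropy`, `support`, `n_tokens`,
#'   `reliable`.
#' @export
entropy_table <- function(adult, base = 10, min_tokens = 5L) {
  stopifnot(inherits(adult, "production_matrix"))
  n_tokens <- colSums(adult$counts)
  h <- vapply(adult$words, function(w)
    suppressWarnings(as.numeric(word_entropy(adult, w, base, min_tokens))),
    numeric(1))
  support <- colSums(adult$counts > 0)
  data.frame(word = adult$words, entropy = unname(h[adult$words]),
             support = unname(support[adult$words]),
             n_tokens = unname(n_tokens[adult$words]),
             reliable = unname(n_tokens[adult$words] >= min_tokens),
             stringsAsFactors = FALSE)
}

#' Load a caregiver input-frequency table
#'
#' Reads a delimited file of (surface_form, count) rows emulating summed
#' child-directed-speech counts, and aggregates the counts of all
#' surface forms mapping to each lexicon stem. Stems with no row get
#' count 0, with a warning.
#'
#' @param path delimited text file with columns `surface_form`, `count`.
#' @param lexicon an [emotion_lexicon()].
#' @return named integer vector, one count per lexicon stem.
#' @export
load_input_frequency <- function(path, lexicon) {
  d <- utils::read.csv(path, colClasses = c(surface_form = "character",
                                            count = "numeric"),
                       encoding = "UTF-8")
  if (!all(c("surface_form", "count") %in% names(d)))
    stop("expected columns surface_form, count")
  if (anyNA(d$count) || any(d$count < 0))
    stop("malformed counts in ", path)
  stems <- lexicon$words$stem
  mapped <- lexicon$synonym_map[tolower(d$surface_form)]
  known <- !is.na(mapped)
  agg <- tapply(d$count[known], mapped[known], sum)
  out <- stats::setNames(rep(0, length(stems)), stems)
  out[names(agg)] <- agg
  missing <- stems[!stems %in% names(agg)]
  if (length(missing))
    warning("no input-frequency rows for stem(s): ",
            paste(missing, collapse = ", "), "; set to 0", call. = FALSE)
  out
}

#' Word-level measures table
#'
#' Assembles the per-word measures used in the ease-of-learning models:
#' production frequency (%) per age group, degree of convergence with
#' adult usage (per-word Spearman rho) per child group, caregiver input
#' frequency, and specificity (adult-usage entropy). Rows are the words
#' used by at least `min_participants` distinct participants.
#'
#' @param coded coded responses for the whole study.
#' @param input_frequency named numeric vector of per-stem caregiver
#'   counts (see [load_input_frequency()]); the unspecific categories
#'   may be included under their code names. Missing words get `NA`.
#' @param adult_group label of the reference group.
#' @param min_participants word-list threshold (default 5).
#' @param base entropy log base.
#' @return An object of class `word_measures`: data.frame with one row
#'   per word and columns `word`, `production_frequency.<group>`,
#'   `convergence.<group>`, `input_frequency`, `specificity`.
#' @export
word_measures <- function(coded, input_frequency = NULL,
                          adult_group = "adult", min_participants = 5L,
                          base = 10) {
  stopifnot(is.data.frame(coded), "code" %in% names(coded))
  if (!adult_group %in% coded$age_group)
    stop("reference group '", adult_group, "' absent from data")
  words_all <- words_produced(coded)
  word_list <- build_word_list(coded, min_participants)
  groups <- unique(coded$age_group)
  child_groups <- setdiff(groups, adult_group)
  mats <- lapply(stats::setNames(groups, groups), function(g)
    production_matrix(coded, g, words = words_all))
  adult_pm <- mats[[adult_group]]
  out <- data.frame(word = word_list, stringsAsFactors = FALSE)
  for (g in groups) {
    pf <- frequency_profile(mats[[g]])
    out[[paste0("production_frequency.", g)]] <- unname(pf[word_list])
  }
  for (g in child_groups) {
    rho <- per_word_convergence(mats[[g]], adult_pm)
    out[[paste0("convergence.", g)]] <- unname(rho[word_list])
  }
  ent <- entropy_table(adult_pm, base = base,
                       min_tokens = min_participants)
  out$specificity <- ent$entropy[match(word_list, ent$word)]
  if (is.null(input_frequency)) {
    out$input_frequency <- NA_real_
  } else {
    out$input_frequency <- unname(input_frequency[word_list])
  }
  class(out) <- c("word_measures", "data.frame")
  out
}

#' Ease-of-learning regression
#'
#' Ordinary least squares on z-scored dependent and predictor variables,
#' so coefficients are standardized betas (for a single predictor the
#' beta equals the Pearson correlation). Words lacking a specificity
#' value (never produced by adults) are handled per `na_action`:
#' `"zero"` (default) scores them 0 before standardizing, which treats
#' never-used words as maximally specific and keeps all rows in the
#' model; `"exclude"` drops them; `"max"` imputes the entropy ceiling
#' log10(20).
#'
#' @param measures a [word_measures()] table (or any data.frame with the
#'   needed columns).
#' @param group age-group label whose outcome is modeled.
#' @param dv `"production_frequency"` or `"degree_of_convergence"`.
#' @param predictors subset of `c("input_frequency", "specificity")`.
#' @param na_action handling of missing specificity.
#' @return An object of class `regression_result`: list with `dv`,
#'   `group`, `beta` (named standardized coefficients), `R2`, `F`,
#'   `df1`, `df2`, `p`, `n`.
#' @export
fit_models <- function(measures, group,
                       dv = c("production_frequency",
                              "degree_of_convergence"),
                       predictors = c("input_frequency", "specificity"),
                       na_action = c("zero", "exclude", "max")) {
  dv <- match.arg(dv)
  na_action <- match.arg(na_action)
  stopifnot(is.data.frame(measures))
  y <- switch(dv,
    production_frequency = measures[[paste0("production_frequency.", group)]],
    degree_of_convergence = measures[[paste0("convergence.", group)]])
  if (is.null(y)) stop("no ", dv, " column for group '", group, "'")
  xs <- lapply(stats::setNames(predictors, predictors), function(p) {
    v <- measures[[p]]
    if (is.null(v)) stop("predictor '", p, "' missing from measures")
    v
  })
  x <- do.call(cbind, xs)
  if ("specificity" %in% colnames(x)) {
    sp <- x[, "specificity"]
    if (na_action == "zero") sp[is.na(sp)] <- 0
    if (na_action == "max") sp[is.na(sp)] <- log10(20)
    x[, "specificity"] <- sp
  }
  # convergence undefined for a word (zero variance) -> treated as 0,
  # matching its tabular rendering
  y[is.na(y)] <- 0
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (length(y) < length(predictors) + 2L)
    stop("too few complete rows for the model")
  zx <- scale(x)
  if (any(!is.finite(zx))) stop("rank-deficient design (constant predictor)")
  fit <- stats::lm(scale(y) ~ zx)
  sm <- summary(fit)
  beta <- stats::coef(fit)[-1]
  names(beta) <- colnames(x)
  fs <- sm$fstatistic
  structure(list(dv = dv, group = group, beta = beta,
                 R2 = sm$r.squared, F = unname(fs[1]),
                 df1 = unname(fs[2]), df2 = unname(fs[3]),
                 p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
                 n = length(y), na_action = na_action),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s ~ %s (%s): R2 = %.2f, F(%d, %d) = %.1f, p = %.3g\n",
              x$dv, paste(names(x$beta), collapse = " + "), x$group,
              x$R2, x$df1, x$df2, x$F, x$p))
  for (b in names(x$beta))
    cat(sprintf("  beta[%s] = %.3f\n", b, x$beta[[b]]))
  invisible(x)
}
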