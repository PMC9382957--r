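# Vocabulary growth (Analysis of distinct-word counts) and convergence
# of children's production patterns toward adult usage.

#' Per-participant vocabulary counts with one-way ANOVA and post hocs
#'
#' Counts the distinct emotion words (canonical stems plus the two
#' unspecific categories) each participant produced across the
#' vignettes, then tests for an age-group effect with a one-way ANOVA
#' computed from group sums of squares (F, df, p, eta squared), followed
#' by Bonferroni-corrected pairwise pooled-variance t tests over all
#' group pairs.
#'
#' @param coded coded responses.
#' @param groups ordered group labels; defaults to the order of first
#'   appearance in `coded`.
#' @return An object of class `vocab_stats`: `per_participant`
#'   (data.frame participant_id, age_group, n_words), `group_means`,
#'   `group_sds`, `anova` (list F, df_between, df_within, p,
#'   eta_squared, degenerate flag), `posthoc` (data.frame pair,
#'   t, p, p_adjusted).
#' @export
vocab_stats <- function(coded, groups = unique(coded$age_group)) {
  stopifnot(is.data.frame(coded), "code" %in% names(coded))
  if (length(groups) < 2L) stop("need at least two groups")
  keep <- !coded$code %in% c(NOT_EMOTION, NO_ANSWER)
  # distinct words per participant; participants producing none count 0
  all_part <- unique(coded[c("participant_id", "age_group")])
  d <- coded[keep, ]
  n_distinct <- tapply(d$code, d$participant_id,
                       function(x) length(unique(x)))
  per <- data.frame(
    participant_id = all_part$participant_id,
    age_group = factor(all_part$age_group, levels = groups),
    n_words = as.integer(ifelse(
      is.na(match(all_part$participant_id, names(n_distinct))), 0L,
      n_distinct[all_part$participant_id])),
    stringsAsFactors = FALSE)
  ns <- table(per$age_group)
  if (any(ns < 2L)) stop("degenerate group (n < 2): ",
                         paste(names(ns)[ns < 2], collapse = ", "))
  means <- tapply(per$n_words, per$age_group, mean)
  sds <- tapply(per$n_words, per$age_group, stats::sd)
  # one-way ANOVA from sums of squares
  grand <- mean(per$n_words)
  ss_between <- sum(ns * (means - grand)^2)
  ss_total <- sum((per$n_words - grand)^2)
  ss_within <- ss_total - ss_between
  df_b <- length(groups) - 1L
  df_w <- nrow(per) - length(groups)
  degenerate <- ss_total == 0
  f_stat <- if (degenerate) NA_real_ else (ss_between / df_b) / (ss_within / df_w)
  p <- if (degenerate) NA_real_ else stats::pf(f_stat, df_b, df_w,
                                               lower.tail = FALSE)
  eta2 <- if (degenerate) NA_real_ else ss_between / ss_total
  # Bonferroni-corrected pooled-variance pairwise t tests
  pairs <- utils::combn(as.character(groups), 2)
  n_pairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    x <- per$n_words[per$age_group == g1]
    y <- per$n_words[per$age_group == g2]
    tt <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                   error = function(e) NULL)  # constant data
    data.frame(group1 = g1, group2 = g2,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               p_adjusted = if (is.null(tt)) NA_real_
                            else min(1, tt$p.value * n_pairs),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_participant = per,
                 group_means = means, group_sds = sds,
                 anova = list(F = f_stat, df_between = df_b,
                              df_within = df_w, p = p,
                              eta_squared = eta2, degenerate = degenerate),
                 posthoc = posthoc),
            class = "vocab_stats")
}

#' @export
print.vocab_stats <- function(x, ...) {
  cat("<vocab_stats> group means:",
      paste(sprintf("%s=%.1f", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  if (!x$anova$degenerate)
    cat(sprintf("  F(%d, %d) = %.1f, p = %.3g, eta^2 = %.2f\n",
                x$anova$df_between, x$anova$df_within, x$anova$F,
                x$anova$p, x$anova$eta_squared))
  invisible(x)
}

#' Whole-matrix convergence of a child group toward adult usage
#'
#' Spearman correlation (average ranks for ties; the all-zero cells form
#' one large tie group) between two production matrices flattened
#' row-major, including zero cells.
#'
#' @param child,adult [production_matrix()] objects with identical
#'   vignette and word orders.
#' @return list with `group`, `rho`, `n_cells`.
#' @export
matrix_convergence <- function(child, adult) {
  stopifnot(inherits(child, "production_matrix"),
            inherits(adult, "production_matrix"))
  if (!identical(dim(child$counts), dim(adult$counts)) ||
      !identical(child$words, adult$words) ||
      !identical(child$vignette_ids, adult$vignette_ids))
    stop("production matrices must share vignette and word orders")
  x <- as.vector(t(child$counts))
  y <- as.vector(t(adult$counts))
  list(group = child$age_group,
       rho = stats::cor(x, y, method = "spearman"),
       n_cells = length(x))
}

#' Per-word convergence toward adult usage
#'
#' Spearman correlation between a word's vignette vector in the child
#' matrix and in the adult matrix. Words with zero variance in either
#' vector have no defined correlation and are reported as `NA`.
#'
#' @inheritParams matrix_convergence
#' @return named numeric vector (one rho per word, `NA` if undefined).
#' @export
per_word_convergence <- function(child, adult) {
  stopifnot(inherits(child, "production_matrix"),
            inherits(adult, "production_matrix"))
  if (!identical(child$words, adult$words))
    stop("production matrices must share the word order")
  vapply(seq_along(child$words), function(j) {
    x <- child$counts[, j]; y <- adult$counts[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(child$words)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with normal
#' one-tailed (primary) and two-tailed p values.
#'
#' @param r1,r2 correlation coefficients, |r| < 1.
#' @param n1,n2 sample sizes (> 3) behind each coefficient.
#' @return list with `z`, `p_one_tailed`, `p_two_tailed`.
#' @examples
#' fisher_z_test(.443, .551, 1320, 1320)$z  # about -3.7
#' @export
fisher_z_test <- function(r1, r2, n1, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p1 <- stats::pnorm(-abs(z))
  list(z = z, p_one_tailed = p1, p_two_tailed = 2 * p1)
}
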