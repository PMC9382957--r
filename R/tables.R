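# Packaged reference tables: the published group-level summary (mean
# word counts, convergence rhos) and word-level measures (production
# frequency, convergence, input frequency, specificity) of the original
# study, shipped as plain-text fixtures. They provide the inputs for the
# correlation-comparison and ease-of-learning checks that are desk
# reproducible without the archived raw data.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "emovocab")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' Published group-level reference summary
#'
#' Mean (SD) number of distinct emotion words per participant and the
#' Spearman convergence of each child group's production matrix with the
#' adults', as published for the original sample.
#'
#' @return data.frame with columns `age_group`, `mean_words`,
#'   `sd_words`, `rho` (NA for the adult reference group).
#' @export
table1_reference <- function() {
  utils::read.csv(ref_path("table1_reference.csv"),
                  colClasses = c(age_group = "character"),
                  encoding = "UTF-8")
}

#' Published word-level reference measures
#'
#' The 38-word inventory (36 stems plus the two unspecific categories)
#' with per-group production frequencies (%), per-word convergence with
#' adult usage (Spearman rho), caregiver input frequency, and word
#' specificity (adult-usage entropy, log base 10; NA for the three
#' words adults never produced).
#'
#' @return data.frame with one row per word; column `word` holds the
#'   package-internal word code (stem or unspecific category label).
#' @export
table2_reference <- function() {
  d <- utils::read.csv(ref_path("table2_word_measures.csv"),
                       encoding = "UTF-8")
  code <- d$german
  code[code == "unspezifisch positiv"] <- UNSPECIFIC_POS
  code[code == "unspezifisch negativ"] <- UNSPECIFIC_NEG
  d$word <- code
  d
}

#' Reference measures in `word_measures` layout
#'
#' Reshapes [table2_reference()] into the column layout produced by
#' [word_measures()], so [fit_models()] runs on the published numbers.
#'
#' @return A `word_measures` data.frame.
#' @export
table2_as_measures <- function() {
  d <- table2_reference()
  groups <- c("4-5" = "4_5", "6-7" = "6_7", "8-9" = "8_9",
              "10-11" = "10_11", "adult" = "adult")
  out <- data.frame(word = d$word, stringsAsFactors = FALSE)
  for (g in names(groups))
    out[[paste0("production_frequency.", g)]] <- d[[paste0("pf_", groups[[g]])]]
  for (g in names(groups)[1:4])
    out[[paste0("convergence.", g)]] <- d[[paste0("conv_", groups[[g]])]]
  out$input_frequency <- d$input_frequency
  out$specificity <- d$specificity
  class(out) <- c("word_measures", "data.frame")
  out
}
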