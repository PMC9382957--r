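# End-to-end orchestration of the five analyses: vocabulary growth,
# production-frequency profiles, convergence toward adult usage,
# semantic dimensions by MDS, and ease-of-learning regressions.

#' Pipeline configuration
#'
#' Either `responses` (a raw-response data.frame or a fixture path) or
#' synthetic-generation settings (`design` + `params`) must be supplied;
#' by default a synthetic study is generated.
#'
#' @param responses raw responses data.frame or path to a fixture; NULL
#'   to simulate.
#' @param design a [study_design()].
#' @param params a [simulation_params()]; its `seed` is overridden by
#'   `seed` when given.
#' @param input_frequency named per-stem caregiver counts, or a path
#'   for [load_input_frequency()]; defaults to the packaged published
#'   counts.
#' @param adult_group reference group label.
#' @param min_participants word-list threshold.
#' @param mds_dims,mds_nonmetric MDS options.
#' @param entropy_base log base for specificity.
#' @param na_action missing-specificity handling in [fit_models()].
#' @param out_dir optional directory for the report bundle.
#' @param seed integer seed for synthetic generation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(responses = NULL, design = default_design(),
                            params = simulation_params(),
                            input_frequency = NULL,
                            adult_group = "adult",
                            min_participants = 5L, mds_dims = 2L,
                            mds_nonmetric = TRUE, entropy_base = 10,
                            na_action = "zero", out_dir = NULL,
                            seed = NULL) {
  if (min_participants < 1L) stop("min_participants must be >= 1")
  if (!is.null(seed)) params$seed <- as.integer(seed)
  structure(list(responses = responses, design = design, params = params,
                 input_frequency = input_frequency,
                 adult_group = adult_group,
                 min_participants = as.integer(min_participants),
                 mds_dims = as.integer(mds_dims),
                 mds_nonmetric = mds_nonmetric,
                 entropy_base = entropy_base, na_action = na_action,
                 out_dir = out_dir, seed = params$seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the five analyses in order on real or synthetic responses:
#' (1) per-participant vocabulary counts with one-way ANOVA and
#' Bonferroni post hocs; (2) production-frequency profiles per group;
#' (3) whole-matrix Spearman convergence of each child group toward the
#' adults plus Fisher r-to-z comparisons of adjacent groups; (4)
#' co-naming similarity matrices, their two-dimensional SMACOF
#' embeddings and valence-oriented coordinates; (5) word-level measures
#' and the ease-of-learning regressions. When `config$out_dir` is set,
#' writes per-analysis JSON, delimited tables, MDS coordinates and a run
#' log.
#'
#' @param config a [pipeline_config()].
#' @return A report bundle (list) with elements `config_echo`, `coded`,
#'   `word_list`, `analysis1` ... `analysis5`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  lex <- design$lexicon
  responses <- config$responses
  if (is.null(responses)) {
    responses <- simulate_responses(design, config$params)
  } else if (is.character(responses)) {
    responses <- read_fixture(responses)
  }
  if (!config$adult_group %in% responses$age_group)
    stop("reference group '", config$adult_group,
         "' absent from responses")
  coded <- code_dataset(responses, lex, design = design,
                        warn_unknown = FALSE)
  groups <- design$age_groups[design$age_groups %in% coded$age_group]
  child_groups <- setdiff(groups, config$adult_group)
  words_all <- words_produced(coded)
  word_list <- build_word_list(coded, config$min_participants)

  # Analysis 1: vocabulary size by age
  a1 <- vocab_stats(coded, groups = groups)

  # Analysis 2: production-frequency profiles
  mats <- lapply(stats::setNames(groups, groups), function(g)
    production_matrix(coded, g, words = words_all))
  a2 <- lapply(mats, frequency_profile)

  # Analysis 3: convergence toward adult usage
  adult_pm <- mats[[config$adult_group]]
  conv <- lapply(mats[child_groups], matrix_convergence, adult = adult_pm)
  rhos <- vapply(conv, `[[`, numeric(1), "rho")
  n_cells <- vapply(conv, `[[`, numeric(1), "n_cells")
  fisher <- NULL
  if (length(child_groups) >= 2L) {
    fisher <- do.call(rbind, lapply(seq_len(length(child_groups) - 1L),
      function(i) {
        g1 <- child_groups[i]; g2 <- child_groups[i + 1L]
        fz <- fisher_z_test(rhos[[g1]], rhos[[g2]],
                            n_cells[[g1]], n_cells[[g2]])
        data.frame(group1 = g1, group2 = g2, z = fz$z,
                   p_one_tailed = fz$p_one_tailed,
                   p_two_tailed = fz$p_two_tailed,
                   stringsAsFactors = FALSE)
      }))
  }
  a3 <- list(rho = rhos, n_cells = n_cells, fisher = fisher)

  # Analysis 4: co-naming similarity and MDS per group
  valence <- design$vignettes$valence
  a4 <- lapply(stats::setNames(groups, groups), function(g) {
    sim <- similarity_matrix(coded, g,
                             vignette_ids = design$vignettes$id)
    diss <- to_dissimilarity(sim)
    fit <- smacof(diss, k = config$mds_dims,
                  nonmetric = config$mds_nonmetric)
    fit <- orient_mds(fit, valence)
    list(similarity = sim, dissimilarity = diss, mds = fit)
  })

  # Analysis 5: word measures and ease-of-learning models
  infreq <- config$input_frequency
  if (is.null(infreq)) {
    t2 <- table2_reference()
    infreq <- stats::setNames(t2$input_frequency, t2$word)
  } else if (is.character(infreq)) {
    infreq <- load_input_frequency(infreq, lex)
  }
  measures <- word_measures(coded, input_frequency = infreq,
                            adult_group = config$adult_group,
                            min_participants = config$min_participants,
                            base = config$entropy_base)
  youngest <- child_groups[1]
  models <- list()
  for (dv in c("production_frequency", "degree_of_convergence")) {
    for (g in child_groups) {
      preds <- if (g == youngest) c("input_frequency", "specificity")
               else "specificity"
      key <- paste(dv, g, sep = ".")
      models[[key]] <- tryCatch(
        fit_models(measures, g, dv = dv, predictors = preds,
                   na_action = config$na_action),
        error = function(e) e)
    }
  }
  a5 <- list(measures = measures, models = models)

  bundle <- list(config_echo = config, coded = coded,
                 word_list = word_list, words_all = words_all,
                 analysis1 = a1, analysis2 = a2, analysis3 = a3,
                 analysis4 = a4, analysis5 = a5)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

num_or_null <- function(x) if (is.null(x)) NULL else unclass(x)

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  j <- function(x, file) jsonlite::write_json(
    x, file.path(out_dir, file), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE, na = "null")
  a1 <- bundle$analysis1
  j(list(group_means = as.list(a1$group_means),
         group_sds = as.list(a1$group_sds), anova = a1$anova,
         posthoc = a1$posthoc), "analysis1_vocabulary.json")
  utils::write.csv(a1$per_participant,
                   file.path(out_dir, "vocabulary_counts.csv"),
                   row.names = FALSE)
  j(lapply(bundle$analysis2, as.list), "analysis2_frequencies.json")
  j(list(rho = as.list(bundle$analysis3$rho),
         n_cells = as.list(bundle$analysis3$n_cells),
         fisher = bundle$analysis3$fisher), "analysis3_convergence.json")
  mds_out <- lapply(bundle$analysis4, function(x)
    list(stress = x$mds$stress, n_iter = x$mds$n_iter,
         converged = x$mds$converged,
         coords = apply(x$mds$coords, 1, as.numeric, simplify = FALSE)))
  j(mds_out, "analysis4_mds.json")
  utils::write.csv(bundle$analysis5$measures,
                   file.path(out_dir, "word_measures.csv"),
                   row.names = FALSE)
  models <- lapply(bundle$analysis5$models, function(m) {
    if (inherits(m, "error")) list(error = conditionMessage(m))
    else list(dv = m$dv, group = m$group, beta = as.list(m$beta),
              R2 = m$R2, F = m$F, df1 = m$df1, df2 = m$df2, p = m$p,
              n = m$n)
  })
  j(models, "analysis5_models.json")
  cfg <- bundle$config_echo
  log_lines <- c(
    paste0("seed: ", cfg$seed),
    paste0("adult_group: ", cfg$adult_group),
    paste0("min_participants: ", cfg$min_participants),
    paste0("mds: k=", cfg$mds_dims, " nonmetric=", cfg$mds_nonmetric),
    paste0("entropy_base: ", cfg$entropy_base),
    paste0("na_action: ", cfg$na_action),
    paste0("n_words_total: ", length(bundle$words_all)),
    paste0("n_words_list: ", length(bundle$word_list)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
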