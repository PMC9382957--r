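# Word specificity (entropy), input-frequency aggregation, and the
# ease-of-learning regressions.

test_that("entropy: analytic values and missing-not-zero convention", {
  counts <- cbind(one = c(9, 0, 0, 0, 0), two = c(5, 5, 0, 0, 0),
                  unused = c(0, 0, 0, 0, 0))
  pm <- toy_pm(counts)
  expect_equal(as.numeric(word_entropy(pm, "one")), 0)
  expect_equal(as.numeric(word_entropy(pm, "two")), log10(2))
  expect_true(is.na(word_entropy(pm, "unused")))
  expect_equal(attr(word_entropy(pm, "unused"), "support"), 0L)
  # uniform over 20 vignettes hits the log10 ceiling
  pm20 <- toy_pm(matrix(3, 20, 1))
  expect_equal(as.numeric(word_entropy(pm20, "w1")), log10(20))
  # below the reliability bound -> warning, not error
  pm_small <- toy_pm(matrix(c(2, 1), 2, 1))
  expect_warning(word_entropy(pm_small, "w1"), "unreliable")
  expect_error(word_entropy(pm, "nope"), "not in matrix")
})

test_that("entropy is permutation-invariant and grows when mass spreads", {
  set.seed(61)
  counts <- rpois(20, 2) + c(5, rep(0, 19))
  pm <- toy_pm(matrix(counts, 20, 1))
  perm <- sample(20)
  pm_perm <- toy_pm(matrix(counts[perm], 20, 1))
  expect_equal(as.numeric(word_entropy(pm, "w1")),
               as.numeric(word_entropy(pm_perm, "w1")))
  # spreading equal mass over k cells: H = log10(k), strictly increasing
  h <- vapply(1:20, function(k) {
    cts <- c(rep(6, k), rep(0, 20 - k))
    as.numeric(word_entropy(toy_pm(matrix(cts, 20, 1)), "w1"))
  }, numeric(1))
  expect_equal(h, log10(1:20))
  expect_true(all(diff(h) > 0))
})

test_that("entropy_table summarises all words of the adult matrix", {
  d <- default_design()
  r <- simulate_responses(d, simulation_params(seed = 2))
  coded <- code_dataset(r, d$lexicon)
  adult <- production_matrix(coded, "adult")
  et <- entropy_table(adult)
  expect_equal(et$word, adult$words)
  expect_true(all(et$entropy[et$support == 1] == 0, na.rm = TRUE))
  expect_true(all(is.na(et$entropy[et$n_tokens == 0])))
  expect_true(all(et$entropy <= log10(20) + 1e-12, na.rm = TRUE))
})

test_that("input-frequency loader aggregates surface forms by stem", {
  lex <- default_lexicon()
  f <- tempfile(fileext = ".csv")
  writeLines(c("surface_form,count", "traurig,200", "traurige,33",
               "Angst,12"), f)
  expect_warning(tab <- load_input_frequency(f, lex), "set to 0")
  expect_equal(tab[["traurig"]], 233)
  expect_equal(tab[["Angst"]], 12)
  expect_equal(tab[["Ekel"]], 0)
  # empty file: all zero with warning
  f0 <- tempfile(fileext = ".csv")
  writeLines("surface_form,count", f0)
  expect_warning(tab0 <- load_input_frequency(f0, lex))
  expect_true(all(tab0 == 0))
  fbad <- tempfile(fileext = ".csv")
  writeLines(c("surface_form,count", "traurig,-3"), fbad)
  expect_error(suppressWarnings(load_input_frequency(fbad, lex)),
               "malformed")
})

test_that("word_measures assembles the word-level table", {
  d <- default_design()
  r <- simulate_responses(d, simulation_params(seed = 3))
  coded <- code_dataset(r, d$lexicon)
  infreq <- setNames(table2_reference()$input_frequency,
                     table2_reference()$word)
  wm <- word_measures(coded, input_frequency = infreq)
  expect_s3_class(wm, "word_measures")
  expect_setequal(wm$word, build_word_list(coded))
  expect_true(all(c("production_frequency.4-5", "convergence.10-11",
                    "input_frequency", "specificity") %in% names(wm)))
  # unspecific pseudo-words are rows like any word
  expect_true("unspecific_positive" %in% wm$word)
})

test_that("regression identities: R2, standardized beta, affine invariance", {
  set.seed(71)
  sp <- runif(38, 0, 1.3)
  m <- data.frame(word = paste0("w", 1:38),
                  `production_frequency.kid` = 3 * sp + 1,
                  specificity = sp, input_frequency = runif(38, 0, 500),
                  check.names = FALSE)
  fit <- suppressWarnings(  # lm flags the exact fit
    fit_models(m, "kid", dv = "production_frequency",
               predictors = "specificity"))
  expect_equal(fit$R2, 1)
  expect_equal(unname(fit$beta["specificity"]), 1)
  # single-predictor beta equals the Pearson correlation
  m$`production_frequency.kid` <- 3 * sp + rnorm(38)
  fit2 <- fit_models(m, "kid", dv = "production_frequency",
                     predictors = "specificity")
  expect_equal(unname(fit2$beta["specificity"]),
               cor(m$`production_frequency.kid`, sp), tolerance = 1e-12)
  # affine rescaling of a predictor leaves beta and R2 unchanged
  m2 <- m; m2$specificity <- 100 * m2$specificity - 7
  fit3 <- fit_models(m2, "kid", dv = "production_frequency",
                     predictors = "specificity")
  expect_equal(fit3$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit3$R2, fit2$R2, tolerance = 1e-10)
  # two predictors: F and df bookkeeping
  fit4 <- fit_models(m, "kid", dv = "production_frequency",
                     predictors = c("input_frequency", "specificity"))
  expect_equal(fit4$df1, 2)
  expect_equal(fit4$df2, 35)
  expect_error(fit_models(m[1:3, ], "kid", dv = "production_frequency",
                          predictors = c("input_frequency", "specificity")),
               "too few")
})

test_that("missing specificity handling: zero, exclude, max", {
  set.seed(72)
  sp <- c(runif(35, 0, 1.2), NA, NA, NA)
  y <- ifelse(is.na(sp), 0, sp) * 2 + rnorm(38, 0, .3)
  m <- data.frame(word = paste0("w", 1:38),
                  `production_frequency.kid` = y, specificity = sp,
                  check.names = FALSE)
  fz <- fit_models(m, "kid", dv = "production_frequency",
                   predictors = "specificity", na_action = "zero")
  fe <- fit_models(m, "kid", dv = "production_frequency",
                   predictors = "specificity", na_action = "exclude")
  fm <- fit_models(m, "kid", dv = "production_frequency",
                   predictors = "specificity", na_action = "max")
  expect_equal(fz$n, 38)
  expect_equal(fe$n, 35)
  expect_equal(fm$n, 38)
  expect_false(isTRUE(all.equal(fz$R2, fm$R2)))
})

test_that("regression recovers a planted specificity effect", {
  beta_true <- 0.8
  betas <- vapply(1:20, function(s) {
    set.seed(s)
    sp <- runif(38, 0, 1.3)
    y <- beta_true * scale(sp)[, 1] + rnorm(38, 0, sqrt(1 - beta_true^2))
    m <- data.frame(word = paste0("w", 1:38),
                    `production_frequency.kid` = y, specificity = sp,
                    check.names = FALSE)
    unname(fit_models(m, "kid", dv = "production_frequency",
                      predictors = "specificity")$beta)
  }, numeric(1))
  expect_true(all(betas > 0))
  se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - beta_true), 2 * se + 1e-3)
})
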