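# Production matrices, frequency profiles, and co-naming similarity.

test_that("production matrix tallies participants per vignette x word", {
  codes <- matrix(c("traurig", "Angst",
                    "traurig", "no_answer"), nrow = 2, byrow = TRUE)
  coded <- coded_from_matrix(codes, group = "4-5")
  pm <- production_matrix(coded, "4-5", words = c("traurig", "Angst"),
                          vignette_ids = 1:2)
  expect_equal(pm$counts["1", "traurig"], 2L, ignore_attr = TRUE)
  expect_equal(pm$counts["2", "Angst"], 1L, ignore_attr = TRUE)
  expect_equal(sum(pm$counts), 3L)  # no_answer contributes nothing
  expect_error(production_matrix(coded, "adult"), "absent")
})

test_that("empty group yields an all-zero matrix of fixed shape", {
  coded <- coded_from_matrix(matrix("no_answer", 1, 4), group = "4-5")
  pm <- production_matrix(coded, "4-5", words = c("traurig", "Angst"),
                          vignette_ids = 1:4)
  expect_equal(dim(pm$counts), c(4L, 2L))
  expect_true(all(pm$counts == 0L))
  expect_error(frequency_profile(pm), "no emotion-word tokens")
})

test_that("token-sum invariant: matrix total equals codable tokens", {
  d <- default_design()
  r <- simulate_responses(d, simulation_params(seed = 8))
  coded <- code_dataset(r, d$lexicon)
  words <- words_produced(coded)
  for (g in c("4-5", "adult")) {
    pm <- production_matrix(coded, g, words = words)
    n_tokens <- sum(coded$age_group == g &
                      !coded$code %in% c("no_answer", "not_emotion"))
    expect_equal(sum(pm$counts), n_tokens)
  }
})

test_that("frequency profile is forced percentage arithmetic", {
  pm <- toy_pm(cbind(c(3, 0), c(0, 1)))
  fp <- frequency_profile(pm)
  expect_equal(unname(fp), c(75, 25))
  pm1 <- toy_pm(matrix(c(4, 2), 2, 1))
  expect_equal(unname(frequency_profile(pm1)), 100)
  d <- default_design()
  r <- simulate_responses(d, simulation_params(seed = 1))
  coded <- code_dataset(r, d$lexicon)
  fp45 <- frequency_profile(production_matrix(coded, "4-5"))
  expect_equal(sum(fp45), 100)
  # young children lean on the valence-only categories: both rank top-3
  top3 <- names(sort(fp45, decreasing = TRUE))[1:3]
  expect_true(all(c("unspecific_positive", "unspecific_negative") %in% top3))
})

test_that("similarity counts same-word events per participant pair", {
  codes <- matrix(c("stolz", "stolz", "Angst"), nrow = 1)
  coded <- coded_from_matrix(codes, group = "g")
  sm <- similarity_matrix(coded, "g", vignette_ids = 1:3)
  expect_equal(sm$s[1, 2], 1L)
  expect_equal(sm$s[1, 3], 0L)
  expect_equal(sm$s[2, 3], 0L)
  expect_true(isSymmetric(unname(sm$s)))
  # all participants using one word everywhere: s = n off-diagonal
  codes2 <- matrix("traurig", nrow = 3, ncol = 4)
  sm2 <- similarity_matrix(coded_from_matrix(codes2), "g",
                           vignette_ids = 1:4)
  off <- row(sm2$s) != col(sm2$s)
  expect_true(all(sm2$s[off] == 3L))
  # no_answer / not_emotion never match, and shrink n_pairs
  codes3 <- matrix(c("no_answer", "no_answer",
                     "not_emotion", "not_emotion",
                     "traurig", "traurig"), nrow = 3, byrow = TRUE)
  sm3 <- similarity_matrix(coded_from_matrix(codes3), "g",
                           vignette_ids = 1:2)
  expect_equal(sm3$s[1, 2], 1L)
  expect_equal(sm3$n_pairs[1, 2], 1L)
})

test_that("similarity matches exhaustive pair enumeration on small cases", {
  set.seed(99)
  pool <- c("traurig", "Angst", "Freude", "unspecific_positive",
            "no_answer", "not_emotion")
  for (rep in 1:60) {
    n <- sample(1:4, 1); nv <- sample(2:4, 1)
    codes <- matrix(sample(pool, n * nv, replace = TRUE), n, nv)
    coded <- coded_from_matrix(codes)
    sm <- similarity_matrix(coded, "g", vignette_ids = seq_len(nv))
    oracle <- similarity_oracle(coded, "g", seq_len(nv))
    expect_equal(unname(sm$s), oracle$s)
    expect_equal(unname(sm$n_pairs), oracle$n_pairs)
  }
})

test_that("similarity is invariant under participant relabeling", {
  d <- default_design()
  r <- simulate_responses(d, simulation_params(seed = 9))
  coded <- code_dataset(r, d$lexicon)
  sm <- similarity_matrix(coded, "6-7")
  shuffled <- coded
  ids <- unique(coded$participant_id)
  set.seed(1)
  map <- setNames(sample(ids), ids)
  shuffled$participant_id <- unname(map[coded$participant_id])
  sm2 <- similarity_matrix(shuffled, "6-7")
  expect_equal(sm$s, sm2$s)
  expect_equal(sm$n_pairs, sm2$n_pairs)
})

test_that("unspecific matchability is configurable", {
  codes <- matrix(c("unspecific_positive", "unspecific_positive"), nrow = 1)
  coded <- coded_from_matrix(codes)
  sm_on <- similarity_matrix(coded, "g", vignette_ids = 1:2)
  sm_off <- similarity_matrix(coded, "g", vignette_ids = 1:2,
                              match_unspecific = FALSE)
  expect_equal(sm_on$s[1, 2], 1L)
  expect_equal(sm_off$s[1, 2], 0L)
  expect_equal(sm_off$n_pairs[1, 2], 0L)
})
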