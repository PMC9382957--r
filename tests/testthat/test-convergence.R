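# Vocabulary statistics, Spearman convergence, Fisher r-to-z.

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(21)
  codes_a <- replicate(8, sample(c("traurig", "Angst", "Freude"), 6,
                                 replace = TRUE))
  coded <- rbind(coded_from_matrix(t(codes_a)[1:4, , drop = FALSE], "a"),
                 coded_from_matrix(t(codes_a)[5:8, , drop = FALSE], "b"))
  coded$participant_id <- paste(coded$age_group, coded$participant_id)
  vs <- vocab_stats(coded, groups = c("a", "b"))
  x <- vs$per_participant$n_words[vs$per_participant$age_group == "a"]
  y <- vs$per_participant$n_words[vs$per_participant$age_group == "b"]
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(vs$anova$F, unname(tt$statistic)^2)
  expect_equal(vs$anova$p, tt$p.value, tolerance = 1e-12)
  expect_equal(nrow(vs$posthoc), 1L)
})

test_that("constant counts flag a degenerate ANOVA", {
  codes <- matrix("traurig", 4, 3)
  coded <- rbind(coded_from_matrix(codes[1:2, ], "a"),
                 coded_from_matrix(codes[3:4, ], "b"))
  coded$participant_id <- paste(coded$age_group, coded$participant_id)
  vs <- vocab_stats(coded, groups = c("a", "b"))
  expect_true(vs$anova$degenerate)
  expect_true(is.na(vs$anova$F))
})

test_that("vocab_stats matches aov and Bonferroni caps at 1", {
  d <- default_design()
  r <- simulate_responses(d, simulation_params(seed = 1))
  coded <- code_dataset(r, d$lexicon)
  vs <- vocab_stats(coded, groups = d$age_groups)
  fit <- aov(n_words ~ age_group, data = vs$per_participant)
  sm <- summary(fit)[[1]]
  expect_equal(vs$anova$F, sm[["F value"]][1], tolerance = 1e-10)
  expect_equal(vs$anova$df_between, 4L)
  expect_equal(vs$anova$df_within, 145L)  # 150 participants, 5 groups
  expect_equal(nrow(vs$posthoc), 10L)     # all pairs of 5 groups
  expect_true(all(vs$posthoc$p_adjusted <= 1))
  expect_true(all(vs$posthoc$p_adjusted >= vs$posthoc$p))
  expect_true(vs$anova$eta_squared > 0 && vs$anova$eta_squared < 1)
})

test_that("matrix convergence: identity, reversal, and tie oracle", {
  m <- toy_pm(matrix(c(0, 1, 2, 3, 4, 5), 3, 2))
  expect_equal(matrix_convergence(m, m)$rho, 1)
  rev <- toy_pm(matrix(c(5, 4, 3, 2, 1, 0), 3, 2))
  expect_equal(matrix_convergence(m, rev)$rho, -1)
  expect_equal(matrix_convergence(m, rev)$n_cells, 6L)
  a <- toy_pm(matrix(c(0, 0, 2, 1, 0, 3), 3, 2))
  b <- toy_pm(matrix(c(1, 0, 0, 2, 2, 0), 3, 2))
  expect_equal(matrix_convergence(a, b)$rho,
               spearman_oracle(as.vector(t(a$counts)),
                               as.vector(t(b$counts))))
  mism <- toy_pm(matrix(0, 3, 3))
  expect_error(matrix_convergence(m, mism), "share")
})

test_that("spearman agrees with the average-rank oracle exhaustively", {
  # all pairs of length-4 count vectors over {0,1,2}
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  vecs <- grid[apply(grid, 1, function(v) length(unique(v)) > 1), ]
  idx <- seq_len(nrow(vecs))
  got <- want <- matrix(NA_real_, nrow(vecs), nrow(vecs))
  for (i in idx) {
    x <- vecs[i, ]
    for (j in idx) {
      y <- vecs[j, ]
      got[i, j] <- matrix_convergence(toy_pm(matrix(x, 2, 2)),
                                      toy_pm(matrix(y, 2, 2)))$rho
      want[i, j] <- spearman_oracle(as.vector(t(matrix(x, 2, 2))),
                                    as.vector(t(matrix(y, 2, 2))))
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("spearman agrees with the oracle on 1000 random larger cases", {
  set.seed(7)
  got <- want <- numeric(0)
  for (rep in 1:1000) {
    n <- sample(5:40, 1)
    x <- rpois(n, 2); y <- rpois(n, 2)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- c(got, matrix_convergence(toy_pm(matrix(x, n, 1)),
                                     toy_pm(matrix(y, n, 1)))$rho)
    want <- c(want, spearman_oracle(x, y))
  }
  expect_gt(length(got), 950)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("rho is invariant under strictly monotone count transforms", {
  set.seed(13)
  x <- rpois(40, 3); y <- rpois(40, 3)
  base <- matrix_convergence(toy_pm(matrix(x, 20, 2)),
                             toy_pm(matrix(y, 20, 2)))$rho
  warped <- matrix_convergence(toy_pm(matrix(x^3 + 2 * x, 20, 2)),
                               toy_pm(matrix(exp(y), 20, 2)))$rho
  expect_equal(base, warped, tolerance = 1e-12)
})

test_that("per-word convergence handles perfect and undefined cases", {
  child <- toy_pm(cbind(Ekel = c(5, 0, 0, 0), traurig = c(0, 0, 0, 0),
                        Angst = c(1, 2, 0, 1)))
  adult <- toy_pm(cbind(Ekel = c(9, 0, 0, 0), traurig = c(1, 2, 0, 0),
                        Angst = c(0, 3, 1, 0)))
  rho <- per_word_convergence(child, adult)
  expect_equal(rho[["Ekel"]], 1)           # used for exactly the adult vignette
  expect_true(is.na(rho[["traurig"]]))     # zero variance -> undefined
  expect_equal(rho[["Angst"]],
               spearman_oracle(child$counts[, "Angst"],
                               adult$counts[, "Angst"]))
  expect_equal(per_word_convergence(adult, adult),
               c(Ekel = 1, traurig = 1, Angst = 1))
})

test_that("fisher z reproduces closed form and its symmetries", {
  fz <- fisher_z_test(.3, .5, 100, 200)
  manual <- (atanh(.3) - atanh(.5)) / sqrt(1 / 97 + 1 / 197)
  expect_equal(fz$z, manual)
  expect_equal(fz$p_two_tailed, 2 * fz$p_one_tailed)
  # antisymmetry and null
  expect_equal(fisher_z_test(.5, .3, 100, 200)$z,
               -fisher_z_test(.3, .5, 200, 100)$z)
  expect_equal(fisher_z_test(.4, .4, 50, 50)$z, 0)
  expect_error(fisher_z_test(1, .5, 10, 10), "< 1")
  expect_error(fisher_z_test(.2, .5, 3, 10), "exceed 3")
})
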