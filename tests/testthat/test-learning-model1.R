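test_that("choice weights evaluate the conformist rule exactly", {
  # {2,1,1} with alpha = 2: 4/(4+1+1), 1/6, 1/6
  expect_equal(choice_weights(c(2, 1, 1), alpha = 2),
               c(2 / 3, 1 / 6, 1 / 6))
  # alpha = 1 with M = T = 1 is plain proportional sampling
  expect_equal(choice_weights(c(3, 2, 1)), c(3, 2, 1) / 6)
  # content and demonstrator terms multiply in
  expect_equal(choice_weights(c(1, 1), alpha = 1, M = c(1, 0.05)),
               c(1, 0.05) / 1.05)
  expect_error(choice_weights(numeric(0)), "empty")
})

test_that("choice weights are monotone in the type's sample frequency", {
  base <- choice_weights(c(2, 3, 4), alpha = 1.5)[1]
  up <- choice_weights(c(3, 3, 4), alpha = 1.5)[1]
  expect_gt(up, base)
  # exhaustive proportionality check at alpha = 1 on all 3-type memories
  for (f1 in 1:5) for (f2 in 1:5) for (f3 in 1:5) {
    f <- c(f1, f2, f3)
    expect_equal(choice_weights(f, alpha = 1), f / sum(f))
  }
})

make_pool <- function(reps, t = NULL, N_s = 50) {
  list(repertoires = lapply(reps, as.integer),
       t_m = if (is.null(t)) rep(1, length(reps)) else t,
       M = rep(1, N_s))
}

test_that("mutation extremes behave as specified", {
  p <- sim_params(N_p = 10, N_s = 50, mu = 0, N_T = 3, alpha = 1)
  pool <- make_pool(list(7, 7, 7))
  # mu = 0, single shared type: repertoire is exactly that type
  expect_identical(learn_repertoire_m1(pool, p, r_m = 1, seed = 1), 7L)
  # mu = 1: every learned syllable is replaced by a different type
  p1 <- update_params(p, list(mu = 1))
  picked <- replicate(300, learn_repertoire_m1(pool, p1, r_m = 1))
  expect_true(all(picked != 7L))
  expect_gt(length(unique(picked)), 20)  # spread over the alphabet
})

test_that("tiny-case learning probabilities match enumeration", {
  set.seed(42)
  p <- sim_params(N_p = 10, N_s = 50, mu = 0, N_T = 3, alpha = 1)
  pool <- make_pool(list(1, 1, 2))
  n <- 3e4
  draws <- replicate(n, learn_repertoire_m1(pool, p, r_m = 1))
  p_a <- mean(draws == 1L)
  se <- sqrt(2 / 9 / n)
  expect_lt(abs(p_a - 2 / 3), 3 * se)
})

test_that("an exhausted memory only grows further through mutation", {
  pool <- make_pool(list(c(1, 2), c(1, 2)))
  # mu = 0: the whole memory and nothing else
  p0 <- sim_params(N_p = 10, N_s = 50, mu = 0, N_T = 2, alpha = 1)
  rep0 <- learn_repertoire_m1(pool, p0, r_m = 4, seed = 7)
  expect_setequal(rep0, c(1L, 2L))
  # mu = 1: every remaining slot is filled by an innovation
  p1 <- sim_params(N_p = 10, N_s = 50, mu = 1, N_T = 2, alpha = 1)
  rep1 <- learn_repertoire_m1(pool, p1, r_m = 4, seed = 8)
  expect_length(rep1, 4)
  expect_equal(anyDuplicated(rep1), 0L)
})

test_that("demonstrator attractiveness weights the choice", {
  # two demonstrators with different t singing different types; alpha = 1
  p <- sim_params(N_p = 10, N_s = 50, mu = 0, N_T = 2, alpha = 1, v = 1)
  pool <- make_pool(list(1, 2), t = c(9, 1))
  set.seed(8)
  draws <- replicate(4000, learn_repertoire_m1(pool, p, r_m = 1))
  p_1 <- mean(draws == 1L)
  se <- sqrt(0.9 * 0.1 / 4000)
  expect_lt(abs(p_1 - 0.9), 4 * se)
})

test_that("the neutral reduction matches an independent drift oracle", {
  # alpha = 1, v = 0, p_att = 1: frequency spectra must agree with a
  # plain-R reimplementation of unbiased sample-and-copy drift (a
  # deeper 500-replicate version of this check runs with the
  # end-to-end experiments)
  nrep <- 200
  p <- sim_params(N_p = 30, N_s = 50, mu = 0.01, N_T = 3, alpha = 1,
                  v = 0.01, p_att = 1, years = 25)
  set.seed(123)
  spec_impl <- rowSums(vapply(seq_len(nrep), function(i) {
    res <- run_simulation(p)
    spectrum_bins(res$population$repertoires)
  }, numeric(5)))
  set.seed(321)
  spec_oracle <- rowSums(vapply(seq_len(nrep), function(i) {
    spectrum_bins(oracle_neutral_sim(30, 50, mu = 0.01, N_T = 3,
                                     years = 25,
                                     rep_probs = default_rep_probs()))
  }, numeric(5)))
  ct <- rbind(spec_impl, spec_oracle)
  expect_gt(suppressWarnings(chisq.test(ct))$p.value, 0.01)
})
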