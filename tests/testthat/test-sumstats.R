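test_that("hand-built toy samples give the printed statistic values", {
  # every individual sings the same single type
  sv <- summary_vector(make_fixture("toy_single_type"))
  expect_equal(unname(sv[["prop_singleton"]]), 0)
  expect_equal(unname(sv[["n_types"]]), 1)
  expect_equal(unname(sv[["max_singers"]]), 5)
  expect_equal(unname(sv[["diversity_H"]]), 0)   # 1 * log2(1)
  expect_equal(unname(sv[["share_any"]]), 1)
  expect_equal(unname(sv[["share_multi"]]), 0)
  expect_true(is.na(sv[["powerlaw_exp"]]))       # degenerate sentinel

  # two types at f = {0.5, 0.5}: H = -1 with the printed sign convention
  sv2 <- summary_vector(make_fixture("toy_half_half"))
  expect_equal(unname(sv2[["diversity_H"]]), -1)
  expect_true(is.na(sv2[["powerlaw_exp"]]))      # sum ln(2 f) = 0

  # all pairs share exactly one type
  sv3 <- summary_vector(list(c("A", "X1"), c("A", "X2"), c("A", "X3")))
  expect_equal(unname(sv3[["share_any"]]), 1)
  expect_equal(unname(sv3[["share_multi"]]), 0)
})

test_that("the power-law exponent is the literal printed formula", {
  a <- powerlaw_exponent(c(0.75, 0.25))
  expect_equal(a, 1 + 2 / (log(1.5) + log(0.5)))
  expect_equal(round(a, 2), -5.95)
  expect_true(is.na(powerlaw_exponent(c(0.5, 0.5))))
  # proportions are invariant under duplicating every individual
  s1 <- summary_vector(list(c("A", "B"), "A", "A"))
  s2 <- summary_vector(list(c("A", "B"), "A", "A", c("A", "B"), "A", "A"))
  expect_equal(s1[["powerlaw_exp"]], s2[["powerlaw_exp"]])
})

test_that("KS statistic equals a brute-force recomputation", {
  set.seed(20)
  res <- run_simulation(sim_params(N_p = 100, N_s = 80, mu = 0.05,
                                   alpha = 1.2, years = 100), seed = 21)
  smp <- sample_individuals(res$population, 50, seed = 22)
  sv <- summary_vector(smp)
  k <- table(unlist(smp$syllables))
  f <- as.numeric(k) / sum(k)
  a <- 1 + length(f) / sum(log(2 * f))
  n <- 50
  fit_pmf <- seq_len(n)^(-a) / sum(seq_len(n)^(-a))
  emp_pmf <- tabulate(as.numeric(k), n) / length(k)
  expect_equal(unname(sv[["ks_fit"]]),
               max(abs(cumsum(emp_pmf) - cumsum(fit_pmf))))
  expect_equal(unname(sv[["fit_at_2"]]),
               abs(cumsum(emp_pmf)[2] - cumsum(fit_pmf)[2]))
})

test_that("singleton/intermediate/common proportions partition the types", {
  set.seed(23)
  for (i in 1:5) {
    res <- run_simulation(sim_params(N_p = 80, N_s = 60, mu = 0.08,
                                     alpha = 1.1, years = 60))
    sv <- summary_vector(sample_individuals(res$population, 40))
    expect_equal(unname(sv[["prop_singleton"]] + sv[["prop_intermediate"]] +
                        sv[["prop_common"]]), 1)
    expect_gte(sv[["prop_rare"]], sv[["prop_singleton"]])
  }
})

test_that("statistics are invariant to relabeling and reordering", {
  sets <- list(c("A", "B"), c("B", "C"), "C", c("A", "C", "D"))
  sv <- summary_vector(sets)
  relab <- lapply(sets, function(s)
    c(A = "w", B = "x", C = "y", D = "z")[s])
  sv2 <- summary_vector(unname(relab))
  expect_equal(unname(unclass(sv)), unname(unclass(sv2)))
  sv3 <- summary_vector(sets[c(3, 1, 4, 2)])
  expect_equal(unname(unclass(sv)), unname(unclass(sv3)))
})

test_that("the logit transform clamps boundaries and passes others through", {
  sv <- summary_vector(make_fixture("toy_single_type"))
  tv <- transform_vector(sv)
  expect_true(is.finite(tv[["share_any"]]))      # logit(1) clamped
  expect_equal(tv[["n_types"]], unname(sv[["n_types"]]))
  expect_true(is.na(tv[["powerlaw_exp"]]))       # sentinel preserved
  # a proportion of exactly 0.5 maps to logit 0
  sv2 <- summary_vector(list(c("A", "B"), c("B", "C"), c("C", "D"),
                             c("D", "E")))
  expect_equal(unname(sv2[["share_any"]]), 0.5)
  tv2 <- transform_vector(sv2)
  expect_equal(unname(tv2[["share_any"]]), 0)
})

test_that("the mean type correlation matches a direct computation", {
  sets <- list(c("A", "B"), c("A", "B"), "A", "C")
  sv <- summary_vector(sets)
  n <- 4
  p <- c(A = 3, B = 2, C = 1) / n
  pj <- c(AB = 2, AC = 0, BC = 0) / n
  r <- function(pij, pi_, pj_)
    (pij - pi_ * pj_) / sqrt(pi_ * (1 - pi_) * pj_ * (1 - pj_))
  rs <- c(r(pj[["AB"]], p[["A"]], p[["B"]]),
          r(pj[["AC"]], p[["A"]], p[["C"]]),
          r(pj[["BC"]], p[["B"]], p[["C"]]))
  w <- c(sqrt(p[["A"]] * p[["B"]]), sqrt(p[["A"]] * p[["C"]]),
         sqrt(p[["B"]] * p[["C"]]))
  expect_equal(unname(sv[["mean_type_cor"]]), sum(rs * w) / sum(w))
})

test_that("the statistics table has one row per population, raw and transformed", {
  tab <- summary_table(make_fixture("mini_study")$sample)
  expect_equal(nrow(tab), 3)
  expect_equal(ncol(tab), 27)  # population + 13 raw + 13 transformed
  expect_true(all(paste0(c("n_types", "share_any"), "_t") %in% names(tab)))
  expect_equal(tab$n_types, tab$n_types_t)  # pass-through columns
})
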