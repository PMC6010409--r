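test_that("prior draws respect bounds and log-uniformity", {
  spec <- prior_spec(model = 1)
  th <- sample_prior(spec, 2e4, seed = 40)
  expect_true(all(th$mu >= 1e-4 & th$mu <= 0.3))
  expect_true(all(th$p_att >= 0.01 & th$p_att <= 1))
  expect_true(all(th$alpha >= 0.25 & th$alpha <= 4))
  # log-uniform: log(mu) passes a uniformity KS test
  expect_gt(ks.test(log(th$mu), "punif", log(1e-4), log(0.3))$p.value,
            0.01)
  expect_gt(ks.test(th$p_att, "punif", 0.01, 1)$p.value, 0.01)
})

test_that("fixed parameters are pinned and removed from the spec", {
  spec <- prior_spec(model = 1, fixed = list(N_T = 5, N_p = 500))
  expect_false(any(c("N_T", "N_p") %in% spec$name))
  th <- sample_prior(spec, 10, seed = 41)
  expect_true(all(th$N_T == 5))
  expect_true(all(th$N_p == 500))
  spec2 <- prior_spec(model = 2)
  expect_true(all(c("N_T1", "N_T2", "W") %in% spec2$name))
  expect_false("alpha" %in% spec2$name)
})

test_that("the PLS-score discrepancy is the distance between means", {
  a <- matrix(rnorm(18), 3, 6)
  expect_equal(discrepancy(a, a), 0)
  b <- sweep(a, 2, c(3, 4, 0, 0, 0, 0), "+")
  expect_equal(discrepancy(b, a), 5)
  expect_equal(discrepancy(a[c(2, 3, 1), ], a), 0)  # mean invariance
  a_na <- a; a_na[1, 1] <- NA
  expect_equal(discrepancy(a_na, a), Inf)
})

test_that("posterior summaries use weighted quantiles", {
  spec <- prior_spec(model = 1, fixed = list(N_p = 500, N_s = 200,
                                             N_T = 5, v = 1, p_att = 0.6))
  one <- data.frame(alpha = 1.5, mu = 0.02, weight = 1, distance = 0.1)
  s <- posterior_summary(one, spec)
  expect_equal(s$estimates$median, c(1.5, 0.02))
  expect_equal(s$estimates$lower, s$estimates$upper)
  eq <- data.frame(alpha = c(1, 2, 3), mu = rep(0.02, 3),
                   weight = rep(1 / 3, 3), distance = 0.1)
  expect_equal(posterior_summary(eq, spec)$estimates$median[1], 2)
  sk <- data.frame(alpha = c(1, 100), mu = rep(0.02, 2),
                   weight = c(0.9, 0.1), distance = 0.1)
  expect_equal(posterior_summary(sk, spec)$estimates$median[1], 1)
})

tiny_setup <- function() {
  list(base = sim_params(model = 1, N_p = 60, N_s = 180, years = 60,
                         N_T = 5),
       spec = prior_spec(model = 1,
                         fixed = list(N_p = 60, N_s = 180, N_T = 5,
                                      v = 0.1, p_att = 1)),
       design = study_design(labels = c("a", "b"), n = c(25, 25),
                             true_params = sim_params(model = 1,
                               alpha = 1.3, mu = 0.02, p_att = 1,
                               v = 0.1, N_T = 5, N_p = 60, N_s = 180,
                               years = 60)))
}

test_that("with an enormous tolerance PMC round 1 reproduces the prior", {
  ts <- tiny_setup()
  obs <- generate_study(ts$design, seed = 42)$sample
  pp <- prior_predictive(ts$spec, ts$base, 40, sample_n = 25, seed = 43)
  ok <- !apply(pp$stats, 1, anyNA)
  proj <- fit_projection(pp$stats[ok, ], pp$z[ok, , drop = FALSE], k = 3)
  fit <- pmc_fit(obs, ts$spec, ts$base, proj, schedule = 1e9,
                 n_rounds = 1, n_particles = 120, seed = 44)
  ps <- fit$rounds[[1]]
  expect_equal(sum(ps$weight), 1)
  expect_gt(ks.test(log(ps$mu), "punif", log(1e-4), log(0.3))$p.value,
            0.01)
  expect_gt(ks.test(log(ps$alpha), "punif", log(0.25), log(4))$p.value,
            0.01)
})

test_that("PMC runs are seed-reproducible and sharpen across rounds", {
  ts <- tiny_setup()
  obs <- generate_study(ts$design, seed = 45)$sample
  pp <- prior_predictive(ts$spec, ts$base, 50, sample_n = 25, seed = 46)
  ok <- !apply(pp$stats, 1, anyNA)
  proj <- fit_projection(pp$stats[ok, ], pp$z[ok, , drop = FALSE], k = 3)
  om <- colMeans(t(vapply(split_populations(obs), function(s)
    project_scores(transform_vector(summary_vector(s)), proj),
    numeric(3))))
  d0 <- apply(project_scores(pp$stats[ok, ], proj), 1,
              function(sc) sqrt(sum((sc - om)^2)))
  sched <- recalibrate_schedule(d0, quantiles = c(0.6, 0.3))
  fit1 <- pmc_fit(obs, ts$spec, ts$base, proj, sched, n_particles = 40,
                  seed = 47)
  fit2 <- pmc_fit(obs, ts$spec, ts$base, proj, sched, n_particles = 40,
                  seed = 47)
  expect_identical(fit1$rounds, fit2$rounds)
  meds <- vapply(fit1$rounds, function(r) median(r$distance), 0)
  expect_lte(meds[2], meds[1])             # distances non-increasing
  expect_true(all(fit1$ess > 0))
  for (r in fit1$rounds) expect_equal(sum(r$weight), 1)
})

test_that("tolerance recalibration yields a decreasing positive schedule", {
  set.seed(48)
  d <- rexp(200, 1) + 0.1
  eps <- recalibrate_schedule(d, quantiles = c(0.4, 0.2, 0.1, 0.05))
  expect_length(eps, 4)
  expect_true(all(eps > 0))
  expect_true(all(diff(eps) < 0))
})

test_that("cross-validation is deterministic and well-formed", {
  ts <- tiny_setup()
  cv1 <- cross_validate(ts$spec, ts$base, n_sims = 120, sample_n = 25,
                        k = 2, seed = 49)
  cv2 <- cross_validate(ts$spec, ts$base, n_sims = 120, sample_n = 25,
                        k = 2, seed = 49)
  expect_identical(cv1, cv2)
  expect_setequal(cv1$parameter, c("alpha", "mu"))
  expect_true(all(cv1$relative_error > 0))
  expect_true(all(is.finite(cv1$relative_error)))
})

test_that("the adaptive schedule tightens from the accepted distances", {
  ts <- tiny_setup()
  obs <- generate_study(ts$design, seed = 50)$sample
  pp <- prior_predictive(ts$spec, ts$base, 40, sample_n = 25, seed = 51)
  ok <- !apply(pp$stats, 1, anyNA)
  proj <- fit_projection(pp$stats[ok, ], pp$z[ok, , drop = FALSE], k = 3)
  eps1 <- recalibrate_schedule(prior_distances(pp, obs, proj),
                               quantiles = 0.6)
  fit <- pmc_fit(obs, ts$spec, ts$base, proj, schedule = eps1,
                 n_rounds = 2, adapt_q = 0.5, n_particles = 30, seed = 52)
  expect_length(fit$schedule, 2)
  expect_lt(fit$schedule[2], fit$schedule[1])
  expect_equal(fit$schedule[2],
               unname(quantile(fit$rounds[[1]]$distance, 0.5)))
  expect_true(all(fit$rounds[[2]]$distance < fit$schedule[2]))
})
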