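#' Prior specification for the learning models
#'
#' Default priors: log-uniform for `N_p` {400, 3000}, `N_s` {180, 500},
#' `N_T` {2.5, 50}, `v` {0.01, 6}, `alpha` {0.25, 4}, `mu` {0.0001, 0.3},
#' and for the attrition model `N_T1` {2.5, 15}, `N_T2` {1.5, 50}, `W`
#' {0.01, 20}; uniform for `p_att` {0.01, 1}. Any parameter can be fixed
#' at a constant (removing it from the inference) via `fixed`.
#'
#' @param model 1 (explicit conformist bias) or 2 (attrition).
#' @param fixed Named list of parameters to hold constant, e.g.
#'   `list(N_T = 5, N_p = 500)`.
#' @return A `prior_spec` data frame (columns `name`, `dist`, `lower`,
#'   `upper`) with attribute `fixed`.
#' @export
prior_spec <- function(model = 1, fixed = list()) {
  tab <- data.frame(
    name  = c("N_p", "N_s", "N_T", "v", "alpha", "mu", "p_att",
              "N_T1", "N_T2", "W"),
    dist  = c(rep("log-uniform", 6), "uniform", rep("log-uniform", 3)),
    lower = c(400, 180, 2.5, 0.01, 0.25, 1e-04, 0.01, 2.5, 1.5, 0.01),
    upper = c(3000, 500, 50, 6, 4, 0.3, 1, 15, 50, 20),
    stringsAsFactors = FALSE)
  keep <- if (model == 1) c("N_p", "N_s", "N_T", "v", "alpha", "mu", "p_att")
          else c("N_p", "N_s", "v", "mu", "p_att", "N_T1", "N_T2", "W")
  tab <- tab[tab$name %in% setdiff(keep, names(fixed)), , drop = FALSE]
  if (any(tab$lower >= tab$upper)) stop("prior lower bound >= upper bound")
  rownames(tab) <- NULL
  structure(tab, fixed = fixed, model = model, class = c("prior_spec",
                                                         "data.frame"))
}

#' Draw parameter vectors from the prior
#'
#' Log-uniform parameters are drawn as `exp(U(log lower, log upper))`,
#' uniform parameters as `U(lower, upper)`; fixed parameters are appended
#' as constant columns.
#'
#' @param spec A [prior_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Data frame of `n` parameter vectors.
#' @export
sample_prior <- function(spec, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "prior_spec"))
  draws <- lapply(seq_len(nrow(spec)), function(i) {
    if (spec$dist[i] == "log-uniform")
      exp(runif(n, log(spec$lower[i]), log(spec$upper[i])))
    else runif(n, spec$lower[i], spec$upper[i])
  })
  out <- as.data.frame(setNames(draws, spec$name))
  for (nm in names(attr(spec, "fixed")))
    out[[nm]] <- attr(spec, "fixed")[[nm]]
  out
}

# working scale: log for log-uniform, natural for uniform priors (on both
# the prior is flat, so importance weights need no density correction)
to_working <- function(theta, spec) {
  z <- as.matrix(theta[, spec$name, drop = FALSE])
  for (i in seq_len(nrow(spec)))
    if (spec$dist[i] == "log-uniform") z[, i] <- log(z[, i])
  z
}

from_working <- function(z, spec) {
  th <- as.data.frame(z)
  names(th) <- spec$name
  for (i in seq_len(nrow(spec)))
    if (spec$dist[i] == "log-uniform") th[[i]] <- exp(th[[i]])
  th
}

in_support <- function(theta, spec) {
  ok <- rep(TRUE, nrow(theta))
  for (i in seq_len(nrow(spec)))
    ok <- ok & theta[[spec$name[i]]] >= spec$lower[i] &
          theta[[spec$name[i]]] <= spec$upper[i]
  ok
}

#' Distance between simulated and observed PLS score sets
#'
#' Euclidean distance, over all PLS dimensions, between the mean of the
#' simulated per-population scores and the mean of the observed ones.
#' Score sets containing `NA` sentinels (degenerate simulations) give
#' `Inf`, which the PMC sampler treats as a rejection.
#'
#' @param sim_scores,obs_scores Matrices (populations x components) or
#'   vectors of per-population PLS scores.
#' @return Nonnegative scalar distance.
#' @export
discrepancy <- function(sim_scores, obs_scores) {
  sm <- if (is.null(dim(sim_scores))) sim_scores else colMeans(sim_scores)
  om <- if (is.null(dim(obs_scores))) obs_scores else colMeans(obs_scores)
  stopifnot(length(sm) == length(om))
  if (anyNA(sm) || anyNA(om)) return(Inf)
  sqrt(sum((sm - om)^2))
}

# average transformed statistics over n_sub independent subsamples of a
# simulated population; a sentinel in any subsample poisons the row
sampled_stats <- function(pop, n, n_sub) {
  acc <- 0
  for (s in seq_len(n_sub)) {
    smp <- sample_individuals(pop, n)
    acc <- acc + transform_vector(summary_vector(smp))
  }
  acc / n_sub
}

# simulate all populations for one parameter vector and return the matrix
# of per-population PLS scores (one theta applied to every population);
# n_sub subsamples per population average away sampling noise at no
# simulation cost
simulate_scores <- function(theta, base_params, sample_sizes, proj,
                            n_sub = 1) {
  params <- update_params(base_params, theta)
  t(vapply(sample_sizes, function(n) {
    res <- run_simulation(params)
    project_scores(sampled_stats(res$population, min(n, params$N_p),
                                 n_sub), proj)
  }, numeric(proj$k)))
}

#' Prior-predictive simulation batch
#'
#' Draws `n` parameter vectors from the prior and simulates one
#' population per draw, returning the transformed statistics and the
#' working-scale parameters — the training material for
#' [fit_projection()] and for recalibrating the tolerance schedule.
#'
#' @param spec A [prior_spec()].
#' @param base_params Baseline [sim_params()] (model, years, mortality,
#'   repertoire-size distribution); prior draws overwrite its fields.
#' @param n Number of prior draws.
#' @param sample_n Individuals sampled from each simulated population.
#' @param n_sub Number of independent subsamples per simulated
#'   population whose transformed statistics are averaged (reduces
#'   sampling noise without extra simulations; the observed data always
#'   remain a single sample).
#' @param seed Optional integer seed.
#' @return List with `theta` (natural scale), `z` (working scale),
#'   `stats` (n x 13 transformed statistics).
#' @export
prior_predictive <- function(spec, base_params, n, sample_n, n_sub = 1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- sample_prior(spec, n)
  stats <- matrix(NA_real_, n, 13, dimnames = list(NULL, stat_names))
  for (i in seq_len(n)) {
    params <- update_params(base_params, theta[i, , drop = FALSE])
    res <- run_simulation(params)
    stats[i, ] <- sampled_stats(res$population,
                                min(sample_n, params$N_p), n_sub)
  }
  list(theta = theta, z = to_working(theta, spec), stats = stats)
}

#' Distances of prior-predictive simulations from an observed sample
#'
#' Projects each prior-predictive statistics row and the observed
#' per-population statistics with the same fitted projection, and
#' returns the Euclidean distance of every simulated score vector from
#' the observed mean score vector — the raw material for
#' [recalibrate_schedule()].
#'
#' @param batch A [prior_predictive()] result.
#' @param observed A multi-population `repertoire_sample` (or list of
#'   single-population samples).
#' @param proj A fitted [fit_projection()].
#' @return Numeric vector of distances (`NA` rows give `Inf`).
#' @export
prior_distances <- function(batch, observed, proj) {
  obs_list <- if (is.data.frame(observed)) split_populations(observed)
              else observed
  om <- colMeans(t(vapply(obs_list, function(s)
    project_scores(transform_vector(summary_vector(s)), proj),
    numeric(proj$k))))
  apply(batch$stats, 1, function(row) {
    if (anyNA(row)) return(Inf)
    sc <- project_scores(row, proj)
    sqrt(sum((sc - om)^2))
  })
}

#' Recalibrate a tolerance schedule from prior-predictive distances
#'
#' The absolute tolerances of any published schedule are tied to the
#' scaling of the projection they were computed under; a schedule for a
#' new projection is therefore set from quantiles of the distances
#' achieved by prior-predictive simulations.
#'
#' @param distances Finite prior-predictive distances.
#' @param quantiles Decreasing quantile levels, one per PMC round (default
#'   a geometric series 0.5, 0.3, 0.2, 0.12).
#' @return Strictly decreasing positive tolerance vector.
#' @export
recalibrate_schedule <- function(distances,
                                 quantiles = c(0.5, 0.3, 0.2, 0.12)) {
  d <- distances[is.finite(distances)]
  stopifnot(length(d) > 10, all(diff(quantiles) < 0))
  eps <- as.numeric(quantile(d, quantiles))
  if (any(diff(eps) >= 0)) eps <- rev(sort(unique(eps)))[seq_along(quantiles)]
  eps
}

#' Population Monte Carlo ABC
#'
#' Round 1 is rejection sampling from the prior at the first tolerance;
#' each later round resamples the previous particles by weight, perturbs
#' them with a multivariate Gaussian kernel on the working scale whose
#' covariance is twice the weighted empirical covariance of the previous
#' round (a full covariance, so proposals follow any parameter ridge),
#' rejects proposals outside the prior support, simulates every
#' population, and accepts while the distance to the observed mean PLS
#' scores is below the round's tolerance. Importance weights follow the
#' standard PMC update `w_i = p(theta_i) / sum_j w_j K(theta_i | theta_j)`
#' (the prior is flat on the working scale).
#'
#' @param observed A multi-population `repertoire_sample`, or a list of
#'   single-population samples.
#' @param spec A [prior_spec()].
#' @param base_params Baseline [sim_params()]; prior draws overwrite its
#'   inferred fields.
#' @param proj A fitted [fit_projection()].
#' @param schedule Either a decreasing tolerance vector (one entry per
#'   round, e.g. from [recalibrate_schedule()]), or a single number: the
#'   first-round tolerance of an *adaptive* schedule in which each later
#'   round's tolerance is the `adapt_q` quantile of the previous round's
#'   accepted distances. The adaptive form tracks how fast the particle
#'   cloud concentrates and reaches far smaller final tolerances for the
#'   same simulation budget.
#' @param n_rounds Number of rounds when `schedule` is a single
#'   first-round tolerance (ignored otherwise).
#' @param adapt_q Quantile of the previous round's accepted distances
#'   used as the next tolerance in the adaptive form; a vector is
#'   recycled over rounds 2..n_rounds.
#' @param kernel_scale Multiplier on the weighted empirical covariance
#'   used as the perturbation kernel covariance (2 is the classic PMC
#'   inflation; 1 proposes more locally and accepts more often at some
#'   cost in particle diversity).
#' @param n_sub Subsamples averaged per simulated population (see
#'   [prior_predictive()]).
#' @param n_particles Accepted particles per round (default 1000).
#' @param seed Optional integer seed.
#' @param max_tries Cap on simulation attempts per round, as a multiple
#'   of `n_particles`; exceeded acceptance floor aborts with a
#'   diagnostic.
#' @param progress Print per-round diagnostics.
#' @return List of class `pmc_fit`: per-round `particle_set` data frames
#'   (parameters, `weight`, `distance`), plus the schedule and
#'   effective sample sizes.
#' @export
pmc_fit <- function(observed, spec, base_params, proj, schedule,
                    n_rounds = 4, adapt_q = 0.35, n_particles = 1000,
                    kernel_scale = 2, n_sub = 1, seed = NULL,
                    max_tries = 200, progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  adaptive <- length(schedule) == 1 && n_rounds > 1
  if (adaptive) schedule <- c(schedule, rep(NA_real_, n_rounds - 1))
  obs_list <- if (is.data.frame(observed)) split_populations(observed)
              else observed
  sample_sizes <- vapply(obs_list, nrow, 0L)
  obs_scores <- t(vapply(obs_list, function(s)
    project_scores(transform_vector(summary_vector(s)), proj),
    numeric(proj$k)))

  p <- nrow(spec)
  rounds <- list()
  ess <- numeric(length(schedule))
  z_prev <- NULL; w_prev <- NULL

  for (r in seq_along(schedule)) {
    if (adaptive && r > 1)
      schedule[r] <- unname(quantile(rounds[[r - 1]]$distance,
                                     rep_len(adapt_q, length(schedule) -
                                             1)[r - 1]))
    eps <- schedule[r]
    acc_z <- matrix(NA_real_, n_particles, p)
    acc_d <- numeric(n_particles)
    acc_w <- numeric(n_particles)
    if (r > 1) {
      kcov <- kernel_scale *
        stats::cov.wt(z_prev, wt = w_prev, method = "ML")$cov
      kL <- chol(kcov + diag(1e-10, p))      # t(kL) %*% kL = kcov
      kLinv <- backsolve(kL, diag(p))
    }
    n_acc <- 0L; tries <- 0L
    while (n_acc < n_particles) {
      tries <- tries + 1L
      if (tries > max_tries * n_particles)
        stop("PMC round ", r, ": acceptance rate below floor (",
             n_acc, "/", tries, " at eps=", signif(eps, 3), ")")
      if (r == 1) {
        theta <- sample_prior(spec, 1)
        z <- to_working(theta, spec)
      } else {
        j <- sample.int(nrow(z_prev), 1, prob = w_prev)
        z <- z_prev[j, ] + drop(rnorm(p) %*% kL)
        z <- matrix(z, 1, dimnames = list(NULL, spec$name))
        theta <- from_working(z, spec)
        for (nm in names(attr(spec, "fixed")))
          theta[[nm]] <- attr(spec, "fixed")[[nm]]
        if (!in_support(theta, spec)) next
      }
      d <- discrepancy(simulate_scores(theta, base_params, sample_sizes,
                                       proj, n_sub), obs_scores)
      if (d < eps) {
        n_acc <- n_acc + 1L
        acc_z[n_acc, ] <- z
        acc_d[n_acc] <- d
      }
    }
    if (r == 1) {
      acc_w <- rep(1 / n_particles, n_particles)
    } else {
      # kernel mixture density at each accepted particle (the Gaussian
      # normalising constant is common to all terms and cancels)
      for (i in seq_len(n_particles)) {
        diffs <- sweep(z_prev, 2, acc_z[i, ])
        d2 <- rowSums((diffs %*% kLinv)^2)
        acc_w[i] <- 1 / sum(w_prev * exp(-0.5 * d2))
      }
      acc_w <- acc_w / sum(acc_w)
    }
    ess[r] <- 1 / sum(acc_w^2)
    theta_acc <- from_working(acc_z, spec)
    ps <- cbind(theta_acc, weight = acc_w, distance = acc_d)
    class(ps) <- c("particle_set", "data.frame")
    attr(ps, "round") <- r
    attr(ps, "eps") <- eps
    rounds[[r]] <- ps
    z_prev <- acc_z; w_prev <- acc_w
    if (progress)
      message(sprintf("round %d: eps=%.3g accepted %d/%d ESS=%.0f",
                      r, eps, n_particles, tries, ess[r]))
  }
  structure(list(rounds = rounds, schedule = schedule, ess = ess,
                 spec = spec, obs_scores = obs_scores),
            class = "pmc_fit")
}

#' @export
print.pmc_fit <- function(x, ...) {
  cat("PMC-ABC fit: ", length(x$rounds), " rounds, ",
      nrow(x$rounds[[length(x$rounds)]]), " particles/round\n", sep = "")
  cat("  tolerances:", paste(signif(x$schedule, 3), collapse = " "), "\n")
  cat("  final-round ESS:", round(x$ess[length(x$ess)], 1), "\n")
  invisible(x)
}

# weighted quantile, inverse-CDF convention: smallest x with F(x) >= p
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], 0)
}

weighted_cor <- function(z, w) {
  w <- w / sum(w)
  m <- colSums(z * w)
  zc <- sweep(z, 2, m)
  cv <- crossprod(zc * sqrt(w), zc * sqrt(w))
  d <- sqrt(diag(cv))
  cv / tcrossprod(d)
}

#' Posterior summaries of a particle set
#'
#' Weighted medians and 95% credible intervals per parameter (natural
#' scale) and weighted Pearson correlations between parameters on the
#' working (log) scale.
#'
#' @param ps A `particle_set` (one round of [pmc_fit()]), or a `pmc_fit`
#'   (its final round is used).
#' @param spec The [prior_spec()] used for the fit (inferred from a
#'   `pmc_fit`).
#' @return List with data frame `estimates` (`median`, `lower`, `upper`)
#'   and correlation matrix `correlations`.
#' @export
posterior_summary <- function(ps, spec = NULL) {
  if (inherits(ps, "pmc_fit")) {
    spec <- ps$spec
    ps <- ps$rounds[[length(ps$rounds)]]
  }
  stopifnot(!is.null(spec))
  w <- ps$weight
  if (all(w == 0)) stop("all particle weights are zero")
  est <- t(vapply(spec$name, function(nm)
    weighted_quantile(ps[[nm]], w, c(0.5, 0.025, 0.975)), numeric(3)))
  est <- data.frame(parameter = spec$name, median = est[, 1],
                    lower = est[, 2], upper = est[, 3],
                    row.names = NULL)
  z <- to_working(ps, spec)
  list(estimates = est, correlations = weighted_cor(z, w))
}

#' Leave-one-out cross-validation of the ABC design
#'
#' Simulates `n_sims` pseudo-observed datasets directly from the prior
#' and, taking each in turn, estimates its parameters by rejection ABC
#' against the remaining simulations (accepting the closest fraction
#' `tol_prop` by PLS-score distance). Reports, per parameter, the mean
#' squared error of the posterior-median estimate on the working scale
#' relative to the prior variance on that scale: values near 1 mean the
#' data carry no information about the parameter; values well below 1
#' mean it is estimable.
#'
#' @param spec A [prior_spec()] (use `fixed` to pin parameters, e.g.
#'   `N_T = 5`).
#' @param base_params Baseline [sim_params()].
#' @param n_sims Number of prior draws (>= 100).
#' @param sample_n Individuals sampled per simulated population.
#' @param k PLS components.
#' @param tol_prop Accepted fraction for the rejection step.
#' @param seed Optional integer seed.
#' @param batch Optional precomputed [prior_predictive()] batch (used by
#'   the pipeline to avoid re-simulating).
#' @return Data frame: `parameter`, `mse`, `prior_var`,
#'   `relative_error = mse / prior_var`.
#' @export
cross_validate <- function(spec, base_params, n_sims = 1000, sample_n = 60,
                           k = 6, tol_prop = 0.02, seed = NULL,
                           batch = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_sims >= 100)
  if (is.null(batch))
    batch <- prior_predictive(spec, base_params, n_sims, sample_n)
  ok <- !apply(batch$stats, 1, anyNA)
  stats <- batch$stats[ok, , drop = FALSE]
  z <- batch$z[ok, , drop = FALSE]
  n <- nrow(stats)
  proj <- fit_projection(stats, z, k = k)
  scores <- project_scores(stats, proj)
  n_keep <- max(5, ceiling(tol_prop * (n - 1)))
  err <- matrix(NA_real_, n, ncol(z))
  for (i in seq_len(n)) {
    d2 <- colSums((t(scores) - scores[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(n_keep)]
    est <- apply(z[nb, , drop = FALSE], 2, stats::median)
    err[i, ] <- (est - z[i, ])^2
  }
  pv <- apply(z, 2, var)
  data.frame(parameter = spec$name,
             mse = colMeans(err),
             prior_var = pv,
             relative_error = colMeans(err) / pv,
             row.names = NULL)
}
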