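#' Default repertoire-size distribution
#'
#' Categorical distribution over adult repertoire sizes 1..6 with mode 3,
#' emulating field repertoire surveys of swamp sparrows (typical repertoire
#' around 3 syllable types, range 1-6). Replace it with an empirical
#' distribution via the `rep_probs` argument of [sim_params()].
#'
#' @return Numeric vector of probabilities for repertoire sizes 1..6.
#' @export
default_rep_probs <- function() {
  c(0.05, 0.20, 0.40, 0.20, 0.10, 0.05)
}

#' Simulation parameters for the song-learning models
#'
#' Bundles and validates the parameters of the individual-based
#' transmission models. Model 1 uses an explicit conformist bias: a
#' juvenile memorises the repertoires of `N_T` adults and picks syllable
#' types with probability proportional to `F^alpha * M * T`, where `F` is
#' the type's frequency among the demonstrators, `M` its content
#' attractiveness and `T` the mean attractiveness of the demonstrators
#' singing it. Model 2 generates conformity implicitly through
#' overproduction and selective attrition: the union of `N_T1` memorised
#' repertoires is pruned one type at a time, the type to drop being the
#' one left unselected by a weighted draw with weights `(W + G) * M * T`,
#' where `G` counts how often the type was heard in a second sample of
#' `N_T2` adults.
#'
#' @param mu Mutation (innovation/error/immigration) probability per
#'   syllable-learning event, in `[0, 1]`.
#' @param N_T Number of demonstrators memorised (model 1). Non-integer
#'   values (e.g. from a log-uniform prior) are rounded at use.
#' @param v Dispersion (standard deviation of the log-scale normal) of the
#'   demonstrator-attractiveness score `t = exp(N(0, v))`; `v = 0` switches
#'   demonstrator bias off.
#' @param p_att Proportion of syllable types that are attractive
#'   (`M = 1`); the rest get `M = 0.05`. In `(0, 1]`.
#' @param alpha Conformity exponent; `alpha > 1` is a conformist bias,
#'   `alpha < 1` anti-conformist.
#' @param N_p Population size (constant through time).
#' @param N_s Number of possible syllable types.
#' @param mortality Per-year death probability (default 0.4).
#' @param years Simulation length in years (default 5000).
#' @param model Learning rule: 1 (explicit bias) or 2 (attrition).
#' @param N_T1,N_T2,W Model-2 parameters: sizes of the two demonstrator
#'   samples and the weight of phase-1 evidence. Ignored when `model = 1`.
#' @param rep_probs Probabilities of adult repertoire sizes `1..length()`;
#'   defaults to [default_rep_probs()].
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(N_p = 100, N_s = 200, mu = 0.01, alpha = 1.2)
#' @export
sim_params <- function(mu = 0.01, N_T = 5, v = 0, p_att = 1, alpha = 1,
                       N_p = 500, N_s = 200, mortality = 0.4, years = 5000,
                       model = 1, N_T1 = 3, N_T2 = 4, W = 1.5,
                       rep_probs = default_rep_probs()) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0, mu <= 1)
  stopifnot(p_att > 0, p_att <= 1)
  stopifnot(alpha > 0)
  stopifnot(mortality >= 0, mortality < 1)
  stopifnot(years >= 0, N_p >= 2)
  stopifnot(model %in% c(1, 2))
  stopifnot(v >= 0, W > 0)
  if (model == 1 && round(N_T) < 1) stop("N_T must be >= 1 when model = 1")
  if (model == 2 && (round(N_T1) < 1 || round(N_T2) < 1))
    stop("N_T1 and N_T2 must be >= 1 when model = 2")
  if (any(rep_probs < 0) || sum(rep_probs) <= 0)
    stop("rep_probs must be nonnegative and sum to a positive value")
  rep_probs <- rep_probs / sum(rep_probs)
  max_rm <- max(which(rep_probs > 0))
  if (N_s < max_rm)
    stop("invalid configuration: N_s (", N_s,
         ") is smaller than the largest possible repertoire size (",
         max_rm, ")")
  structure(list(mu = mu, N_T = N_T, v = v, p_att = p_att, alpha = alpha,
                 N_p = as.integer(N_p), N_s = as.integer(N_s),
                 mortality = mortality, years = as.integer(years),
                 model = as.integer(model), N_T1 = N_T1, N_T2 = N_T2,
                 W = W, rep_probs = rep_probs),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Song-learning simulation parameters (model ", x$model, ")\n",
      sep = "")
  cat(sprintf("  N_p=%d  N_s=%d  years=%d  mortality=%.2f\n",
              x$N_p, x$N_s, x$years, x$mortality))
  cat(sprintf("  mu=%.4g  v=%.3g  p_att=%.3g\n", x$mu, x$v, x$p_att))
  if (x$model == 1) {
    cat(sprintf("  alpha=%.3g  N_T=%.3g\n", x$alpha, x$N_T))
  } else {
    cat(sprintf("  N_T1=%.3g  N_T2=%.3g  W=%.3g\n", x$N_T1, x$N_T2, x$W))
  }
  invisible(x)
}

#' Update simulation parameters from a named list
#'
#' Convenience used by the inference layer: returns `params` with the
#' entries named in `theta` replaced. Unknown names are an error.
#'
#' @param params A [sim_params()] object.
#' @param theta Named list or vector of replacement values.
#' @return A revalidated `sim_params` object.
#' @export
update_params <- function(params, theta) {
  stopifnot(inherits(params, "sim_params"))
  theta <- as.list(theta)
  bad <- setdiff(names(theta), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(theta)] <- theta
  do.call(sim_params, p)
}
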