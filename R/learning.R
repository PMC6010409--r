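#' Conformist choice weights (model 1)
#'
#' Normalised probability of selecting each memorised syllable type under
#' the explicit-bias rule: proportional to `F^alpha * M * T`, where `F`
#' is the number of demonstrators in the memorised sample that sang the
#' type, `M` its content attractiveness and `T` the mean attractiveness
#' of those demonstrators. `alpha > 1` boosts common types beyond their
#' sample frequency.
#'
#' @param counts Positive numeric vector of demonstrator counts `F` per
#'   memorised type.
#' @param alpha Conformity exponent (> 0).
#' @param M,T Content and demonstrator attractiveness per type; recycled.
#' @return Probability vector summing to 1, same length as `counts`.
#' @examples
#' # one type heard from 5 demonstrators, ten types heard once:
#' choice_weights(c(5, rep(1, 10)), alpha = 1.316)[1]  # ~0.45
#' choice_weights(c(5, rep(1, 10)), alpha = 1)[1]      # 1/3
#' @export
choice_weights <- function(counts, alpha = 1, M = 1, T = 1) {
  if (length(counts) == 0) stop("memory is empty")
  stopifnot(all(counts > 0), alpha > 0)
  w <- counts^alpha * rep_len(M, length(counts)) * rep_len(T, length(counts))
  if (!any(w > 0)) stop("all choice weights are zero")
  w / sum(w)
}

#' Learn a repertoire under model 1 (explicit conformist bias)
#'
#' Samples `N_T` demonstrators uniformly without replacement from the
#' adult pool, memorises their syllable types with sample frequencies `F`
#' and mean demonstrator scores `T`, and draws `r_m` types without
#' replacement with probabilities proportional to `F^alpha * M * T`.
#' Each drawn syllable mutates with probability `mu` into a uniformly
#' chosen different type not already in the repertoire; the final
#' repertoire is a set of distinct types. If the memory holds fewer than
#' `r_m` distinct types, the whole memory is kept and each remaining slot
#' is filled by a uniform innovation with probability `mu` (so no novelty
#' can enter when `mu = 0`).
#'
#' @param pool A `song_population` (or list with `repertoires`, `t_m`,
#'   `M`) of surviving adults to learn from.
#' @param params A [sim_params()] object (uses `alpha`, `mu`, `N_T`,
#'   `N_s`).
#' @param r_m Target repertoire size (>= 1).
#' @param seed Optional integer seed.
#' @return Integer vector of distinct syllable types.
#' @export
learn_repertoire_m1 <- function(pool, params, r_m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(r_m >= 1)
  .cpp_learn_m1(pool$repertoires, pool$t_m, pool$M, params$alpha,
                params$mu, as.integer(round(params$N_T)),
                as.integer(r_m))
}

#' One attrition step (model 2)
#'
#' Selects syllable types by weighted sampling without replacement until a
#' single type remains unselected, and removes that type — equivalently,
#' removes the last item of a Plackett-Luce ordering with the given
#' weights. Common (heavily weighted) types are rarely last, which is the
#' source of the emergent conformist bias in the attrition model.
#'
#' @param weights Positive weights, length >= 2 (`(W + G) * M * T` in the
#'   full model).
#' @param n Number of independent removal draws to return.
#' @param seed Optional integer seed.
#' @return The 1-based index of the removed item (an integer vector when
#'   `n > 1`).
#' @examples
#' table(removal_step(c(2, 1, 1), n = 1000))  # heavy item rarely removed
#' @export
removal_step <- function(weights, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(weights) < 2) stop("need at least 2 items to remove one")
  stopifnot(all(weights >= 0), n >= 1)
  out <- .cpp_pl_last(weights, as.integer(n))
  if (n == 1) out[1] else out
}

#' Learn a repertoire under model 2 (overproduction and attrition)
#'
#' Phase 1 memorises the union of `N_T1` adult repertoires (truncated to
#' at most 8 types by attrition steps before any phase-2 evidence, i.e.
#' with weights `W * M * T`). Phase 2 samples `N_T2` further adults,
#' disjoint from the first sample, and counts for each memorised type the
#' number of phase-2 repertoires containing it (`G`; types first heard in
#' phase 2 cannot be memorised). Attrition steps with weights
#' `(W + G) * M * T` then shrink the memory to `r_m` types. Each retained
#' syllable finally mutates with probability `mu`.
#'
#' @inheritParams learn_repertoire_m1
#' @return Integer vector of distinct syllable types (may be shorter than
#'   `r_m` if the phase-1 memory was smaller).
#' @export
learn_repertoire_m2 <- function(pool, params, r_m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(r_m >= 1)
  .cpp_learn_m2(pool$repertoires, pool$t_m, pool$M, params$mu,
                as.integer(round(params$N_T1)),
                as.integer(round(params$N_T2)), params$W,
                as.integer(r_m))
}
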