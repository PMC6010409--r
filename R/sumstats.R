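stat_names <- c("prop_singleton", "prop_rare", "prop_intermediate",
                "prop_common", "n_types", "max_singers", "diversity_H",
                "powerlaw_exp", "ks_fit", "fit_at_2", "share_any",
                "share_multi", "mean_type_cor")

logit_stats <- c("prop_singleton", "prop_rare", "prop_intermediate",
                 "prop_common", "share_any", "share_multi")

#' Power-law exponent of a type-frequency distribution
#'
#' Literal evaluation of `alpha_p = 1 + ns * (sum_i ln(2 f_i))^-1` over
#' the type proportions `f_i`. Returns `NA` (a sentinel the ABC layer
#' treats as infinite distance) when the denominator vanishes, e.g. for
#' `f = {0.5, 0.5}`.
#'
#' @param freqs Type proportions summing to 1 (>= 2 types).
#' @return The exponent, or `NA_real_` when undefined.
#' @export
powerlaw_exponent <- function(freqs) {
  stopifnot(length(freqs) >= 2, all(freqs > 0))
  denom <- sum(log(2 * freqs))
  if (abs(denom) < 1e-12) return(NA_real_)
  1 + length(freqs) / denom
}

# discrete power-law pmf over singer counts 1..n with exponent a
powerlaw_pmf <- function(a, n) {
  k <- seq_len(n)
  w <- k^(-a)
  w / sum(w)
}

#' The 13 summary statistics of a repertoire sample
#'
#' Computes, for a single-population sample of individual syllable-type
#' sets: (1) proportion of types sung by one individual; (2) by at most 4;
#' (3) by more than one but at most `c` individuals, `c` = 5% of the
#' number of types (rounded up, at least 1); (4) by more than `c`; (5) the
#' number of types `ns`; (6) the number of individuals singing the
#' commonest type; (7) the diversity index `H = sum_i f_i log2(f_i)` over
#' token proportions `f_i` (the negative Shannon entropy, kept with this
#' sign); (8) the power-law exponent [powerlaw_exponent()]; (9) the
#' Kolmogorov-Smirnov statistic between the empirical distribution of
#' singer counts and the fitted discrete power law on support `1..n`;
#' (10) the absolute discrepancy of those two cumulative distributions at
#' a singer count of 2; (11) the proportion of pairs of individuals
#' sharing at least one type; (12) sharing more than one; (13) the
#' weighted mean correlation coefficient between types,
#' `rbar = sum r_ij sqrt(p_i p_j) / sum sqrt(p_i p_j)` over distinct type
#' pairs, where `p_i` is the proportion of individuals singing type `i`.
#'
#' Statistics that are undefined on degenerate samples (a single type, a
#' vanishing power-law denominator, or no valid type pair) are returned
#' as `NA` sentinels; the ABC layer rejects such simulations.
#'
#' @param sample A single-population `repertoire_sample`, or a list of
#'   character vectors of type labels (>= 2 individuals).
#' @return Named numeric vector of length 13 (class `summary_vector`),
#'   with attributes `n_individuals` and `c_threshold`.
#' @export
summary_vector <- function(sample) {
  sets <- if (is.data.frame(sample)) sample$syllables else sample
  sets <- lapply(sets, as.character)
  n <- length(sets)
  if (n < 2) stop("need at least 2 individuals")
  types <- sort(unique(unlist(sets)))
  ns <- length(types)
  B <- matrix(0L, n, ns, dimnames = list(NULL, types))
  for (i in seq_len(n)) B[i, sets[[i]]] <- 1L
  k <- colSums(B)                      # singers per type (= tokens)
  f <- k / sum(k)                      # token proportions
  c_thr <- max(1, ceiling(0.05 * ns))

  s <- c(prop_singleton = mean(k == 1),
         prop_rare = mean(k <= 4),
         prop_intermediate = mean(k > 1 & k <= c_thr),
         prop_common = mean(k > c_thr),
         n_types = ns,
         max_singers = max(k),
         diversity_H = sum(f * log2(f)),
         powerlaw_exp = NA_real_, ks_fit = NA_real_, fit_at_2 = NA_real_,
         share_any = NA_real_, share_multi = NA_real_,
         mean_type_cor = NA_real_)

  if (ns >= 2) {
    a <- powerlaw_exponent(f)
    s["powerlaw_exp"] <- a
    if (!is.na(a)) {
      emp <- tabulate(k, nbins = n) / ns
      gap <- abs(cumsum(emp) - cumsum(powerlaw_pmf(a, n)))
      s["ks_fit"] <- max(gap)
      s["fit_at_2"] <- gap[2]
    }
  }

  A <- tcrossprod(B)
  ut <- upper.tri(A)
  s["share_any"] <- mean(A[ut] >= 1)
  s["share_multi"] <- mean(A[ut] > 1)

  if (ns >= 2) {
    p <- k / n
    P <- crossprod(B) / n              # joint presence probabilities
    pi <- matrix(p, ns, ns)
    pj <- t(pi)
    denom <- sqrt(pi * (1 - pi) * pj * (1 - pj))
    r <- (P - pi * pj) / denom
    wt <- sqrt(pi * pj)
    sel <- upper.tri(r) & denom > 0
    if (any(sel))
      s["mean_type_cor"] <- sum(r[sel] * wt[sel]) / sum(wt[sel])
  }

  structure(s, n_individuals = n, c_threshold = c_thr,
            class = "summary_vector")
}

#' Transform a summary vector for inference
#'
#' Applies the empirical-logit transform to the six proportion statistics
#' (singleton, rare, intermediate, common, share-any, share-multi),
#' clamping each proportion to `[eps, 1 - eps]` with
#' `eps = 0.5 / (number of items defining it)` — the number of types for
#' the spectrum proportions, the number of individual pairs for the
#' sharing proportions — so boundary values stay finite. All other
#' statistics pass through unchanged; `NA` sentinels are preserved.
#'
#' @param sv A [summary_vector()] (attributes supply the denominators),
#'   or a plain named vector with `n_individuals` given explicitly.
#' @param n_individuals Number of individuals in the sample; defaults to
#'   the attribute stored by [summary_vector()].
#' @return Named numeric vector of length 13.
#' @export
transform_vector <- function(sv, n_individuals = attr(sv, "n_individuals")) {
  stopifnot(!is.null(n_individuals))
  out <- as.numeric(sv)
  names(out) <- names(sv)
  ns <- sv[["n_types"]]
  n_pairs <- n_individuals * (n_individuals - 1) / 2
  denoms <- c(prop_singleton = ns, prop_rare = ns, prop_intermediate = ns,
              prop_common = ns, share_any = n_pairs, share_multi = n_pairs)
  for (nm in logit_stats) {
    eps <- 0.5 / denoms[[nm]]
    p <- min(max(out[[nm]], eps), 1 - eps)
    out[[nm]] <- qlogis(p)
  }
  out
}

#' Summary-statistic table for a multi-population sample
#'
#' One row per population: the 13 raw statistics followed by the 13
#' transformed ones (suffix `_t`).
#'
#' @param sample A `repertoire_sample` possibly spanning populations.
#' @return Data frame with a `population` column and 26 statistic columns.
#' @export
summary_table <- function(sample) {
  per_pop <- split_populations(sample)
  rows <- lapply(names(per_pop), function(p) {
    sv <- summary_vector(per_pop[[p]])
    tv <- transform_vector(sv)
    cbind(data.frame(population = p),
          as.data.frame(as.list(setNames(as.numeric(sv), names(sv)))),
          as.data.frame(as.list(setNames(tv, paste0(names(tv), "_t")))))
  })
  do.call(rbind, rows)
}
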