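#' Tradition ages of surviving syllable types
#'
#' For every syllable type present at the end of a simulation, the age is
#' the number of years since the type was last (re)introduced into the
#' population: `age = years - innovation_year`, so a type innovated in
#' the final year has age 0 and a type present continuously since
#' initialisation has age equal to the run length (e.g. 5000 in a
#' 5000-year run). A type that went extinct and was later re-innovated
#' counts from the most recent innovation.
#'
#' @param res A `song_simresult` (or a `song_population`).
#' @return An age table: data frame with `type`, `frequency` (number of
#'   singers at the end) and `age` in years.
#' @export
type_ages <- function(res) {
  pop <- if (inherits(res, "song_simresult")) res$population else res
  counts <- tabulate(unlist(pop$repertoires), nbins = length(pop$M))
  surv <- which(counts > 0)
  data.frame(type = surv,
             frequency = counts[surv],
             age = pop$year - pop$type_birth[surv])
}

#' Longevity summaries over a collection of age tables
#'
#' Given age tables from simulations at posterior parameter values (one
#' table per simulated population), computes per table the age of the
#' oldest surviving type, the proportion of types older than `threshold`
#' years, and the token-weighted proportion (each type weighted by its
#' number of singers) older than `threshold`; the three statistics are
#' then averaged across tables, matching a per-population-then-average
#' reading of multi-population longevity summaries.
#'
#' @param tables A single age table or a list of them (from
#'   [type_ages()]).
#' @param threshold Age threshold in years (default 500).
#' @return List with `mean_oldest`, `prop_types_older`,
#'   `prop_tokens_older` and `threshold`.
#' @export
age_stats <- function(tables, threshold = 500) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0) stop("no age tables supplied")
  per <- vapply(tables, function(tab) {
    stopifnot(all(c("frequency", "age") %in% names(tab)),
              nrow(tab) >= 1)
    c(oldest = max(tab$age),
      types = mean(tab$age > threshold),
      tokens = sum(tab$frequency[tab$age > threshold]) /
               sum(tab$frequency))
  }, numeric(3))
  list(mean_oldest = mean(per["oldest", ]),
       prop_types_older = mean(per["types", ]),
       prop_tokens_older = mean(per["tokens", ]),
       threshold = threshold)
}

#' Re-simulate at posterior particle values and summarise tradition ages
#'
#' Draws `n` particles from a final-round particle set (by weight),
#' re-runs the simulator at each with fresh seeds, and pools the
#' resulting age tables into [age_stats()].
#'
#' @param ps A `particle_set` or `pmc_fit`.
#' @param base_params Baseline [sim_params()] (notably `years`).
#' @param n Number of posterior simulations.
#' @param threshold Age threshold in years.
#' @param seed Optional integer seed.
#' @return List with the pooled `stats` ([age_stats()]) and the list of
#'   age `tables`.
#' @export
posterior_ages <- function(ps, base_params, n = 100, threshold = 500,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(ps, "pmc_fit")) ps <- ps$rounds[[length(ps$rounds)]]
  w <- ps$weight
  pars <- setdiff(names(ps), c("weight", "distance"))
  idx <- sample.int(nrow(ps), n, replace = TRUE, prob = w)
  tables <- lapply(idx, function(i) {
    params <- update_params(base_params, as.list(ps[i, pars]))
    type_ages(run_simulation(params))
  })
  list(stats = age_stats(tables, threshold), tables = tables)
}
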