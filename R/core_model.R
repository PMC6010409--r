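#' Initialise a population
#'
#' Allocates each of `N_p` individuals a repertoire size drawn from the
#' configured repertoire-size distribution and fills it with distinct
#' syllable types drawn uniformly from `{1..N_s}`. Content attractiveness
#' `M` is set once per type (Bernoulli(`p_att`) between 1 and 0.05) and
#' demonstrator attractiveness per individual as `t = exp(N(0, v))`.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed (calls [set.seed()]).
#' @return A `song_population`: list with elements `repertoires` (list of
#'   integer vectors), `t_m`, `birth_ind`, `M`, `type_birth`, `year`.
#' @export
init_population <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample.int(length(params$rep_probs), params$N_p, replace = TRUE,
                      prob = params$rep_probs)
  reps <- lapply(sizes, function(r) sample.int(params$N_s, r))
  M <- ifelse(runif(params$N_s) < params$p_att, 1, 0.05)
  t_m <- exp(rnorm(params$N_p, 0, params$v))
  structure(list(repertoires = reps,
                 t_m = t_m,
                 birth_ind = integer(params$N_p),
                 M = M,
                 type_birth = integer(params$N_s),
                 year = 0L),
            class = "song_population")
}

#' @export
print.song_population <- function(x, ...) {
  sizes <- lengths(x$repertoires)
  present <- length(unique(unlist(x$repertoires)))
  cat("Song population: ", length(x$repertoires), " individuals, year ",
      x$year, "\n", sep = "")
  cat("  ", present, " syllable types in use (alphabet ", length(x$M),
      "); repertoire sizes ", min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Advance a population by one or more years
#'
#' Each year, every adult dies independently with probability
#' `params$mortality`; deaths are drawn simultaneously, and each dead slot
#' is refilled by a juvenile that learns its repertoire from the surviving
#' adults under the configured learning rule (model 1 or 2). Juveniles of
#' the same year are never demonstrators, and a type whose population
#' count rises from zero through mutation has its innovation year reset.
#'
#' @param pop A `song_population`.
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed.
#' @param nyears Number of years to advance (default 1).
#' @return The advanced `song_population`.
#' @export
advance_year <- function(pop, params, seed = NULL, nyears = 1) {
  stopifnot(inherits(pop, "song_population"), inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  if (nyears == 0) return(pop)
  st <- .cpp_advance(pop$repertoires, pop$t_m, pop$birth_ind, pop$M,
                     pop$type_birth, pop$year, params$model, params$mu,
                     params$v, params$alpha, as.integer(round(params$N_T)),
                     as.integer(round(params$N_T1)),
                     as.integer(round(params$N_T2)), params$W,
                     params$mortality, params$rep_probs,
                     as.integer(nyears))
  structure(list(repertoires = st$repertoires, t_m = st$t_m,
                 birth_ind = st$birth_ind, M = pop$M,
                 type_birth = st$type_birth, year = st$year),
            class = "song_population")
}

#' Run a full simulation
#'
#' Initialises a population and advances it `params$years` years, keeping
#' track of the year each syllable type was last (re)introduced, so that
#' tradition ages can be read off the final state. A type present
#' continuously since initialisation has age equal to the run length.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed.
#' @return A `song_simresult`: list with the final `population`, the
#'   per-type `ages` table (see [type_ages()]), and `params`.
#' @export
run_simulation <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- init_population(params)
  if (params$years > 0) pop <- advance_year(pop, params,
                                            nyears = params$years)
  res <- structure(list(population = pop, params = params),
                   class = "song_simresult")
  res$ages <- type_ages(res)
  res
}

#' @export
print.song_simresult <- function(x, ...) {
  cat("Song simulation result after ", x$population$year, " years\n",
      sep = "")
  cat("  ", nrow(x$ages), " surviving syllable types; oldest age ",
      if (nrow(x$ages)) max(x$ages$age) else NA, " years\n", sep = "")
  invisible(x)
}

#' Sample observable repertoires from a simulated population
#'
#' Draws `n` individuals uniformly without replacement and returns them in
#' the observable format shared by empirical and simulated data: one row
#' per individual with a population label, planar coordinates (synthesised
#' uniformly in a square of side `extent` around `centre`, or `NA` if
#' `extent` is `NULL`) and the set of syllable-type labels.
#'
#' @param pop A `song_population`.
#' @param n Number of individuals to sample (`n <= N_p`).
#' @param seed Optional integer seed.
#' @param population Population label for the sampled rows.
#' @param extent Side (metres) of the square within which coordinates are
#'   synthesised; `NULL` leaves coordinates `NA`.
#' @param centre Length-2 centre of the square.
#' @return A `repertoire_sample` data frame with columns `individual_id`,
#'   `population`, `x_m`, `y_m` and the list-column `syllables`.
#' @export
sample_individuals <- function(pop, n, seed = NULL, population = "pop1",
                               extent = NULL, centre = c(0, 0)) {
  stopifnot(inherits(pop, "song_population"))
  if (!is.null(seed)) set.seed(seed)
  N_p <- length(pop$repertoires)
  if (n > N_p) stop("cannot sample ", n, " individuals from a population of ",
                    N_p)
  idx <- sample.int(N_p, n)
  if (is.null(extent)) {
    x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  } else {
    x <- centre[1] + runif(n, -extent / 2, extent / 2)
    y <- centre[2] + runif(n, -extent / 2, extent / 2)
  }
  repertoire_sample(
    individual_id = paste0(population, "_", idx),
    population = rep(population, n),
    x_m = x, y_m = y,
    syllables = lapply(pop$repertoires[idx], as.character))
}

#' Construct a repertoire sample
#'
#' The observable unit shared by empirical and simulated data: a data
#' frame with one row per individual and a list-column of syllable-type
#' labels.
#'
#' @param individual_id,population Character vectors.
#' @param x_m,y_m Numeric planar coordinates in metres (may be `NA`).
#' @param syllables List of character vectors of distinct type labels.
#' @return A data frame of class `repertoire_sample`.
#' @export
repertoire_sample <- function(individual_id, population, x_m, y_m,
                              syllables) {
  stopifnot(length(individual_id) == length(syllables),
            length(population) == length(syllables))
  if (any(lengths(syllables) == 0)) stop("every repertoire must be nonempty")
  if (any(vapply(syllables, anyDuplicated, 0L) > 0))
    stop("repertoires must not contain duplicate types")
  out <- data.frame(individual_id = as.character(individual_id),
                    population = as.character(population),
                    x_m = as.numeric(x_m), y_m = as.numeric(y_m),
                    stringsAsFactors = FALSE)
  out$syllables <- lapply(syllables, as.character)
  class(out) <- c("repertoire_sample", "data.frame")
  out
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat("Repertoire sample: ", nrow(x), " individuals, ",
      length(unique(x$population)), " population(s), ",
      length(unique(unlist(x$syllables))), " syllable types\n", sep = "")
  invisible(x)
}

#' Split a repertoire sample by population
#'
#' @param sample A `repertoire_sample`.
#' @return Named list of single-population `repertoire_sample` objects.
#' @export
split_populations <- function(sample, ...) {
  pops <- unique(sample$population)
  setNames(lapply(pops, function(p) {
    out <- sample[sample$population == p, , drop = FALSE]
    class(out) <- c("repertoire_sample", "data.frame")
    out
  }), pops)
}
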