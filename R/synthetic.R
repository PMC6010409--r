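#' Study design for the synthetic multi-population generator
#'
#' Describes the sampling design the generator emulates: by default six
#' populations with the sample sizes of the field survey the models were
#' built for (208, 71, 70, 74, 91, 101 males), each sampled from an
#' independently simulated population, with individual coordinates drawn
#' uniformly inside a small square per population and population centres
#' placed far apart, so that within-population sharing is spatially
#' unstructured while between-population sharing arises only through
#' chance re-invention.
#'
#' @param labels Population labels.
#' @param n Per-population sample sizes (each `<=` `true_params$N_p`).
#' @param true_params The ground-truth [sim_params()]. The default truth
#'   for recovery experiments is a conformist-bias model 1 with
#'   `alpha = 1.3`, `mu = 0.02`, `p_att = 0.6`, `v = 1`, `N_T = 5`, at a
#'   reduced scale (`N_p = 500`, 1000 years) that reaches a stationary
#'   frequency spectrum at desk-scale runtime.
#' @param extent Side of each population's square, metres.
#' @param separation Distance between population centres, metres.
#' @return A `study_design` list.
#' @export
study_design <- function(labels = c("Conneaut", "Montezuma", "Adirondacks",
                                    "Waterloo", "Horicon", "HudsonValley"),
                         n = c(208, 71, 70, 74, 91, 101),
                         true_params = sim_params(model = 1, alpha = 1.3,
                                                  mu = 0.02, p_att = 0.6,
                                                  v = 1, N_T = 5,
                                                  N_p = 500, N_s = 200,
                                                  years = 1000),
                         extent = 2000, separation = 1e5) {
  stopifnot(length(labels) == length(n), all(n >= 2),
            all(n <= true_params$N_p), separation > 10 * extent)
  structure(list(labels = labels, n = n, true_params = true_params,
                 extent = extent, separation = separation),
            class = "study_design")
}

#' Generate a synthetic multi-population repertoire study
#'
#' Runs one independent simulation per population at the design's true
#' parameters, samples the design's number of individuals from each,
#' synthesises coordinates, and returns the combined sample together
#' with a ground-truth manifest (true parameters and all seeds). Syllable
#' type labels are prefixed per population, reflecting independent
#' cultural evolution: no type is shared between populations.
#'
#' @param design A [study_design()].
#' @param seed Integer seed; per-population seeds are derived from it.
#' @return List with `sample` (a multi-population `repertoire_sample`)
#'   and `manifest` (true parameters, seeds, design).
#' @export
generate_study <- function(design = study_design(), seed = 1) {
  stopifnot(inherits(design, "study_design"))
  npop <- length(design$labels)
  seeds <- seed * 1000L + seq_len(npop)
  parts <- vector("list", npop)
  for (i in seq_len(npop)) {
    res <- run_simulation(design$true_params, seed = seeds[i])
    centre <- c((i - 1) %% 3, (i - 1) %/% 3) * design$separation
    smp <- sample_individuals(res$population, design$n[i],
                              population = design$labels[i],
                              extent = design$extent, centre = centre)
    smp$syllables <- lapply(smp$syllables, function(s)
      paste0(design$labels[i], ".", s))
    parts[[i]] <- smp
  }
  sample <- do.call(rbind, parts)
  class(sample) <- c("repertoire_sample", "data.frame")
  manifest <- list(true_params = unclass(design$true_params),
                   labels = design$labels, n = design$n,
                   extent = design$extent, separation = design$separation,
                   seed = seed, population_seeds = seeds)
  list(sample = sample, manifest = manifest)
}

#' Bundled deterministic fixtures
#'
#' Tiny hand-constructed or seeded datasets for unit tests and examples:
#' \describe{
#'   \item{`toy_single_type`}{5 individuals all singing type `A`.}
#'   \item{`toy_half_half`}{4 individuals, two singing `A`, two `B`.}
#'   \item{`toy_jaccard`}{two individuals `{A,B,C}` and `{B,C,D}`.}
#'   \item{`mini_study`}{3 populations x 30 individuals generated from a
#'     reduced conformist design with fixed seeds.}
#' }
#'
#' @param name Fixture name.
#' @return A `repertoire_sample` (for `mini_study`, the full
#'   [generate_study()] list).
#' @export
make_fixture <- function(name) {
  switch(name,
    toy_single_type = repertoire_sample(
      individual_id = paste0("i", 1:5), population = rep("toy", 5),
      x_m = seq(0, 40, 10), y_m = rep(0, 5),
      syllables = rep(list("A"), 5)),
    toy_half_half = repertoire_sample(
      individual_id = paste0("i", 1:4), population = rep("toy", 4),
      x_m = c(0, 10, 20, 30), y_m = rep(0, 4),
      syllables = list("A", "A", "B", "B")),
    toy_jaccard = repertoire_sample(
      individual_id = c("i1", "i2"), population = rep("toy", 2),
      x_m = c(0, 10), y_m = c(0, 0),
      syllables = list(c("A", "B", "C"), c("B", "C", "D"))),
    mini_study = generate_study(
      study_design(labels = paste0("pop", 1:3), n = rep(30, 3),
                   true_params = sim_params(model = 1, alpha = 1.3,
                                            mu = 0.02, p_att = 0.6, v = 1,
                                            N_T = 5, N_p = 120, N_s = 200,
                                            years = 200)),
      seed = 99),
    stop("unknown fixture: ", name))
}
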