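---
title: "Modelling the cultural evolution of song syllable repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cultural evolution of song syllable repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultsong)
```

## The question and the modelling frame

Oscine songbirds learn their songs socially, and in species such as the
swamp sparrow the unit of transmission is the *syllable type*: a discrete
cluster of acoustically similar syllables that different males can share
through vocal learning. A population of singers then carries a
frequency distribution of syllable types, shaped year after year by who
learns what from whom. `cultsong` implements an individual-based model
of this process, a battery of population summary statistics, and a
likelihood-free (ABC) inference layer that fits the model to
multi-population repertoire surveys. The scientific target is the set of
individual learning parameters — imitation error rate, conformist bias,
demonstrator bias, content bias — and their population-level
consequence: how long syllable-type traditions persist.

## The transmission model

A population holds a constant number `N_p` of individuals. Each year
every individual dies independently with probability `mortality`
(default 0.4), and every vacancy is filled by a juvenile that learns a
repertoire of `r_m` distinct syllable types from the surviving adults;
`r_m` is drawn from a configurable repertoire-size distribution over
1–6 with mode 3 (`default_rep_probs()`), emulating the field pattern of
about three types per male. The possible types are the integers
`1..N_s`. Three biases act on learning:

* **Content bias.** Each type carries a fixed attractiveness
  `M ∈ {1, 0.05}`; a proportion `p_att` of types is attractive. The
  smaller `p_att`, the more novel types are penalised.
* **Demonstrator bias.** Each individual carries an attractiveness
  score `t = exp(N(0, v))`. We treat `v` as the *standard deviation* of
  the underlying normal: it is used throughout as a scale knob with a
  prior spanning 0.01–6, and a standard deviation reads most naturally
  on that range. `v = 0` switches the bias off.
* **Conformist bias** (model 1). A juvenile memorises the repertoires
  of `N_T` adults sampled uniformly without replacement, recording for
  every memorised type its frequency `F` among the demonstrators and
  the mean score `T` of the demonstrators singing it. Types are then
  drawn without replacement with probability proportional to
  `F^alpha * M * T`. `alpha > 1` favours common types beyond their
  frequency; `alpha < 1` is anti-conformist.

Each drawn syllable is replaced, with probability `mu`, by a uniformly
drawn *different* type not already in the repertoire — "mutation" covers
innovation, copying error and immigration alike. If the memory holds
fewer distinct types than `r_m`, the learner keeps the whole memory and
each unfilled slot innovates with probability `mu` (so nothing new can
enter when `mu = 0`).

**Model 2 — overproduction and selective attrition.** Here conformity is
emergent rather than explicit. Phase 1 memorises the union of `N_T1`
adult repertoires (truncated to at most 8 types, matching the largest
plastic-song repertoires observed in young sparrows). Phase 2 samples a
further `N_T2` adults — types first heard now cannot be memorised — and
counts, for each memorised type, the number of phase-2 repertoires
containing it (`G`). The repertoire then shrinks one type at a time:
types are selected by weighted sampling without replacement with
weights `(W + G) * M * T`, and the single type left *unselected* is
removed (the last item of a Plackett–Luce ordering). Common types are
rarely last, which is exactly a conformist bias. `W` weighs the
phase-1 evidence against the phase-2 tallies. The published description
of this model is silent about mutation; we apply the same per-syllable
mutation with probability `mu` to the final retained repertoire,
because without innovation the model admits no non-trivial stationary
frequency spectrum. `G` counts repertoires containing a type (not
tokens), the closest reading of "how often the type is heard".

Several orderings are underdetermined by the verbal model description
and fixed here once: deaths are drawn simultaneously at the start of a
year; juveniles learn only from adults that survived that year (same-
year juveniles are never demonstrators); a learner never samples
itself; the two model-2 samples are disjoint; mutation applies per draw
before set-deduplication. A type's innovation year is reset only when
its population count rises from zero, so a re-invented *extant* type
keeps its age, while a truly extinct one restarts at zero.

## Tradition ages

The simulator records the year each type was last introduced. At the
end of a run, a surviving type's age is `years - innovation_year`: a
type present since initialisation in a 5000-year run has age 5000, one
innovated in the final year has age 0. `age_stats()` reports, per
population and then averaged, the age of the oldest surviving type and
the proportions of types and of syllable tokens (types weighted by
their number of singers) older than a threshold, 500 years by default.
Pooling is per-population-first because the quantities of interest are
population-level summaries.

## Summary statistics

`summary_vector()` computes 13 statistics of a single-population sample
of repertoires: four spectrum proportions (types sung by exactly one
individual; by at most four; by more than one but at most `c`; by more
than `c`, where `c` is 5% of the number of types, rounded up and at
least 1), the number of types, the count of singers of the commonest
type, the diversity index `H = Σ f_i log2(f_i)` over token proportions
(kept with this sign — it is the negative Shannon entropy; any monotone
recoding is equivalent for ABC, and we keep the literal form), the
power-law exponent `alpha_p = 1 + ns (Σ ln 2f_i)^-1`, two goodness-of-
fit statistics against the fitted power law, the proportions of pairs
of individuals sharing at least one and more than one type, and a
weighted mean inter-type correlation.

The power-law comparison needs an explicit construction, which the
exponent formula alone does not pin down. Because each individual sings
each of its types exactly once, token proportions are proportional to
singer counts, so we fit the discrete law `p(k) ∝ k^-alpha_p` on the
singer-count support `1..n` and compare cumulative distributions of
singer counts: the Kolmogorov–Smirnov statistic is their largest
absolute gap, and the second fit statistic is the gap at a singer count
of exactly 2 — the low-frequency end where spectra are most
discriminating. What matters for inference is only that the identical
construction is applied to empirical and simulated samples.

Degenerate samples (a single type; a vanishing power-law denominator;
no valid type pair) return `NA` sentinels. The ABC layer maps sentinels
to infinite distance, so such parameter draws are simply rejected.

Before inference the six proportions are logit-transformed with an
empirical clamp to `[eps, 1-eps]`, `eps = 0.5 / (number of items
defining the proportion)` — the type count for spectrum proportions,
the pair count for sharing proportions.

## Dimension reduction and inference

The 13 transformed statistics are redundant; following standard
practice for ABC with many statistics, they are projected by partial
least squares onto a small number of components fitted on a
prior-predictive simulation batch (parameters as responses, statistics
as predictors). Both blocks are centred and scaled to unit variance,
and parameters enter on their prior working scale (log for log-uniform
priors) so the responses are symmetric. The NIPALS implementation
exports centring, scaling and the rotation matrix as plain JSON
(`write_projection()`), so empirical and simulated data are projected
by the same affine map in any process. `select_components()` picks the
component count by leave-one-out cross-validation with a 5% parsimony
rule; the package default is 6 components.

Priors (`prior_spec()`): log-uniform `N_p` {400, 3000}, `N_s`
{180, 500}, `N_T` {2.5, 50}, `v` {0.01, 6}, `alpha` {0.25, 4}, `mu`
{0.0001, 0.3}, `N_T1` {2.5, 15}, `N_T2` {1.5, 50}, `W` {0.01, 20};
uniform `p_att` {0.01, 1}. Continuous draws of demonstrator counts are
rounded at use. Any parameter can be pinned via `fixed`.

`pmc_fit()` implements population Monte Carlo ABC. One parameter vector
is drawn per particle and applied to independent simulations of every
surveyed population (population size drawn once per particle); the
distance is the Euclidean norm between the mean simulated and mean
observed PLS score vectors across populations. Round 1 is rejection
sampling from the prior at the first tolerance; later rounds resample
the previous particles by weight and perturb them with a multivariate
Gaussian kernel on the working scale whose covariance is twice the
weighted empirical covariance of the previous round, with the matching
importance-weight update (the priors are flat on the working scales,
so no density correction is needed beyond the kernel mixture).
Doubling the empirical spread is the standard PMC choice; using the
full covariance rather than per-component variances matters here
because the fitted parameters are strongly correlated — for example a
stronger conformist bias trades off against a higher innovation rate —
and proposals that ignore the ridge are mostly wasted simulations.
Proposals outside the prior support are rejected outright.

A published tolerance series is tied to the scaling of the projection
it was computed under and is meaningless under a different one, so
tolerances must be recalibrated per fit. Two forms are supported.
`recalibrate_schedule()` fixes the whole series in advance from
quantiles of the prior-predictive distances (default 0.5, 0.3, 0.2,
0.12 — a geometric decay mirroring a long published series compressed
into four rounds). The form the packaged experiments use is adaptive:
only the first tolerance comes from the prior-predictive median, and
each later round's tolerance is the `adapt_q` (default 0.35) quantile
of the previous round's *accepted* distances. The adaptive series
tracks how fast the particle cloud actually concentrates — prior-
quantile series systematically overestimate how small a tolerance a
fixed budget can afford early on, and underestimate it late — and in
our experiments reaches roughly the tolerance region where simulations
at the true parameters themselves live, which is what makes the
posterior sharp enough to be informative.

`cross_validate()` checks the design the way the original analysis
did: simulate pseudo-observations directly from the prior and estimate
each one from the rest by rejection ABC, reporting per-parameter mean
squared error on the working scale relative to the prior variance —
near 1 means the statistics carry no information about the parameter.

## The synthetic study generator

`generate_study()` stands in for the field data set: by default six
populations with sample sizes 208, 71, 70, 74, 91 and 101, each an
independent simulation at the true parameters, sampled at the matched
size. Summary statistics are computed on samples matched to the
empirical sample sizes, not on whole simulated populations, because the
sharing statistics are sample-size dependent. Coordinates are uniform
within a small square per population, with population centres placed
far apart; they carry no causal role within populations — consistent
with surveys finding no within-population spatial structure in sharing
— and between-population divergence arises purely from independent
evolution, not from explicit isolation by distance. Type labels are
prefixed per population, so cross-population sharing is exactly zero in
the generator; the real data differ here (neighbouring populations do
share types at low rates), which the generator deliberately does not
emulate. Passing recovery tests on synthetic data therefore shows the
inference machinery is self-consistent, not that the field data meet
the model's assumptions.

The default truth for recovery experiments is a conformist model 1 with
`alpha = 1.3`, `mu = 0.02`, `p_att = 0.6`, `v = 1`, `N_T = 5`, at
`N_p = 500` and 1000 years. A 1000-year run at these rates is long past
the transient from the random initial condition, and a population of
500 is within the survey-based prior range; both choices keep a full
PMC fit tractable on one core. In the bundled recovery experiment we
estimate `mu`, `v`, `alpha` and `p_att` and pin `N_T` at its true value
of 5 — the same choice the original validation design makes, because
`alpha` and `N_T` are strongly confounded (more demonstrators mean
better frequency estimates and a weaker bias fits equally well) — and
pin `N_p` and `N_s` at the generator truth. The experiment uses 3
populations of 60 sampled individuals, 200 prior-predictive
simulations for the projection, 200 particles and a 4-round adaptive
schedule starting at the prior-predictive median distance, with a
locally scaled kernel (`kernel_scale = 1`) and four averaged
subsamples per simulated population (`n_sub = 4`). The last adaptive
quantile is slightly looser than the earlier ones (0.42 versus 0.35):
the final round dominates the simulation bill, and the looser step
trades a little posterior sharpness for roughly a quarter of the whole
experiment's runtime. At these settings the experiment runs in well
under half an hour on one core.

## Dataset-level analyses

The empirical module mirrors the descriptive analyses that accompany
such surveys. `jaccard()` and `sharing_vs_distance()` quantify
repertoire sharing against geographic distance, within and between
populations. `mantel_test()` wraps `vegan::mantel` (one-sided
permutation test, optional strata so that permutations never cross
population boundaries). `upgma()` is average-linkage clustering of a
syllable dissimilarity matrix (the matrix itself — e.g. from dynamic
time warping of spectrograms — is an input; its computation is out of
scope). `gsi_profile()` cuts the dendrogram at each candidate number of
clusters and scores it with the global silhouette index. The index
reference is not explicit about aggregation, so the default is the mean
over clusters of the mean per-item silhouette width, with the plain
item mean as an option; singleton clusters score 0, the common
convention. The peak is the global argmax over the candidate range, and
local maxima are reported as well. Note a property of the
cluster-mean variant worth knowing: on unstructured dissimilarities it
drifts upward at large cluster counts, because tiny tight clusters
dominate the average — compare both variants when the peak lands near
the end of the range. `nmi()` scores agreement between a clustering and
reference labels, normalised by the arithmetic mean of the label
entropies (maximum and geometric-mean variants available).

## Numerical choices and edge cases

* Weighted quantiles use the inverse-CDF (step) convention, so a
  dominant particle is itself the median.
* Weighted draws with all-zero weights fall back to uniform; the
  Plackett–Luce removal enumerates nothing and simply simulates the
  successive draw.
* Mutation redraws until the target differs from the selected type and
  from the repertoire (with a deterministic fallback scan when the
  alphabet is nearly exhausted).
* If fewer adults survive than a demonstrator sample requires, the
  sample is clamped to the survivor pool; a year in which everyone dies
  is an error.
* `run_simulation(years = 0)` returns the initial state with all ages
  zero.
* PMC aborts with a diagnostic when a round's acceptance rate falls
  below a configurable floor instead of spinning forever.

## Problem sizes used by the test-suite experiments

The packaged experiments are sized for a single core: the neutral-drift
equivalence check runs 500 replicates of a 30-individual, 25-year
population against an independently coded oracle; the recovery
experiment uses the design above (roughly 10–15 minutes); the
cross-validation check uses 1000 prior draws of single 500-individual,
400-year populations with `N_T` and `N_p` pinned. These sizes are the
package's own desk-scale defaults; all of them are configurable
upward.

## Limitations

The demographic core has no overlapping learning periods, no spatially
structured demonstrator choice, no migration distinct from mutation,
and no large-scale demographic or ecological disturbance; tradition-age
estimates are therefore "under stable conditions" statements. Model
comparison between the explicit-bias and attrition rules is out of
scope (both can be fitted; Bayes-factor machinery for ABC is
notoriously fragile). The audio pipeline upstream of a dissimilarity
matrix — spectrogram measurement and dynamic time warping — is not
reimplemented.
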