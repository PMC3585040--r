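---
title: "Coalescent inference of stem-cell division mode in intestinal crypts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent inference of stem-cell division mode in intestinal crypts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cryptcoal)
```

## The model

An intestinal crypt is modelled as two coupled cell populations: a stem
niche of `N1` cells (deme 1) and a transit-amplifying pool of `N2` cells
(deme 2). Each generation every stem cell divides in one of three ways:

* **type I** (symmetric renewal): two stem daughters, fraction `alpha`;
* **type II** (symmetric differentiation): two transit daughters,
  fraction `alpha`;
* **type III** (asymmetric): one of each, fraction `beta`.

A constant stem pool forces the two symmetric fractions to be equal, so
`2 alpha + beta = 1` and the model has a single free parameter: the
asymmetric fraction `beta`. `beta = 1` is strict *cell asymmetry* (every
division balances itself); `beta = 0` is pure *population asymmetry*
(homeostasis only holds on average, and stem lineages drift to fixation —
the neutral-drift picture of adult crypts). The differentiated daughters
(`N1` per generation) migrate into deme 2, where a fraction
`gamma = (N2 - N1)/(2 N2)` of cells divides once and the remainder is
extruded towards the villus, keeping both deme sizes exactly constant.

Looking backward in time, two random stem lineages coalesce in one
generation with probability `2 alpha / (N1 - 1)`: asymmetric divisions
slow lineage turnover, so larger `beta` means older genealogies. A sample
of cells (whose stem/transit split is hypergeometric) follows a two-deme
coalescent described by a Markov chain on the ancestral lineage counts
`(m, n)`; its one-generation transitions combine coalescence events in
either deme with (backward) migration of transit lineages into the stem
deme.

Cell genealogies are latent. They are connected to data through
single-cell microsatellite genotypes: each marker mutates as a two-step
random walk on repeat length (`+/-1` and, at 1/7 the rate, `+/-2`;
total rate `mu = 0.01` per site per generation in the
mismatch-repair-deficient background). The likelihood of a crypt's
genotype matrix is

    Pr(D | beta) = E_G [ prod_markers Pr(D_marker | G) ],

estimated by Monte-Carlo over `k` sampled genealogies, with each
`Pr(D_marker | G)` computed by Felsenstein pruning over the truncated
repeat-offset space. Markers share one genealogy per crypt (a clonal cell
sample has no recombination), so the product over markers is taken
*inside* the expectation. Maximum likelihood over a grid of `beta` values,
marker-resampling bootstrap and a chi-square likelihood-ratio test
(`H0: beta_young = beta_old`, 1 df) complete the inference stack.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `N1`, `N2` | 15, 185 | cells | observed colon-crypt compartment sizes |
| `gamma` | (N2-N1)/(2 N2) | — | exact deme-2 turnover identity |
| `division_hours` | 22 | h | stem-cell cycle length |
| `morphogenesis_start_day` | 7 | d | crypt formation begins postnatally |
| `morphogenesis_generations` | 8 | gen | founder expansion + asymmetric fill at the default sizes |
| `mu` | 0.01 | /site/gen | measured microsatellite rate in Mlh1-deficient mice |
| `step2_ratio` | 1/7 | — | relative frequency of two-repeat steps |
| `window` | 20 | repeats | truncation half-width of the offset space |
| `k` | 20000 | genealogies | production Monte-Carlo size (tests use far fewer) |
| beta grid | 0 to 1 by 0.04 | — | resolution supported by the Monte-Carlo noise |
| bootstrap `B` | 100 | replicates | resampling markers, never cells |
| profile drop | 1.92 | log-units | `0.5 * qchisq(0.95, 1)` |

The clock maps ages to generations as
`round((day - 7) * 24 / 22)`: day 52 is ~49 generations (non-stationary:
likelihoods use forward-simulated genealogies, with the generation number
drawn per genealogy from a truncated normal, mean 41 homeostatic
generations, sd 5, bounds mean ± 10) and day 340 is ~363 generations
(stationary: likelihoods sample the backward chain directly).

## Integer division-type counts

Holding the stem deme at exactly `N1` cells forces the type I and type II
counts to be equal each generation, which constrains the type III count to
the parity of `N1`. The simulators draw `nIII ~ Binomial(N1, beta)` and,
when the parity is wrong, move it by one in a fair-coin direction. Away
from the boundaries this is unbiased. At `beta = 0` with odd `N1 = 15`,
however, *at least one asymmetric division per generation is forced by
integer arithmetic*, so the realized per-generation stem coalescence
probability is `14/210 = 1/15` rather than the continuum value
`1/14 = 2 alpha/(N1 - 1)`. The backward chain therefore uses *effective*
rates derived from the exact count law (`division_type_law()`), which is
what makes the first-step analytics, the backward chain simulator and the
forward simulator agree to Monte-Carlo precision at every `beta`
(including 0). `expected_tmrca(law = "nominal")` reproduces the idealized
continuum analysis instead (14 generations for two stem lineages at
`beta = 0`). For even `N1` the two coincide exactly.

## The backward chain and its truncation

The transition table enumerates predecessor states reachable by at most
two backward events per generation (coalescence in either deme, migration,
a migrant pair landing on one type-II parent, a stem lineage absorbing a
migrant through a type-III parent). Rows are built by second-order
inclusion-exclusion with exact joint event probabilities; the leading mass
of three-or-more-event combinations is subtracted from the no-event entry
and reported as `neglected`, never redistributed (a renormalized mode
exists for sensitivity checks). For states with `m + n <= 2` the rows are
exact; the neglected mass grows roughly like `C(n,3) (N1/N2)^3`, staying
below `1e-3` for all states with `m + n <= 3` at the default sizes but
reaching ~2e-3 at `(0, 4)`. The *genealogy sampler* does not use the
truncated table at all: it simulates the exact one-generation slot process
(parents' child slots drawn from the count law, lineages assigned to
distinct slots without replacement), i.e. the exact time reversal of the
forward simulator, so chain-versus-forward agreement is structural and the
truncation only touches the analytic expectations.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` mirrors the study design: mice at chosen ages, two
crypts each, 4–6 cells per crypt, a shared per-mouse panel of 70–90 usable
markers (the usable yield of a ~150-marker screen), genotypes simulated
down the sampled genealogy from the crypt-founder state, a per-crypt
founder offset for the mutations accrued between the zygote and the crypt
MRCA (20 prenatal days plus the pre-MRCA span; this is what separates
crypts in the UPGMA trees), missing-completely-at-random dropout (default
0.3), and the inclusion filter requiring two genotyped cells per marker.
Within-crypt analyses re-reference each marker to its modal allele, which
removes the shared founder offset and matches the pruning root fixed at
offset 0 (an option marginalizes the root uniformly instead).

Not emulated: genotyping error and allele dropout beyond MCAR missingness,
per-marker rate variation beyond the discretized beta-distribution
mixture, directional (expansion-biased) mutation, and any niche-signalling
mechanism. Passing tests therefore validate the inference machinery under
the model's own assumptions; they cannot certify robustness to artefacts
real single-cell microsatellite data may carry.

## Numerical choices

* **State space.** Offsets live on `[-window, window]`; probability mass
  stepping outside is folded into the stay probability, so matrices remain
  stochastic. Doubling the window leaves the default-scale likelihoods
  unchanged to ~1e-10, confirming the truncation is inert at <= 400
  generations.
* **Branch matrices** are integer matrix powers, cached per mutation rate
  in an external-pointer store shared across calls.
* **Underflow** is handled by per-node rescaling of the pruning partials
  with a log accumulator.
* **Common random numbers.** All draws in the genealogy samplers use
  inverse-CDF forms and fixed-size uniform blocks per generation, so runs
  with the same seed stay stream-aligned across different `beta` values;
  per-crypt sub-seeds are reused across the grid, both LRT hypotheses are
  maximized over the same fitted surfaces, and both age groups run under
  one seed protocol (identical inputs then give a statistic of exactly 0).
  The bootstrap re-weights the stored per-genealogy, per-marker
  log-likelihood tables, which is exactly a re-run of the analysis under
  the same seeds.
* **Boundary of the parameter space.** Under the stationary source
  `beta = 1` has no equilibrium genealogy distribution (stem lineages
  never coalesce); stationary fits report `-Inf` there with a warning, and
  the backward sampler guards non-termination with a generation cap.
* **Ties.** Grid maxima tie to the smaller `beta` (with a warning); UPGMA
  agglomeration ties break deterministically in label order.

## Monte-Carlo noise and the LRT

The log-likelihood estimator's noise is a data-by-genealogy interaction:
its standard error at `k = 500` genealogies on a 20-marker, 5-cell crypt
is about 1.6 log-units, and it is essentially uncorrelated between grid
points or datasets even under shared random numbers. Because the
likelihood-ratio statistic absorbs the maximum of this noise over the
grid in each age group, nominal chi-square calibration of the test
requires the per-point noise to be well below one log-unit — in practice
`k` on the order of 10^4 (the production default is 20000). The package
exposes this directly: `lrt_type1_calibration()` simulates null study
pairs end-to-end and reports the empirical rejection rate, which is
strongly inflated at `k = 500` and settles to (below-)nominal levels as
`k` grows; the conservative side at large `k` reflects the grid
discretization of the estimates. Power at study scale is exercised by the
test suite on strongly contrasted designs (`beta` 0.8 vs 0.0) and on the
reference two-age bundle, where the null is rejected for the majority of
seeds.

The same interaction limits point estimation: because a change in overall
genealogy size shifts every marker's likelihood in the same direction,
the spread of the per-genealogy log-likelihoods grows linearly with the
marker count, and the log-mean-exp estimator is increasingly dominated by
the single best sampled tree (its effective sample size collapses towards
one within a few dozen markers at desk-scale `k`). Adding markers
therefore sharpens the true likelihood surface and its Monte-Carlo noise
in the same proportion, and the precision of the grid MLE saturates
instead of improving. Overcoming this would require sampling genealogies
from a data-informed proposal with importance weights, which this package
deliberately does not do: the estimator implemented is the plain
Monte-Carlo average over prior genealogies that defines the method.

## Alternative simulators

* **Continuous time.** Events arrive at rate `n * lambda`; the affected
  cell is uniform. The stem pool floats in `[10, 20]` (mean 15). A
  trajectory-level rejection scheme is unusable here — the stem count is
  an unbiased random walk, so a long run almost surely exits a width-10
  interval and the acceptance probability of an entire multi-hundred-
  generation trajectory is effectively zero. Events that would cross a
  bound are instead rejected and redrawn (a reflected walk), with a
  per-event redraw cap that reports the acceptance rate on failure.
* **Age structure.** The transit pool is split by divisions-since-stem;
  defaults `(15, 30, 60, 80)` reproduce the base model's total turnover
  with `K = 4`. Cells at the age cap are always extruded.
* **Spatial structure.** Ordered transit demes with exact per-deme counts
  for staying, advancing and extrusion. A single deme with no advancement
  is *identical in law* to the base model. Concentrating extrusion in the
  distal deme *shortens* within-crypt coalescence here: with fixed deme
  sizes and fixed stem inflow, removing proximal extrusion forces every
  proximal offspring to advance, which eliminates proximal self-renewal
  and funnels lineages back to the stem pool faster. (The opposite
  intuition — distal extrusion prolonging residence — presumes cells can
  accumulate in proximal demes, which exact size constraints forbid.)

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale: `k` of 100–500
genealogies for fits, 300 for parameter-recovery sweeps (8 replicates per
condition across 20/80/320 markers), 200 replicate study pairs for the
type-I calibration, ~100–150 forward histories of up to 800 generations
for the three-way TMRCA comparison, and 10^5 generation-pairs for the
single-generation coalescence rate. The methods themselves impose no such
limits; production analyses should use the `k = 20000` default.

## Known limitations

* Estimates on the `[0, 1]` boundary get one-sided intervals; no boundary
  correction is applied to the chi-square reference (plain 1-df tails are
  used), which is conservative at interior truths and anti-conservative
  exactly on the boundary.
* The grid MLE cannot resolve `beta` below the grid step, and at small
  `k` the Monte-Carlo noise dominates the test calibration (see above).
* The two defensible readings of the descriptive "two-step-model
  distance" are both provided (`ml`: maximum-likelihood separation time;
  `steps`: moment-based); trees default to `ml`. The exact formula behind
  the original descriptive figures is not recoverable, so the choice is a
  package convention.
* The time-varying `beta` schedules are a simulation feature only; no
  schedule inference is attempted.
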