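---
title: "An agent-based model of mating-system evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of mating-system evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matesim)
```

## The model

`matesim` simulates the evolution of a heritable male mating strategy in a
spatially explicit population.  Females hold fixed, regularly spaced
territories on a bounded rectangular grid; the spacing (`female_radius`, in
patches) is the model's measure of female dispersion.  Males carry a binary
genotype — 1 for monogamy, 0 for polygamy — move one patch per tick, and are
re-dispersed at random at the start of every breeding season.

Within a season, every male searches for the nearest *available* female: one
who is neither pregnant nor refractory nor locked up by another male (see
below).  On reaching her patch he copulates.  Each copulation makes the
female pregnant for the rest of the season with probability
`pregnancy_chance` (default 0.05), and otherwise puts her into a refractory
period of `refractory_period_duration` ticks during which she rejects all
males.  After a copulation the two strategies diverge:

* A **monogamous** male pair-bonds with the first female he copulates with.
  With `mate_guarding = TRUE` he stays on her patch for the rest of the
  season, copulating whenever her refractory period ends; guarding is fully
  efficient, so no other male can reach her.  With `mate_guarding = FALSE`
  he wanders randomly while she is refractory and walks back to her when she
  is receptive — leaving a window in which other males can fertilise her
  (extra-pair copulation).  He never courts other females.
* A **polygamous** male simply resumes the search for the next available
  female.

At season end every pregnant female adds one progeny genotype to a trait
pool: the father's genotype perturbed by Gaussian noise,
`G1 = round(G0 + N(0, sigma))`, where the custom rounding maps any value of
at least 0.5 to 1 and everything else to 0.  With the default
`mutation_sigma = 0.35` the flip probability is
`1 - pnorm(0.5/0.35)` ≈ 0.077 per transmission, symmetric in both
directions, which keeps the population from locking into either pure state.
Males live `longevity` seasons (default 4) and are then all replaced at
once: each new male draws his genotype uniformly, with replacement, from the
accumulated pool, which is then cleared.  Both population sizes are constant
throughout, so the adult sex ratio (ASR) is set exactly by
`number_of_males` and `number_of_females`.

The outcome of a run is **percentage monogamy**: the percentage of breeding
seasons in which strictly more than half of the males carried the
monogamous genotype.

```{r quick-run}
p <- sim_params(number_of_males = 25, female_radius = 20,
                season_duration = 400, generations = 40)
res <- run_simulation(p, seed = 1)
res
```

## The availability rule

The phrase that defines availability — a female "neither pregnant nor
refractory nor with a male close to her" — admits two readings, and the
choice turns out to matter a great deal:

* **Occupied blocking** (the default): a female is blocked only while
  another male stands on her patch, and, when guarding is on, while she is
  pair-bonded to a guarding male.  Distant rivals do not block.
* **Proximity blocking** (`proximity_blocking = TRUE`): any other male
  strictly closer than the candidate blocks her; exact distance ties never
  block, so a guard at distance zero still excludes everyone.

Under proximity blocking, males that fall behind in the early-season race
are permanently locked out: every available female has somebody closer, so
they fall back to a random walk and drift in the empty space between
territories.  That strands a fraction of the monogamous males each season,
cancels the reliability advantage of guarding, and makes selection nearly
neutral even at male-biased sex ratios — the male-biased cells then hover
near 50 % instead of fixing monogamy.  Under occupied blocking, males keep
converging on unclaimed females until none remain, so whenever males
outnumber females essentially every monogamous male ends the season
guarding a female of his own, and polygamous males are left to share the
remainder.  The simple bookkeeping that follows — k paired monogamous males
father about k progeny, the other males share what is left — reproduces the
expected headline behaviour (strong monogamy at male-biased ASR with
efficient guarding, polygamy when females outnumber males or guarding is
inefficient, dispersion mattering in between), which is why occupied
blocking is the default.  The proximity variant is kept as a parameter for
sensitivity analysis.

Guarded females are explicitly unavailable to every male except their
partner while guarding is on.  This closes a corner case present in both
distance rules, where a rival could random-walk onto a guarded female's
patch and exploit a distance tie; guarding is meant to be fully efficient,
with extra-pair copulation arising only when guarding is off.

## Geometry, movement and scheduling

* The world is a bounded `cols*radius` by `rows*radius` rectangle sized by
  the female lattice (`cols = ceiling(sqrt(n))`, the most-square
  factorisation; 20 females form a 5 x 4 lattice).  A toroidal topology is
  available via `wrap = TRUE` for sensitivity checks; it is not the
  default because a bounded world keeps dispersion distances unambiguous.
* Distances are Chebyshev (8-neighbour king moves), the natural metric for
  one-patch-per-tick movement on a grid: "move one patch toward" is the
  neighbour step that minimises the remaining distance, ties broken
  uniformly at random; a blocked or idle male moves to a uniformly chosen
  in-bounds neighbour patch.
* Each tick decrements all positive refractory counters first, then steps
  every male once in a freshly shuffled order (randomised scheduling; at
  most one copulation per female per tick follows automatically, because a
  copulation immediately makes her pregnant or refractory).  A consequence
  of decrement-before-step is that an isolated guarded pair copulates
  exactly every `refractory_period_duration` ticks, so the number of
  pregnancy trials in a season of `T` ticks with first copulation at tick 1
  is `floor((T-1)/r) + 1`; the tests hold the simulator to the matching
  closed form `1 - (1-p)^N`.
* A non-guarding monogamous male whose partner is refractory (or already
  pregnant) performs an unbiased random walk; the exact wandering behaviour
  is underdetermined, so the rule is deliberately isolated in one branch of
  the stepping function where alternatives can be swapped in.
* Pair bonds form at the first copulation regardless of its outcome and
  dissolve when males are re-dispersed at the next season start.
* Mutation is applied once, at contribution time, so the pool stores
  post-mutation genotypes; drawing from the pool adds no further noise.
* If a whole generation produces no pregnancy the pool is empty; the next
  cohort then copies the dying cohort's genotype multiset (no selection
  occurred).  This degenerate case is essentially unreachable under the
  study conditions but must not crash.

## The experiment harness

`run_sweep()` crosses the swept values — 15/20/25 males (ASR 43/50/56 %
against 20 females), radii 5–35, season durations 200–800, refractory 10 or
30, guarding on or off; 336 cells — and runs seeded replicates of every
cell.  Per-run seeds are `base_seed + 1024*cell + replicate`, injective as
long as fewer than 1024 replicates are used, so results are reproducible
run by run and insensitive to execution order.  `summarize_cells()` gives
per-cell means with Student-t 95 % confidence intervals over replicates
(the interval method is our choice; the source analysis does not name one).

`fit_regression()` min-max normalises percentage monogamy and the four
predictors (male count, female radius, season duration, and an extra-pair
dummy equal to 1 when guarding is off) onto [0, 1] and fits ordinary least
squares.  The model includes an intercept even though the reference analysis
reports none, because forcing the fit through the origin would inflate R²;
`intercept = FALSE` is available for comparison.
`subset_regressions()` reproduces the companion analysis restricted to
refractory = 10, fitting the full four-predictor model and each predictor
in isolation; the companion standardised coefficients are read as belonging
to this subset model, distinct from the full-dataset estimates.
`dispersion_fit()` regresses percentage monogamy on female radius inside
one cell slice (by default 15 males, 200-tick seasons, guarding on,
refractory 10), the regime where dispersion is the dominant predictor.

```{r regression-demo}
fit_regression(make_fixture("linear_sweep_table"), normalize = FALSE)
```

## Problem sizes and what the tests show

Statistical validation uses three tiers, chosen as a compromise between
resolution and desk-scale runtimes:

* exact and closed-form oracles (lattice geometry, copulation schedules,
  mutation flip rates, OLS against the normal equations) at toy sizes;
* directional checks on a reduced sweep — 30 generations, 3 replicates —
  asserting rank-correlation signs of cell means against each driver;
* quantitative comparison with the published regression statistics on a
  full-grid sweep at 100 generations and 3 replicates (the reference
  analysis used 150 generations and 5 replicates), plus the dispersion
  slice at the reference 150 generations with 5 replicates.

Shorter runs compress percentage monogamy toward its transient (the first
~20 generations carry the signature of the 50/50 founding population), so
run length is the main driver of agreement with the published statistics;
min-max normalisation absorbs much, but not all, of the compression.

The synthetic sweeps emulate the study conditions exactly as parameterised
— they are the study, not a proxy for field data.  Passing tests show that
the implementation reproduces the model's published behaviour under its
own assumptions; they say nothing about real mating systems, where female
choice, variable female traits, resource landscapes, infanticide and
parental care — all deliberately outside this model — come into play.

## Known limitations

* Movement is discrete and king-metric; diagonal travel is as cheap as
  orthogonal, so effective dispersion differs slightly from a continuous
  arena with unit steps.
* The genetics is a single haploid locus transmitted through the father
  only; females are identical and immortal by construction.
* Percentage monogamy is a majority statistic over seasons; with few
  generations it is noticeably biased toward the founding transient.
* One season must fit in memory as simple integer vectors; the engine is
  serial by design (runs are independent, so sweeps parallelise trivially
  at the process level if needed).
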