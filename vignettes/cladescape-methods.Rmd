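---
title: "cladescape: model, measurement layer, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cladescape: model, measurement layer, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cladescape` simulates the diversification of a clade founded by a single
sexual species on a dynamic, fragmented landscape, as an exact
continuous-time (Gillespie) stochastic process at the level of individual
organisms. The package also provides the measurement layer that turns the raw
trajectory into macroevolutionary quantities: species delimitation under the
biological species concept, lineage tracking, phylogenies of extant and
extinct species, diversity-dependent speciation/extinction rate estimation,
stage detection, and macroecological summaries.

### Landscape

The landscape is an `n x n` grid of habitat sites (default `3 x 3`). Each
site has a two-dimensional environmental optimum `z* = (x1*, x2*)`; in the
gradient (baseline) mode both coordinates increase by `delta_x` (default 1
trait unit) between rook-adjacent sites and the central site sits at
`(0, 0)`. A randomized mode draws each optimum uniformly on
`[-width/2, width/2]`, decoupling geography from ecology. Rook-adjacent
sites are separated by borders: a geographic barrier arises on an open
border at rate `f` (default `1e-3` per generation) and disappears at rate
`c` (default `5e-5`). Each border is an independent two-state Markov
process, so `1/(1/f + 1/c)` is the pace of the landscape dynamics (default
`4.76e-5`) and `f/(f + c)` the long-run fraction of time a border is closed
(default 95%). Local catastrophes strike sites at rate `cr` (default 0) and
remove every resident at once. Borders start open, so the founding species
can spread over all sites; this is configurable (`borders_closed`).

### Individuals, traits and genetics

Each individual is diploid and sexed, with two ecological traits `x1, x2`
(resource-utilization position along each environmental axis) and a
choosiness trait `a`, each controlled by `L_k = 16` unlinked additive loci
with no environmental effect. A trait is the sum of its `2 L_k` allelic
values divided by `sqrt(2 L_k)`; with allele-level mutational standard
deviation `s_k * sqrt(2 L_k)` this is the unique additive normalization
under which one mutation perturbs the trait with variance `s_k^2` regardless
of `L_k`. Transmitted alleles mutate with probability `mu_k` (default
`1e-3`); `s_x = 0.1`, `s_a = 0.2` trait units.

Postzygotic isolation accumulates at a separate, unbounded set of neutral
incompatibility loci under an infinite-sites model: each birth carries
probability `mu_n = 1e-3` of one brand-new derived allele at a fresh locus.
Dosage at each such locus is diploid (0, 1 or 2 copies) and segregates
Mendelian-style — a parent with `g` copies transmits one with probability
`g/2` — so derived alleles can drift to fixation within an isolated
population, which is what makes divergence in allopatry irreversible. The
genetic distance between two individuals (or, frequency-weighted, between
two subpopulations) counts loci whose carrier status differs; two
individuals more than `GIT = 15` loci apart cannot interbreed. A flat
"transmit each mutation with probability 1/2" bookkeeping was rejected
during development: under it an allele carried by both parents reaches the
offspring with probability 3/4, carrier frequency obeys `p -> p - p^2/4`,
and every incompatibility allele is deterministically lost — no amount of
isolation then yields speciation.

### Mating

Mating is assortative on the ecological phenotype (a magic trait). The
probability that a pair mates uses the choosiness value of the choosier
individual: `Q = (1 - exp(-a^2)/2) * exp(-||dz||^2 / (2/(a^2 c_am))^2)` for
`a > 0`, `Q = 0.5` for `a = 0`, and the complement for `a < 0`
(disassortative preference). On a reproduction event a focal individual is
drawn, and potential mates are drawn uniformly with replacement among
opposite-sex residents of its site; incompatibility is checked first
(distance above `GIT` vetoes), then mating succeeds with probability `Q`;
after 50 failed draws the reproduction event lapses. Choosiness is
therefore nearly cost-free.

`c_am` scales how sharply choosiness translates into phenotypic
selectivity. It has no canonical value, and the model's behavior is
qualitatively sensitive to it: with `c_am = 1` the choosiness
trait evolves strongly *disassortative* (a candidate's average acceptance
probability over a phenotypically spread population is maximized by
preferring dissimilar partners), incipient species hybridize freely at
secondary contact, and the radiation stalls. With `c_am <= 0.5` selection
on `a` is positive, homogamy rises early and saturates — the behavior the
model is meant to produce — and reinforcement protects incipient species.
The default is `c_am = 0.2`; it is an ordinary configuration key.

### Ecology

Within each site, resources are continuously distributed over phenotype
space: the carrying capacity is Gaussian, `K(z) = K* exp(-||z - z*||^2 /
(2 sigma_K^2))` with `K* = 150` and `sigma_K = 1`, and competition is
frequency-dependent with Gaussian kernel `C(z_i, z_j)` of width
`sigma_C = 0.4` (so selection within a site is disruptive,
`sigma_C/sigma_K = 0.4`). Individual `i` dies at rate `r/K(z_i) * sum_j
C(z_i, z_j)` over co-residents, reproduces at constant rate `r` (one
generation = `1/r` model time), and competition never crosses site borders.
Newborns disperse: under the default island rule a newborn lands uniformly
on the natal site or any open-border neighbor; a `stay_move` rule (move
with probability `m` to a uniform open neighbor) is also provided.

A consequence worth knowing: under these kernels a sexual population
spreads over the resource distribution, so a site's equilibrium abundance
approaches `(sigma_K/sigma_C)^2 * K*` (about `6.25 K*` at the defaults),
not `K*`. Simulation cost scales accordingly.

### Initialization

Runs start from one ancestral species spread over all sites
(`init_per_site = 150` founders each). Founder allelic values are drawn
from a zero-centered Gaussian (allele-level s.d. `init_sd = 0.1`), so the
founder is adapted to the central optimum `(0, 0)` and carries no
incompatibilities.

## Measurement layer

The metacommunity is recorded every 100 generations. Within each site,
subpopulations are single-linkage clusters in `(x1, x2)` space with gap
threshold `sigma_C / 2` — a design choice: a sub-competition-width gap
keeps ecologically interchangeable individuals together, and the threshold
is an ordinary config key.
Species are the connected components of the graph over all subpopulations
with an edge where the pair is neither prezygotically isolated (mean-trait
mating probability below `AMT = 0.01`) nor postzygotically isolated
(frequency-weighted incompatibility distance above `GIT`). Species
identities are stitched across consecutive snapshots by maximal descendant
overlap (each individual carries the id of its ancestor at the previous
snapshot); at a split the most abundant fragment keeps the maternal id
(tie: the fragment with older members), the rest become daughters —
budding speciation, dated at snapshot resolution. The phylogeny of extant
and extinct species follows directly, with branch lengths in generations.

Rates as a function of diversity divide pooled event counts by pooled
species-time at each diversity level (the waiting-time estimator); the
trajectory is piecewise-constant between samples and an event is attributed
to the diversity in effect just before it. The stage-2 growth of diversity
is summarized by a von Bertalanffy fit `N(t) = a (1 - b e^{-ct})^3`
anchored at `N(0) = 9`; the reported stage-2 diversification rate is the
fitted curve's initial slope `3 a b c (1 - b)^2` (monotone in `c` given
`a`, and the natural rate at the stage-2 onset). The stage-1 rate is
`(n_optima - 1) / (stage-1 duration)`. Stage 1 ends when diversity first
reaches the number of environmental optima; stage 3 begins when the largest
species range stays at or below two sites for 1000 generations (the
persistence window suppresses boundary flicker). The stationary window is
the trailing quarter of the horizon, sanity-checked by a Spearman trend
test; turnover is the per-species event rate there. A shape-only plateau
detector (`radiation_plateau`) finds the end of the initial radiation
without reference to the optimum count: the first stall of the trajectory's
running maximum lasting a configurable window, reporting the modal
diversity over that window.

## Numerical and implementation choices

The event loop is an exact Gillespie algorithm in C++ with per-site
incremental competition sums (O(site size) per birth/death). Kernel values
are evaluated through a cubic-corrected lookup table for `exp(-x)`
(relative error below `2e-10`) with values under `exp(-30)` truncated to
zero; sums are recomputed from scratch at every snapshot so floating-point
drift cannot accumulate (an optional per-event audit,
`check_propensities`, verifies the incremental total against a fresh
recomputation to `1e-9` relative tolerance). All randomness flows through
R's generator, so a run is bit-reproducible from `set.seed()`. Simultaneous
events cannot occur in continuous time; snapshot times are handled by
advancing to the sampling instant and redrawing the (memoryless) waiting
time.

## Scaled-down study conditions used by tests and the acceptance script

Full-scale experiments (50 replicates of 100,000 generations per
parameter set; `inst/configs/`) are far beyond a desk run, so the shipped
checks use reduced problem sizes, chosen once:

* Radiation-plateau runs: default 3x3 gradient landscape (9 optima),
  `K* = 75`, `mu_n = 1e-2`, horizon 6,000-7,500 generations, 5 seeds. Raising
  `mu_n` compresses the incompatibility clock — the same
  computational-scaling argument the model itself relies on with its
  elevated trait mutation rates — while the plateau level is set by the
  number of optima, not by the clock. The compression matters beyond mere
  convenience: an incipient species pair is only safe from fusion at
  secondary contact once its divergence is well past `GIT` (hybrid matings
  through the segregating-variation tail can bridge pairs up to roughly
  2-3x `GIT`), and at the default `mu_n = 1e-3` that hardening takes tens
  of thousands of generations (first speciation near generation 18,000 in
  a verification run) — far outside a desk-scale horizon.
* Qualitative factor-response sweeps: clocks compressed the same way
  (`mu_n = 1e-2`, and for the competition-width sweep the barrier pace
  raised 5x at constant isolation time) so contact cycles fit the horizon;
  competition-width sweep on the default 3x3 landscape with `K* = 30` over
  5,000 generations, pace sweep on a `2 x 2` landscape with `K* = 40` over
  6,000 generations, 1-2 replicates per value. At these sizes the
  turnover-versus-pace direction reproduces; the diversity ordering across
  competition widths does not reproduce reliably — it is a property of the
  late (stage-3, niche-packed) stationary state that only exists at
  full scale — and the corresponding checks record that honestly
  rather than relaxing themselves.
* Equilibrium, oracle-equivalence, estimator and fit checks run at small
  closed-form sizes.

What the synthetic generators emulate — and what they do not: the
birth-death event fixtures have exactly constant per-species rates, and the
von Bertalanffy fixtures have exactly the fitted functional form plus
Poisson noise; passing those tests shows the estimators are correct, not
that real (or even simulated) diversification obeys those models. The
simulator itself emulates the model's world, not empirical data: mutation
rates are orders of magnitude above biological values to compress time, and
no real clade has nine equally spaced resource optima.

## Known limitations

* The choosiness dynamics depend on the unrecoverable `c_am`; outside
  roughly `c_am <= 0.5` the model drifts into disassortative mating and
  diversification by reinforcement fails (see above).
* Within-site phenotypic spread at the default kernel widths is comparable
  to the between-site optimum spacing, so prezygotic (AMT) isolation rarely
  triggers at the subpopulation level under the defaults; species
  boundaries are then carried mostly by genetic incompatibilities. An
  occasional open border can therefore transiently fuse a site pair (until
  the pair's divergence hardens well past `GIT`), and the observed
  radiation plateau fluctuates between 7 and 9 species rather than sitting
  exactly at 9.
* Species delimitation caps subpopulation incompatibility distances just
  above `GIT` for speed; use `incompat_distance_subpops()` when the exact
  distance matters.
* No linkage, dominance, sex chromosomes, evolving dispersal, or
  heterogeneous per-border rates.
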