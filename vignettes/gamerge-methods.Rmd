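---
title: "Selecting isomorphous merging groups for multi-crystal SAD with a genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting isomorphous merging groups for multi-crystal SAD with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamerge)
```

## The problem

Serial and mesh data collections produce hundreds of partial sub-data sets
(wedges of 10–30°, each 17–45% complete) from many micro-crystals. A
complete data set must be assembled by merging, but the crystals are not
identical: scale, overall B factor and — most damagingly — reflection-level
structure-factor differences (non-isomorphism) vary between crystal batches.
For SAD phasing this matters doubly, because the signal lives in Friedel
differences $\Delta I = I^+ - I^-$ that are only 1–2% of $I$ (Bijvoet
difference ratios near 0.015): merging incompatible crystals buries the
anomalous signal long before it degrades ordinary statistics such as
completeness.

Choosing the best subset to merge is combinatorial: $2^n - 1$ subsets for
$n$ sub-data sets, already infeasible around $n \approx 25$. `gamerge`
instead encodes a grouping of all $n$ sub-data sets as a chromosome — an
integer vector of length $n$ whose value at position $i$ is the merging
group of sub-data set $i$ — and optimizes it with a genetic algorithm (GA).
Three groups are the default: typically two isomorphous classes plus a
"sink" for low-quality wedges.

## The merging-statistics engine

All statistics are computed on unmerged intensities grouped by
Friedel-unique reflection. Friedel reduction maps $(h,k,l)$ and
$(-h,-k,-l)$ to one representative (first nonzero index positive), keeping
the measured sign; symmetry beyond $P1$ can be supplied as an explicit
operator list, and the synthetic generator emits already-reduced indices.
Resolution uses the exact triclinic reciprocal metric tensor; reflections
are filtered to $d \in (d_\min, d_\max]$ at load, and the load report
accounts for every dropped observation.

For a reflection $h$ with observations $I_i$, $\sigma_i$:

* $R_\mathrm{merge} = \sum_h \sum_i |I_i - \bar I_h| / \sum_h \sum_i I_i$
  and $R_\mathrm{meas}$ with the per-reflection factor
  $\sqrt{n_h/(n_h-1)}$, both over reflections with $n_h \ge 2$ — the
  standard multiplicity-corrected convention.
* $\langle I/\sigma(I)\rangle$: inverse-variance merged intensity over its
  propagated sigma, $\hat I \big/ (\sum_i \sigma_i^{-2})^{-1/2}$, averaged
  over unique reflections. Computed this way (rather than averaging raw
  $I_i/\sigma_i$) it grows with multiplicity when errors are random.
* CC$_{1/2}$: each multiplicity-$\ge 2$ reflection's observations are
  split into two halves (a seeded uniform draw per observation, ordered
  within the reflection, halves alternating); Pearson correlation of the
  half means across reflections. No $\sigma$–$\tau$ correction is applied;
  the split seed is an explicit argument, making the statistic
  deterministic and testable.
* CC$_\mathrm{anom}$: the same half-splitting applied per Friedel sign
  (each sign needs $\ge 2$ observations); the correlation of
  $\langle I^+\rangle_h - \langle I^-\rangle_h$ between the two
  half-sets.
* SigAno: $|\langle I^+\rangle - \langle I^-\rangle| /
  \sqrt{\sigma^2(\langle I^+\rangle) + \sigma^2(\langle I^-\rangle)}$ with
  inverse-variance merged signs, averaged over reflections with both mates.
  It is computed on intensities; no French–Wilson conversion to amplitudes
  is performed, a documented deviation from amplitude-based
  implementations.
* Completeness against the reference set of all uniques observed in the
  full pool (or an explicit count), and multiplicity as observations per
  observed unique.

Each statistic is reported for the inner shell, outer shell and overall.
Shells are equal-count over uniques sorted by descending $d$ (default 10);
"overall" is computed on the unshelled set, never averaged over shells. A
statistic whose precondition fails is `NA`, never silently 0; the scalar
accessors (`r_merge()` etc.) raise an error instead. Pools too small to
support even two shells keep an overall column and report shell values as
missing.

Every statistic is verified against an independent brute-force reference
(plain per-reflection loops) to $10^{-10}$ on randomized merged sets.

## The genetic algorithm

Fitness of a chromosome: every group with at least `min_group_size`
(default 3) members is scored as

$$s = -w_R\,R_\mathrm{meas}^\mathrm{inner} + w_I\,\langle I/\sigma\rangle
+ w_A\,\mathrm{CC_{anom}} + w_C\,\mathrm{CC_{1/2}}
+ w_\mathrm{comp}\,\mathrm{Compl.} + w_\mathrm{mult}\,\mathrm{Mult.}$$

with all non-$R$ terms taken from the overall shell and $R_\mathrm{meas}$
from the inner shell. The chromosome's fitness is its best group's score
(the product of a run is one merging group; the other groups act as sinks
for incompatible wedges; a per-group-sum mode is available behind a config
switch). A weighted term whose statistic is undefined contributes a fixed
penalty (`missing_penalty`, default $10^4$) so that tiny noisy groups are
never rewarded; a chromosome with no qualifying group gets
`no_group_penalty` ($-10^9$).

Each weight is an automatic weight times a user multiplier (defaults 1.0,
2.0, 0.0, 1.0, 0.2, 0.0 for $R_\mathrm{meas}$, $\langle I/\sigma\rangle$,
CC$_\mathrm{anom}$, CC$_{1/2}$, completeness, multiplicity).
`balance_weights()` runs one cycle with unit weights, takes each term's
best value over all scored groups, and sets the automatic weight to
$R_\mathrm{user}/\mathrm{best}$ (the $R_\mathrm{meas}$ weight is
$R_\mathrm{user}$ itself, so doubling $R_\mathrm{user}$ doubles every
automatic weight). This crude single-cycle calibration does not use fully
optimized values, but it stops any single term from dominating the
fitness; terms whose calibration best is not positive are zeroed and
reported.

Operators follow the published operating point: per-individual mutation
and crossover probabilities 0.6 and 0.3. A mutation event resamples each
position uniformly over all labels with probability `mut_indpb` (default
0.1) — the two-level scheme of the DEAP-style engines this design follows;
a 0.6 per-position rate would destroy inheritance. Crossover is single- or
double-point with equal odds. Selection is a size-2 tournament with a
single elite carried over unchanged, which makes the best-ever fitness
monotone and is robust to fitness rescaling by the weight balancer. Runs
are fully deterministic given the config seed; the CC split seed is fixed
per run so that fitnesses are comparable across chromosomes.

Every evaluation is appended to an archive (never pruned): the archive is
the raw material for the statistic-vs-signal analysis below. The
`random_control()` mode re-runs the same evaluation budget with operators
off and uniformly random parent survival — the null distribution against
which GA improvement is judged. `exhaustive_oracle()` enumerates all
assignments (quotiented by group-label permutation, i.e. restricted growth
strings — only the oracle applies the quotient, shrinking its space by up
to $g!$) and is the ground truth for small pools; it refuses more than
$10^6$ raw assignments, the combinatorial wall that motivates the GA.

An optional stagnation stop (`stagnation_stop`, default off) ends a run
after that many generations without best-ever improvement; it is
deterministic and used by the package's own studies to avoid spending
most of a run re-sampling around a converged optimum.

## The synthetic data generator

The generator is first-class, tested code: it provides the ground truth
that real experiments obtain from refined reference structures. It
emulates a mesh-style multi-crystal SAD collection:

* 500 unique reflections (desk-scale; a protein data set has $10^4$–$10^5$)
  in a 60 × 70 × 80 Å orthorhombic cell to 2 Å, intensities
  Wilson-exponential with $e^{-2Bs^2}$ falloff ($B = 20$ Å², $s = 1/2d$),
  giving realistic inner $\gg$ outer $\langle I/\sigma\rangle$ gradients.
* True anomalous differences $\Delta I = 2F\,\Delta F$ with
  $\Delta F \sim N(0, (r\,\mathrm{RMS}(F))^2)$ at Bijvoet ratio
  $r = 0.015$, the regime of the weak-signal experiments this method
  targets; the realized ratio is within sampling error of the target by
  construction.
* 60 wedges: two isomorphous classes of 25 plus 10 junk wedges. Each wedge
  observes a random 45 ± 5% of the uniques (clipped to (0.01, 1]), each
  1 + Poisson(1) times. Friedel mates are measured sign-balanced within a
  wedge (alternating with a random phase), as anomalous-phasing collection
  strategies aim for; fully random signs would plant a spurious
  class-composition asymmetry between the $I^+$ and $I^-$ observation
  sets of mixed merges.
* Class structure: class B is the poorer batch — scale 0.85, relative B
  +8 Å², and a partially occupied anomalous substructure
  (`anom_frac` = 0.3; variable ion/scatterer occupancy between crystal
  batches is a standard face of non-isomorphism). Both classes carry a
  fixed per-(class, reflection) intensity offset of magnitude
  $\sigma_\Delta = 0.15\,I_h$, identical for both Friedel mates: within a
  pure class it cancels exactly from $I^+ - I^-$, while mixed-class merges
  inherit a composition-dependent residual that corrupts anomalous
  differences — the phenomenon the GA exploits. Junk wedges see the
  unperturbed truth with 5× noise.
* Honest sigmas: the reported $\sigma$ equals the Gaussian noise actually
  added, $\sigma = 0.6\,(1\ \mathrm{or}\ 5)\sqrt{\max(I,0) + 5}$, so
  z-scores on perturbation-free data are standard normal (verified by a
  KS test). Non-isomorphism offsets are deliberately *not* in $\sigma$ —
  they are systematic error.

The magnitudes ($\sigma_\Delta$, noise scale, multiplicity) were chosen
once so that the synthetic statistics land in the reported ranges of real
weak-signal multi-crystal experiments — pure-class CC$_\mathrm{anom}$
around 10–25%, per-class multiplicity near 22, all-merged
$R_\mathrm{meas}$ tens of percent — and are tunable, not fitted.

What the generator does **not** emulate: space-group symmetry beyond
$P1$ + Friedel reduction, radiation-damage time series, scaling/absorption
errors, error-model recalibration of sigmas (real scaling programs inflate
$\sigma$ to match observed scatter; here $\langle I/\sigma\rangle$ grows
with multiplicity exactly as random-error theory predicts), and
diffraction images. Passing tests therefore demonstrate the method's
behaviour under planted, recoverable non-isomorphism with honest errors —
not performance on any particular real data set.

`anomalous_recovery()` — the Pearson correlation between merged observed
$\Delta I$ and the true $\Delta I$ — is the desk-scale stand-in for
model-phased anomalous difference map peak heights. Only its direction and
rank behaviour are comparable to map-based numbers, not its absolute
value.

## The study configuration

The package's own experiments (tests and the acceptance script) run the
GA on the default pools with population 50, up to 300 generations with a
50-generation stagnation stop, `mut_indpb` 0.05, and explicit weights
$w = (25, 0.1, 0, 5, 1, 0)$ chosen a priori by a scale analysis of each
statistic's dynamic range across candidate groups, such that no term's
typical spread dominates: the $R_\mathrm{meas}$ and CC$_{1/2}$ terms
separate pure from mixed groups, the $\langle I/\sigma\rangle$ and
completeness terms reward growing a group within its class, and the
anomalous-CC multiplier is left at its default 0. The last point matters:
the half-split CC$_\mathrm{anom}$ estimator is noisy at desk scale, and a
GA that optimizes it directly learns the split noise (a winner's curse)
rather than the signal. Keeping it out of the target reproduces the
method's central observation from the other side: optimizing ordinary
merging statistics *also* recovers anomalous signal, as measured
afterwards by CC$_\mathrm{anom}$ and ground-truth recovery of the selected
group.

With this configuration the GA best group is one planted class
(adjusted Rand index 1.0 in the packaged studies), with higher
CC$_\mathrm{anom}$, higher recovery and roughly 2.4× lower multiplicity
than merging everything.

## Archive analysis

`archive_analysis()` joins every archived (chromosome, group) evaluation
with its recovery and reports Spearman rank correlations of
CC$_\mathrm{anom}$, CC$_{1/2}$, $\langle I/\sigma\rangle$ and
$R_\mathrm{meas}$ (overall values) with recovery, plus decile-binned mean
recovery per statistic. Rank correlation is used because the relationships
are strongly nonlinear — CC$_{1/2}$ is informative only near the top of
its range. Recovery needs ground truth; on real pools the analysis
degrades to statistics only.

## Numerical and design notes

* Resolution filter half-open, $d \in (d_\min, d_\max]$, applied at load;
  no double counting at shell boundaries.
* Equal-count shells rather than equal-volume: stable statistics in every
  shell; the inner shell is shell 1.
* Ties in the half-split ordering have probability zero (continuous
  uniforms); the split is stable under observation reordering because the
  merged set is canonically ordered first.
* `cc_half`/`cc_anom` return `NA` when fewer than 3 reflections qualify
  or a half has zero variance (degenerate constant data returns 1 when
  the halves are exactly equal).
* The oracle fixes the first chromosome position to label 0 (restricted
  growth), evaluating $\le g^{n-1}$ assignments.
* Problem sizes in the packaged tests were chosen to keep the full suite
  within a coffee break on one core: 150–500 uniques, 6–60 wedges, GA
  budgets of $10^3$–$10^4$ evaluations with caching of repeated group
  evaluations.

## Limitations

* No scaling or outlier rejection between sub-data sets: the pool is
  assumed pre-scaled (as upstream pipelines do).
* $P1$ default symmetry; higher symmetry only via user-supplied operators.
* CC$_\mathrm{anom}$ here is seed-stable but need not match any specific
  scaling program's implementation numerically on real files.
* SigAno on intensities, not amplitudes.
* Single-process; determinism is guaranteed only per (pool, config, seed).
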