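---
title: "Selective bottlenecks in symbiont life cycles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective bottlenecks in symbiont life cycles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcycle)
library(dplyr)
```

`symcycle` studies how a *selective* population bottleneck at host entry
shapes the adaptation of horizontally transmitted bacterial symbionts —
the situation of a rhizobium-like bacterium that must, at every host
cycle, (i) survive in the rhizosphere, (ii) win one of a limited number
of nodulation events, and (iii) proliferate clonally inside its nodule
before being pooled into the next cycle's inoculum. The package has four
analysis layers: a stochastic life-cycle simulator, cohort analysis of
whole-population allele-frequency trajectories, a gene-level parallelism
statistic with a randomization null, and competitive-index statistics,
plus ground-truthed generators that make every layer testable offline.

## The life-cycle model

A population is a set of clonal genotypes, each with two trait values in
$(0, 1]$:

* $c$ — **nodulation competitiveness**, the trait selected at host
  entry;
* $p$ — **within-host proliferation**, the trait governing how many
  cells a founder contributes to the harvest.

One cycle under the default (`bottleneck_first`) ordering is:

1. **Hypermutagenesis.** Each genotype receives a Poisson number of
   mutation events with mean `abundance * U`. Each event converts one
   cell into a new genotype whose traits are the parent's multiplied by
   factors drawn from the `mutation_architecture()`, clamped at the
   theoretical optimum of 1. Clamping happens at genotype creation: a
   trait can never exceed 1 nor reach 0.
2. **Selective bottleneck.** `B` nodules are founded, each by a single
   cell drawn with probability proportional to `abundance * c`
   (a weighted multinomial lottery). This is the only step where $c$
   acts, and it is the step that makes the bottleneck selective rather
   than purely stochastic.
3. **Within-host proliferation and pooling.** A nodule founded by a
   genotype with trait $p$ yields `round(K_max * p)` cells (at least 1);
   populations stay clonal within nodules. The pooled harvest is
   rescaled to `rhizosphere_size` cells by multinomial resampling, which
   preserves expected frequencies and mimics the dilution transfer of a
   pooled nodule crush.

The alternative `proliferation_first` ordering moves clonal
multiplication (proportional to $p$) *before* the bottleneck and makes
nodule output uniform. It answers the chronology question: does it
matter that the bottleneck sits immediately after the mutagenic phase
and before proliferation?

Population state is tracked per genotype (counts, never per-cell
arrays), which keeps $10^6$–$10^7$-cell rhizospheres at desk scale.
Frequency tracks are recorded for every mutation that ever founds a
nodule; a mutation that is never sampled into a nodule exists for less
than one cycle at frequency $10^{-6}$ and is necessarily lost, so
nothing observable is discarded.

### Parameters, defaults, and why

| parameter | default | units / meaning |
|---|---|---|
| `B` | 100 | nodules per cycle (10–3,000 spans the interesting range) |
| `rhizosphere_size` | 1e6 | cells inoculated per cycle |
| `U` | 0.01 | mutation events per cell per rhizosphere phase |
| `K_max` | 1e5 | cells per nodule at $p = 1$ |
| `c0`, `p0` | 1e-4 | ancestor traits (fitness $10^{-8}$: a poorly adapted new symbiont) |
| `n_cycles` | 50 | host cycles |
| `domain_bounds` | (1e-5, 1e-3) | iso-fitness lines separating low/mid/high domains |

The one default that deserves justification is `U`. Transient
rhizosphere hypermutagenesis (error-prone polymerases induced outside
the host) raises the mutation rate by roughly three orders of magnitude.
Working backwards from the observed flux in evolving lineages — on the
order of twenty new mutations per cycle establishing above a 5%
population frequency through a bottleneck of a few hundred nodules — a
single-cell mutant's establishment probability of about
$B\,c_m/(N\,\bar c)$ implies on the order of $10^4$ mutation events per
cycle in a $10^6$-cell rhizosphere, i.e. $U \approx 10^{-2}$ per cell
per cycle. The same order follows from a $\sim$1,000-fold elevation of a
$\sim 10^{-10}$/bp/generation basal rate over $\sim$25 generations on a
5.8-Mb genome. A rate orders of magnitude lower would produce
essentially no establishments over 50 cycles at these population sizes,
leaving the model with nothing to select.

The default mutation architecture is deliberately simple and fully
exposed: a mutation affects $c$ only, $p$ only, or both (probabilities
0.45/0.45/0.1, independent factor draws for "both"); a factor is
beneficial with probability 0.1 (log-uniform on $[1, 100]$), otherwise
deleterious (log-uniform on $[0.1, 1]$). These are plausible,
order-of-magnitude choices for a maladapted ancestor with large
mutational targets, not estimates fitted to data.

### Population summaries and fitness domains

The per-cycle summary is the abundance-weighted **median** of each trait
(an abundance-weighted mean is selectable); fitness is the product of
the two summaries. Fitness domains use strict inequalities on both
sides: `low` below $10^{-5}$, `high` above $10^{-3}$, boundary values
`mid`. A mutation's *domain at origin* is evaluated at the **start** of
its cycle of origin (the previous cycle's post-harvest state, or the
ancestor for cycle 1), because mutations arise in the rhizosphere before
that cycle's bottleneck acts.

### What the simulator shows — and one honest caveat

Pooling the mutations that ever reach 30% frequency and taking the
geometric mean of their fold effects ($c$-factor over $p$-factor) in the
low-fitness domain, the model reproduces the key qualitative claims, as
recomputed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` (100 replicates $\times$ 50 cycles per
condition):

* with a 10-nodule bottleneck, early selected mutations are strongly
  biased toward competitiveness (geometric-mean fold effect around
  30, standardized effect $d \approx 1.9$);
* moving proliferation before the bottleneck brings the two selective
  pressures close to equilibrium (geometric mean near 1, $d \approx 0$);
* weakening the bottleneck to 3,000 nodules shrinks the bias several
  fold (geometric mean around 5, $d \approx 0.5$).

We operationalize "dominance of competitiveness" as a significantly
positive mean log fold effect *with* at least a medium standardized
effect size ($d \ge 0.5$), because with hundreds of pooled mutations a
mean-only test would flag arbitrarily small asymmetries. Under this
rule, dominance at the largest bottleneck sits exactly on the boundary
rather than clearly vanishing. The residue is structural: a brand-new
mutant is a single cell, and its establishment probability is
proportional to its competitiveness at *every* bottleneck size, so some
competitiveness bias survives even the weakest bottleneck under this
effect-size distribution. Complete abolition likely requires a narrower
effect-size distribution than our placeholder defaults; we kept the
defaults rather than tuning them to the expected picture.

## Cohort analysis of allele-frequency trajectories

Whole-population sequencing of an evolving lineage (every other cycle to
cycle 35, in the default sampling design) yields one frequency
trajectory per mutation. Mutations that sweep together — one clone's
linked mutations — form *cohorts*. `cluster_cohorts()` clusters
trajectory rows by hierarchical agglomerative clustering and cuts the
tree at height 0.3; singletons are cohorts too. The distance metric and
linkage are configurable (defaults: Euclidean, complete) since only the
clustering routine and the cut height are canonical; published cohort
compositions need not be exactly reproducible under any particular
choice. Missing frequencies (unsequenced cycles) are linearly
interpolated, extending the terminal values, because the distance must
be defined on complete vectors.

Derived summaries follow the field's conventions: *fixation* is a mean
cohort trajectory exceeding 90%; the *clonal interference fraction* is
the share of mutations that rose above 30% and ended below the 5%
detection limit ("extinction" is operationalized as falling below
detection, and the fraction is undefined — not zero — when nothing ever
rose); *new mutations per cycle* divides first detections by cycles
elapsed, not by the number of sequenced samples.

## Gene-level parallelism (G scores)

For gene $i$ with coding length $L_i$, the expected number of
independent mutations under a uniform per-base-pair process is
$E_i = N_\mathrm{tot} L_i / L_\mathrm{tot}$, and the score is
$G_i = 2 N_i \ln(N_i / E_i)$, with $G_i = 0$ at $N_i = 0$ (limit
convention; negative scores occur when a gene is hit less often than
expected). Counting is event-level: unique
(lineage, replicon, position, alt) combinations at or above the 5%
detection threshold, all mutation types in coding regions, the same site
in two lineages counting twice, multi-nucleotide entries in one gene
counting once. Significance comes from 1,000 randomizations that
reassign $N_\mathrm{tot}$ mutations to genes with probabilities
$L_i/L_\mathrm{tot}$: per-gene $Z_i = (G_i - \bar G_i^{sim})/s_i^{sim}$
with a one-sided upper-tail normal P value (the question is "mutated
*more* often than expected") and Bonferroni correction; the G-score sum
is tested the same way. The normal tail, rather than an empirical
quantile of 1,000 simulations, is what makes extremely small P values
expressible; genes never hit in any randomization have a degenerate null
and conservatively receive $P = 1$, flagged in the output. The
acceptance suite verifies that this recipe keeps the per-gene false-flag
rate under the null below 1% at Bonferroni $\alpha = 0.01$ and detects a
gene observed at ten times its expectation among 5,000 genes with power
above 90%.

## Competitive indexes

A co-inoculation assay yields
$CI = (\mathrm{test_{out}}/\mathrm{ref_{out}})\,/\,(\mathrm{test_{in}}/\mathrm{ref_{in}})$,
shared across fitness (pooled nodule colonies), nodulation (nodule
occupancy), culture-medium and rhizosphere assays; the assay type is
metadata. Undefined CIs (zero denominators) are excluded from means with
a logged count. Significance per strain uses a one-sided Student t-test
against 1 with a specific wrinkle: when every replicate CI exceeds 1 the
values are first inverted and the inverses compared with 1. When CIs
straddle 1 no direction is canonical; we test in the direction of the
sample mean and report which branch was taken. A log-transformed variant
is exposed but off by default. Across strains, P values are
Benjamini–Hochberg corrected; verdicts are `beneficial`/`deleterious`
only when the mean CI is on the matching side of 1 *and* the adjusted P
clears $\alpha = 0.05$.

One numerical property worth knowing: the CI is a ratio estimator, so
its mean over replicate assays carries a finite-sample bias of order
$+CI/(n_\mathrm{out} q)$, where $q$ is the reference strain's share of
the $n_\mathrm{out}$ output units. At the realistic assay scale of 96
nodules this is a +2–5% offset for $CI \ge 1$ — larger than the Monte
Carlo standard error after a few thousand replicates, and irreducible by
any choice of inoculum ratio. The acceptance suite therefore checks the
Monte Carlo mean against the *exact* enumerated expectation of the
estimator (which passes) alongside the naive "within 3 SE of the true
CI" bound (which cannot pass for $CI \ge 1$ at $10^4$ replicates, and is
reported failing rather than loosened). Practitioners comparing mean CIs
with 1 should keep this small upward bias in mind; it does not affect
the sign-based verdicts at realistic effect sizes.

## What the generators emulate — and what they do not

* `gen_trajectories()` plants cohorts as *sequential logistic sweeps*
  (stratified random midpoints, random steepness, 35% of cohorts
  peaking and declining as under clonal interference), with independent
  truncated-normal noise per observation (SD 0.02 by default, the scale
  of binomial sampling noise at a few hundredfold sequencing coverage).
  Logistic sweeps — not simulator output — are used for clustering tests
  so that clustering correctness is testable independently of the
  simulator. Real trajectories have autocorrelated noise, linkage to
  competing cohorts, and detection censoring; a perfect adjusted Rand
  index here bounds only the noise-robustness of the clustering step.
* `gen_mutation_table()` assigns mutations to genes multinomially with
  weights `length * multiplier`, distinct positions within genes laid
  end to end per replicon. It does not emulate mutational spectrum
  heterogeneity along the genome, which the G score deliberately
  ignores.
* `gen_ci_counts()` draws the test strain's share of 96 output units
  binomially with odds $CI \cdot r$. It models neither plant-to-plant
  overdispersion nor nodule co-occupancy (real assays are >90%
  single-strain nodules).
* `sim_to_tables()` bridges the simulator to the analysis dialects
  (sampling every other cycle by default), enabling end-to-end tests.

All generators are bit-reproducible under a fixed seed and emit their
ground truth alongside the data.

## Problem sizes and numerical choices

The shipped test and acceptance runs use 100 replicates $\times$ 50
cycles per simulated condition at `rhizosphere_size = 1e6`; 50 generator
seeds for cohort recovery; 25 runs of the 5,000-gene power experiment
and 5 null runs for calibration; and $10^4$ replicate CI assays per true
CI — sizes chosen so each claim's Monte Carlo error is well below the
effect being asserted. Ties in the weighted median resolve to the lower
value (the smallest value reaching half the total weight). Poisson
mutation counts are truncated at a genotype's abundance (each event
converts one existing cell). `rmultinom()` underlies every resampling
step, so all randomness flows from R's global RNG and a single seed.

## Limitations

No explicit genome, linkage map or recombination; no per-nodule
sequencing resolution (frequencies are pooled across nodules); no
plant-side dynamics, nitrogen fixation, or antimutator evolution; no
genealogy (Muller-plot) inference from cohorts; no read-level
simulation. The bundled `reconstructed_mutants.tsv` is a small curated
summary table of beneficial reconstructed mutations from a nodulation
evolution experiment, included so the documented examples and headline
counts are reproducible offline; it is not a substitute for the full
supplementary mutation tables, which are not distributed with the
package.
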