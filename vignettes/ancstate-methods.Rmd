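---
title: "Models and methods behind ancstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ancstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ancstate reconstructs two kinds of ancestral state along one rooted
reference phylogeny of prokaryotic genomes: the optimal growth temperature
(OGT) of ancestral organisms, read off reconstructed 16S rRNA stem
sequences through a "molecular thermometer", and the ancestral gene-family
repertoire, inferred under a phylogenetic gain-loss-duplication
birth-death model. A single-linkage clustering front end turns an
all-vs-all protein similarity search into the genome-by-family occurrence
matrix that the second track consumes. This vignette explains the models,
the tunable parameters, the simulators used for validation, and the design
choices made where more than one reasonable definition exists.

## The molecular thermometer

The thermometer rests on the long-standing observation that the G+C
content of the double-stranded (stem) regions of rRNA correlates with the
growth temperature of the organism: stems of thermophiles are more
GC-rich because G:C pairs stabilise the helix. The pipeline has four
stages.

**Stem mask.** Stem annotations are per-sequence lists of 1-based
positions into the *ungapped* sequence, projected onto alignment columns.
A column is a stem column when at least a fraction `fraction` (default
1.0, a strict consensus — the conservative choice) of the annotated
sequences with a residue in that column annotate it as stem; gap cells
neither vote nor count in the denominator. `stem_gc()` then computes
100·(G+C)/(A+C+G+T) over masked columns, ignoring gaps and N on both
sides of the ratio.

**Calibration.** `calibrate_thermometer()` fits ordinary least squares of
OGT (°C) on stem GC (%) across extant taxa, reporting the Pearson
correlation, adjusted R², and the correlation of phylogenetically
independent contrasts (`pic_correlation()`, Felsenstein's standardized
contrasts computed with `ape::pic` on the same tree, correlated through
the origin). The contrasts diagnostic matters because both traits are
phylogenetically autocorrelated: a high raw correlation can be driven by
a few deep splits. The calibration object also records the coefficient
covariance matrix of the fit, used optionally for interval construction
(below).

**Nonhomogeneous substitution model.** Ancestral GC is only estimable
under a model in which equilibrium GC is free to vary across the tree.
We use the minimal such model: Tamura (1992) with a branch-specific
equilibrium GC `theta_b` on every branch, one global
transition/transversion ratio `kappa`, and a free root GC `theta_root`
that defines the root state frequencies. Stationary frequencies under
T92 are ((1−θ)/2, θ/2, θ/2, (1−θ)/2) for A, C, G, T. Each branch's
generator is normalized to one expected substitution per site at its own
stationary distribution, so the input branch lengths keep their
substitutions/site meaning and are never re-estimated. Transition
probabilities use the closed-form Tamura–Nei solution rather than a
matrix exponential.

`fit_nonhom_t92()` maximizes the pruning log-likelihood (gaps and N as
missing data; site patterns compressed with weights) by bound-constrained
L-BFGS-B over `kappa` ∈ [0.05, 100] and all thetas ∈ [0.01, 0.99].
Because the likelihood is multilinear in each branch's transition matrix,
one inside–outside pass yields every branch-theta derivative from a
single 4×4 contraction per branch; only the 4×4 kernels themselves are
differenced numerically. This makes the ~2n-parameter optimization cost a
few seconds for 30 taxa and 1,000 sites. Each branch theta is initialized
at the mean stem GC of its descendant tips; `multistart` (default 3)
jittered restarts guard against local optima, under a recorded seed.

**Ancestral prediction.** `sample_ancestral_replicates()` draws R
(default 100) *joint* samples of all ancestral sequences: per site, the
root state from its marginal posterior, then children conditionally down
the tree. Joint sampling (rather than independent marginal draws per
node) preserves the cross-node correlation of GC, which the interval
construction needs. Exact per-node marginal posteriors are returned
alongside and are tested against brute-force enumeration. Ties in the
categorical draws resolve by cumulative probability in A<C<G<T order.
`predict_ancestral_ogt()` converts each replicate's stem GC to OGT with
the calibration line; the point estimate is the replicate mean and the
default interval the 2.5th–97.5th replicate percentile.

Two interval definitions are offered. The default percentile interval
reflects only reconstruction uncertainty *given* the fitted model and
calibration; it is honest about what it conditions on but under-covers
when calibration error dominates — which our simulations show is the
typical regime (see below). With `regression_uncertainty = TRUE`, each
replicate is scored with its own coefficient pair drawn from the
bivariate normal sampling distribution of the OLS fit, propagating
calibration uncertainty into the interval. When the replicate
distribution is extremely skewed the percentile interval is widened to
contain the mean, so `ci_low ≤ point ≤ ci_high` always holds.

## Protein families

Two sequences are linked when they share at least 35% identity
(inclusive), their alignment covers at least 70% of *both* sequence
lengths (inclusive), and the hit E-value is strictly below 1e-4. These
boundary semantics ("at least" read as ≥, "below" as <) are fixed and
tested. Coverage uses the full length of each partner as denominator and
the reported alignment length as numerator, with no gap correction. Only
the best (smallest-E-value) hit per unordered pair survives
symmetrization; self-hits never create edges. Families are the connected
components of the resulting graph (single linkage), computed with igraph
and verified against an independent breadth-first-search oracle;
sequences with no surviving edge become singletons. Identifiers are
"FAM" plus a zero-padded rank by decreasing size, ties broken by the
lexicographically smallest member. No post-hoc family refinement
(splitting by alignment quality) is performed; families are pure
connected components, a recorded limitation.

## Gene-content reconstruction

Each family's copy number evolves along the tree as a continuous-time
Markov chain on {0, 1, ..., C_max}: innovation 0→1 at rate g, per-copy
duplication at rate λ, per-copy loss at rate μ, with no up-transition out
of the cap. C_max defaults to 10; observed counts above the cap are
truncated with a warning, and raising the cap from 8 to 12 moves presence
posteriors by less than 1e-6 when observed counts stay ≤ 4 (tested).
The root prior defaults to the stationary distribution of the family's
truncated generator (a Poisson prior is available). Rates are constant
across branches within a family.

`fit_rates()` estimates (g, λ, μ) per family by bounded ML on the log
scale (bounds [1e-4, 100]); `model = "gl"` fixes λ = 0. Families sharing
an identical leaf-count pattern share one fit. `fit_rates_pooled()`
instead maximizes the summed log-likelihood of all families under one
shared rate triple, collapsing identical patterns with weights, and can
condition each family's likelihood on being observed in at least one
genome (ascertainment correction; off by default).

A deliberate division of labour follows from simulation results: with 16
genomes, *per-family* ML rate estimates are inherently noisy — the median
relative error of the per-family loss rate stays above 50% at any tree
scale we examined, because a single family's 16 counts carry only a
handful of birth-death events. Estimating one *shared* rate triple by
pooling ~1,000 families recovers the loss rate to within a few percent.
The package therefore uses per-family rates (the Count-style route) for
posteriors and event calls, where only the induced posteriors matter,
and the pooled estimator whenever the scientific question is the rate
itself.

`node_posteriors()` runs the inside–outside algorithm for exact marginal
posterior copy-number distributions at every node; `call_events()` builds
the exact joint parent–child posterior on every branch and aggregates it
into the four event classes — gain (parent 0, child ≥ 1), loss
(parent ≥ 1, child 0), expansion (child > parent ≥ 1), contraction
(parent > child ≥ 1). Events, presence (P(n ≥ 1)) and multicopy state
(P(n ≥ 2)) are called when the probability strictly exceeds τ = 0.5;
the strict inequality means a probability of exactly 0.5 is never
called. Both marginal and joint posteriors are tested against exhaustive
enumeration on trees of 3–6 leaves.

`gain_rates()` divides called gains per branch by branch length
(substitutions/site), excluding zero-length branches with a warning
rather than reporting infinite rates, and classes branches as ancestral
(internal child) or contemporary (leaf child). `compare_gain_rates()`
compares the two classes with a Wilcoxon rank-sum test — exact by
complete enumeration when the pooled sample is ≤ 12 without ties, a
tie-corrected normal approximation (no continuity correction) otherwise;
a paired signed-rank variant is available since both test names are in
circulation for this comparison. `gains_vs_substitutions()` regresses
per-branch gain proportion (called gains / families present at the child
node; the denominator is one of several defensible choices and is
labelled) on branch length.

## The simulators and what they do (not) emulate

`simulate_tree()` draws a Yule tree and rescales it to a target mean
root-to-tip length (default 0.5 substitutions/site, a typical depth for
a conserved marker across an archaeal class).

`simulate_family_evolution()` runs the exact gain-loss-duplication jump
process down the tree (vectorized Gillespie per branch), with root states
from the stationary distribution. Defaults g = 0.35, λ = 0, μ = 0.7
give a stationary presence probability 1 − e^{−g/μ} ≈ 0.39, inside the
30–70% occupancy band where ancestral content is genuinely informative.
All node states are recorded; per-branch true events are defined by
diffing parent and child states, so truth is self-consistent by
construction.

`simulate_thermometer_dataset()` assigns OGT to every node by Brownian
motion along branches (default root 60 °C, σ = 12 °C per √(subst/site));
each branch's equilibrium GC is the inverse calibration (default
OGT = 2·GC% − 60) of the child's OGT, clamped to [0.01, 0.99], and
sequences evolve under the branch-specific T92 kernel. Every column is a
stem column. This emulates the *assumption* behind the thermometer —
lineages tracking their thermal niche with rRNA GC — but deliberately
not two features of real data: alignment gaps/ambiguities, and the lag
with which realized GC follows a moving equilibrium. That lag is real in
the simulation too, and it biases the extant-taxa calibration slope
upward at shallow tree depths (tip GC reflects a lineage-averaged, more
root-ward temperature while tip OGT is current); the bias shrinks as
branches lengthen and sequences equilibrate. Recovery experiments
therefore face a trade-off that real data share: deep trees calibrate
better but retain less signal about the root state. Passing tests on
these simulations show the estimators are correct and well-calibrated
*under the model's own assumptions*; they cannot show that real rRNA
evolves by branchwise-stationary T92, and they inherit none of the
alignment and annotation error of real 16S data.

`simulate_planted_families()` / `simulate_hit_table()` plant a family
partition and emit a BLAST-tabular hit file in which within-family pairs
pass all thresholds and optional cross-family noise hits sit below the
identity threshold; with zero noise, clustering must recover the
partition exactly, and output files are byte-identical per seed.

## Numerical choices

* Pruning partials are column-rescaled per node with accumulated log
  scale factors; impossible sites report −Inf rather than NaN.
* The T92 kernel is closed-form; the birth-death kernel uses one
  eigendecomposition of the (real-spectrum, detailed-balance) generator
  per likelihood evaluation, with `Matrix::expm` as fallback whenever the
  eigenvector reconstruction is not accurate to 1e-9; kernels are clipped
  to nonnegative and row-renormalized.
* Optimizer failures are flagged per family (`converged = FALSE`), never
  silent; the pipeline continues and reports the count.
* All stochastic steps (fits' multistarts, replicate sampling,
  simulators) take explicit integer seeds and are bitwise reproducible;
  pipeline outputs are byte-identical across runs with the same
  configuration (wall-clock timings go to log files, which are excluded
  from that contract).

## Problem sizes used in the test suite

The suite validates exactness on 3–6 leaf trees (where enumeration over
all internal state assignments is feasible), kernel correctness against
100,000 simulated jump-process paths, thermometer recovery on 30-tip
trees with 1,000 stem sites over 50 replicate simulations, and
gene-content recovery on a 16-tip tree with 1,000 families — sizes
chosen so that every statistical check has enough resolution to fail if
the code were wrong, while the whole suite stays comfortably runnable on
a laptop.

The thermometer recovery experiments run at tree depth 0.75 and drift
σ = 18 °C/√(subst/site) rather than the simulator defaults: that is the
combination at which 30 Brownian tips typically span ≥ 40 °C of OGT —
the span a calibration needs — while retaining any root signal. Even
there the three goals pull apart: calibration wants deep, equilibrated
tips; root reconstruction wants shallow ones; and interval coverage
inherits both errors. The recovery results should be read with that
trade-off in mind, as quantifying the method's real operating
characteristics rather than certifying tight bounds.

## Known limitations

* The thermometer interval conditions on the fitted substitution model;
  uncertainty in `kappa`/theta estimates is not propagated (the
  `regression_uncertainty` option propagates calibration uncertainty
  only). Coverage of the default percentile interval is well below
  nominal in simulations where calibration error dominates.
* Per-family rate estimates from few genomes are noisy by nature; treat
  them as nuisance parameters behind the posteriors, not as estimands.
* The clustering stage implements single linkage only; chaining through
  promiscuous domains is not mitigated.
* Horizontal transfer is not modelled: a transfer into a lineage is seen
  as a gain, and donor identification is out of scope.
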