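---
title: "Models and methods behind polysynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polysynergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysynergy)
```

polysynergy implements an end-to-end polypharmacology workflow for
kinase-inhibitor combination discovery: a set-theoretic model that
predicts multi-target inhibition sensitivity from monotherapy screens and
kinome-wide binding profiles, experimental synergy scoring, target-pair
deconvolution, and a stochastic simulator of signaling-gated cell growth
with a deterministic twin. This vignette explains the underlying models,
their assumptions, the tunable parameters, and the numerical and design
choices; the README shows the worked end-to-end example.

## The set-theoretic sensitivity model

The modeling input is a drugs x kinases matrix of dissociation constants
(Kd, nM) from a kinome-wide binding assay, and one normalized sensitivity
value per drug. Each drug is reduced to a binary *target profile*: kinase
$k$ is a target of drug $i$ when $K_d(i,k) \le F \cdot \min_{k'}
K_d(i,k')$ with fold-threshold $F = 50$ by default. The threshold is
drug-relative because inhibitors differ enormously in intrinsic potency;
a missing Kd means "not bound at the assayed range" and never yields a
target. Raw drug sensitivity scores (DSS, an AUC-like summary of the
single-agent dose-response) are min-max normalized to $y_i \in [0,1]$.

For a query target set $d$ (a single drug, or the union of two drugs'
profiles), the predicted sensitivity is:

* if some training profiles equal $d$, the mean of their $y_i$;
* otherwise $(y_{\min} + y_{\max})/2$, where $y_{\min}$ averages the
  most-sensitive strict-subset drug $h$ with all subset drugs nested
  above $h$'s profile but less sensitive than $h$, and $y_{\max}$
  symmetrically averages the least-sensitive strict-superset drug $l$
  with superset drugs nested below $l$ but more sensitive than $l$.

The intuition: inhibiting a superset of a drug's targets should kill at
least as well (minimization side), and inhibiting a subset at most as
well (maximization side); averaging the two bounds interpolates.

Two conventions make the rule total, and both are package design
decisions: the empty profile acts as a boundary anchor with $y = 0$ (no
inhibition kills nothing) and the full kinase universe as an anchor with
$y = 1$ (total inhibition kills everything), so a query with no subset or
superset in the training set predicts 0.5. Set relations on the
minimization/maximization side are strict; equality is consumed by the
first branch. One caveat worth knowing: the minimization average is not
monotone under arbitrary data edits -- raising the sensitivity of a
*non-anchor* subset drug above the current anchor re-anchors the average
and can pull additional low-sensitivity drugs into it, lowering the
prediction. The package's property tests therefore assert the form of
monotonicity that does hold (edits to the anchor itself).

### Essential-target selection

The *essential target set* $S$ is the subset of kinases whose projected
profiles best predict the training sensitivities, measured by mean
leave-one-out absolute error of the predictor above. The search is a
deterministic greedy forward-floating procedure: add the kinase whose
inclusion most reduces the LOO error, then attempt removals of earlier
picks, repeating until no candidate reduces the error by at least
`minImprove` or `maxSize` (default 20) is reached. Ties are broken
toward the lexicographically smallest kinase symbol, so the search is
reproducible without randomness. `minImprove` (default 0.01 on the
normalized sensitivity scale, i.e. one percentage point of the dynamic
range) is the parsimony control: without it the floating search chases
noise-level LOO improvements and pads $S$ with spurious targets; with it
the planted-truth recovery experiments converge on the planted set.

Drug combinations are scored by projecting the union of the two profiles
onto $S$ and predicting; the default reported synergy is HSA-style on
predictions, $y_d - \max(\hat y_1, \hat y_2)$, with the raw $\hat y_d$
also emitted, since either scale can be compared to experiments.

The fitted model is also rendered as a drug-target network: selected
kinases with identical binding patterns across the training drugs are
merged into one node (the data cannot distinguish them), nodes are
annotated with the drugs hitting them, and two nodes are adjacent when a
drug hits both. A combination is predicted effective when deleting all
nodes hit by either drug disconnects the remaining graph (or empties
it) -- redundant survival routes appear as parallel paths that a single
drug cannot sever.

## Experimental synergy scoring

Dose-response matrices are $n \times m$ grids of percent inhibition over
the dose combinations of two drugs, with the zero dose of each included,
so the first row/column are the single-agent margins. Values outside
[0, 100] are kept; screening noise routinely produces them.

The Bliss excess volume averages, over the nonzero-dose grid, the
observed combination inhibition minus the Bliss independence expectation
$f_1 + f_2 - f_1 f_2$ computed on inhibition fractions. Margins are
smoothed through a four-parameter logistic fit by default (screens fit
curves before scoring); raw margins are a flag away. A second flag
replaces the expectation with the plain product $f_1 f_2$: applied to
inhibition fractions that form is *not* probabilistic independence, but
it is retained (regression-tested) because it appears in the literature
as a shorthand for the same quantity. On a surface whose cells sit
exactly at independence the score is 0; a uniform planted excess of
$\delta$ percentage points returns exactly $\delta$.

The 4PL model is $y = L + (U - L)/(1 + (\mathrm{EC50}/x)^s)$ fitted by
bounded Levenberg-Marquardt least squares with $L \in [-20, 50]$,
$U \in [0, 150]$, $s \in (0, 10]$, EC50 within a decade of the assayed
dose range; the initializer interpolates the half-response dose on the
log-dose scale. Degenerate inputs (constant responses, fewer than four
distinct doses) or non-convergence fall back to monotone interpolation
of the raw margins with a warning, so scoring never aborts on a flat
curve.

The remaining assay transforms are exact closed forms: the HSA score
$y_{\mathrm{comb}} - \max(y_1, y_2)$; the siRNA double-knockdown score,
the mean over cross-drug target pairs of $y_{ij} - y_i y_j$ on fractions
(reported x100); qPCR percent expression
$100 \cdot 0.5^{\Delta Cp_\mathrm{target}} / 0.5^{\Delta
Cp_\mathrm{housekeeping}}$; CRISPR viability (day-5/day-1
luminescence ratio) and cytotoxicity (death readout divided by that
viability).

## Target-pair deconvolution

To explain why two combinations of a shared drug can behave oppositely,
candidate target pairs are derived from the binding matrix with a
stricter potency rule: kinase $k$ is a potent target when $K_d <
10 \cdot \min K_d$, with a *strict* inequality -- deliberately different
boundary semantics from the inclusive 50-fold modeling rule, mirroring
how the two thresholds are stated. Targets whose log2 expression in the
modeled cell line is below 6 are removed (missing expression counts as
non-expressed, with a warning). Each combination contributes the
unordered cross pairs of its two drugs' surviving targets, self-pairs
excluded; pairs are then grouped as unique-to-A (G1), shared (G2) and
unique-to-B (G3). The groups partition the union and are invariant to
drug order within a combination.

## The signaling-network growth simulator

The mechanistic stage asks whether a small signed signaling network can
reproduce silencing phenotypes. Genes enter the network when their
expression deviates from a cell-line panel mean by more than 100%
($D = |e - \bar e| / \bar e > 1$, strict). Signed edges compile to
mass-action reactions:

* activation $A \to B$: conversion with propensity $k_p(B) X_A$
  (source-consuming by default; a catalytic $A \to A + B$ variant is a
  flag),
* inhibition $B \dashv C$: annihilation $B + C \to \emptyset$ with
  propensity $k_d(C) X_B X_C$,
* every gene: first-order self-degradation $k_d(A) X_A$.

This interaction scheme has no production term, so a literally compiled
network decays to extinction; the compiler therefore adds a constant
source $\emptyset \to A$ at rate $k_p(A)$ for genes with no activating
input by default (`sources = "roots"`). Each gene has exactly one
production constant $k_p$ and one degradation constant $k_d$ (per hour),
shared between its basal source or incoming activation reactions and its
degradation/inhibition reactions respectively.

Cell growth is a separate birth process for a pGrowth species with
propensity $\mathrm{pGrowth} \cdot (\ln 2 / t_{\mathrm{div}}) \cdot
f(\mathrm{TP53})$; a cell divides the instant pGrowth reaches the
threshold $\theta$, and every species (pGrowth included) is split
Binomial$(n, 1/2)$ between the daughters. The TP53 gate is the
decreasing Hill function $f(x) = 1/(1 + (x/Q)^\beta)$ with $Q = 65$
molecules and $\beta = 7$: $f(0) = 1$, $f(Q) = 1/2$, $f \to 0$ at high
TP53, so cells with de-repressed TP53 stall. The Hill *form* is a
package decision (only the gate's role and its two constants are given
by the underlying study); the decreasing Hill with midpoint $Q$ is the
minimal reading. Likewise $\theta = 2\,\mathrm{pGrowth}_0$ with
$\mathrm{pGrowth}_0 = 100$ molecules at birth is a decision chosen so
that exponential pGrowth accumulation with a doubling criterion
reproduces the doubling time $t_{\mathrm{div}}$ (default 38 h, an
MDA-MB-231-like value) when $f = 1$; whether pGrowth itself should be
binomially partitioned is unstated, and partitioning it is the
consistent choice. All of these sit in one config surface
(`addGrowthModule`).

Simulation is an exact Gillespie algorithm over the whole population
(implemented in compiled code): the next event is drawn from the summed
propensity of all cells, the owning cell is chosen proportionally, and
division is processed immediately when triggered -- ties between a
division and any other event at the same instant resolve division-first
by construction. The population is capped (default 2000 cells; the
silencing experiments use smaller caps) by uniform random subsampling,
and the cumulative subsampling factor is folded back into the reported
cell counts, so viability readouts are unbiased. Runs are bitwise
reproducible for a fixed seed. The viability readout is the mean
corrected cell count over the trailing window (default the last 50 h),
and silencing experiments report it normalized to paired-seed control
runs, so the control is 1 by construction. Knock-out removes a gene's
production reactions and zeroes its initial count; knock-down scales
production by $1 - \mathrm{eff}$ (default efficiency 0.8, siRNA-like).

### Rate calibration

Expression targets (RPKM-scaled copy numbers) are met by choosing the
production constants. At the target state the flux balance is *linear*
in the vector of $k_p$ values -- each gene's production is $k_p$ times
known activator levels, and each source-consuming activation edge drains
its source proportionally to the target's $k_p$ -- so the calibrator
solves that linear system directly and then verifies the solution
against the ODE twin, applying damped multiplicative corrections only if
the verification drifts (it converges in one step on the shipped
networks; a naive per-gene multiplicative iteration is unstable here
precisely because of the consumption coupling). Infeasible targets
(requiring non-positive production) are a hard error. Calibration is
idempotent: a second pass changes rates below tolerance.

### The ODE twin and sensitivities

The twin integrates the deterministic mass-action rate equations of the
same reaction set (`deSolve::lsoda`) until the residual of the rate
equations is below tolerance, and errors out if no steady state is found
within the horizon. When the growth module is attached, division is
represented by a continuous dilution term $\mu X$ with $\mu = (\ln 2 /
t_{\mathrm{div}}) f(\mathrm{TP53})$ evaluated along the trajectory:
binomial partitioning halves per-cell counts once per generation, and
without the dilution term the twin would systematically overestimate the
stochastic per-cell means. Systems without growth have no dilution, so
textbook closed forms hold exactly (an isolated source/degradation gene
settles at $k_p / k_d$; a linear cascade matches its closed form to
integrator precision).

Parameter sensitivities are scaled central finite differences at the
steady state, $S(i, p) = (p / X_i)\, \Delta X_i / \Delta p$ with a 1%
default perturbation, summarized per parameter as the mean of
$|S(i, p)|$ over genes and ranked. For an isolated birth-death gene the
self-sensitivity of $k_d$ is $-1$ analytically, which anchors the
implementation; parameters of sink genes have zero off-target influence
by reachability, and the ranking is stable across perturbation sizes.

## Synthetic data: what it emulates and what it does not

All pipeline inputs can be generated with planted ground truth, so every
stage is testable without downloads.

`genScreen` emulates a kinome-scan-sized panel (41 drugs x 385 kinases
by default): binding is sparse (12% background bind probability, heavier
for planted targets at 25%, chosen so that roughly half the screen
responds under the OR rule -- both a realistic screen composition and one
in which the planted set is identifiable rather than shadowed by
alternative covers); affinities are log-normal around 100 nM. Noiseless
sensitivity follows a Boolean rule over the planted essential set
(OR/AND/weighted coverage), plus clipped Gaussian noise. `genSurface`
builds dose-response matrices whose margins follow exact 4PL curves and
whose combination cells sit at Bliss independence plus a planted excess,
so the expected Bliss score equals the planted value. `genNetwork`
provides a fixed nine-gene demo motif -- AURKB inhibiting TP53 directly,
a ZAK-to-p38-like branch (ZAK -> MAP2K3 -> MAPK14 -| TP53) as a second
TP53 sink, CSF1R supporting TP53 through a TGFB1 branch, and two
input-less bystanders -- whose degradation rates and expression targets
were fixed once, via the ODE twin, so that the qualitative silencing
phenotypes (double AURKB+ZAK silencing super-additively de-represses
TP53 and collapses growth; CSF1R co-silencing starves TP53 and rescues
growth) are structural properties of the motif. A random-network mode
samples signed edges with bounded in-degree.

What the generators deliberately do **not** emulate: the marginal
distributions of any real published screen, correlated off-target
binding between chemically similar drugs, dose-response deviations from
the 4PL shape, plate/batch effects, or the topology of a curated
signaling database. Passing the planted-truth experiments therefore
shows that the algorithms recover what they are defined to recover under
clean generative assumptions -- not that they would recover biology from
noisy real screens with model mismatch.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the recovery experiment
at 40 drugs x 20 kinases over 10 seeds, brute-force predictor
equivalence on 1000 random instances of up to 6 drugs and 5 kinases,
Bliss recovery over 200 noisy 8x8 surfaces, a single-cell birth-death
run of 40,000 h for moment checks, three 150 h population runs for the
SSA/ODE comparison, and silencing experiments of 10 runs x 250 h with 8
starting cells capped at 150 -- sizes at which every check is stable
under reseeding while the whole battery stays comfortably inside a
coffee break on one core. Larger populations or longer horizons change
none of the conclusions, only the Monte-Carlo error.

## Known limitations

* The subset search approximates the published sequential
  forward-floating selection generically; with screens whose LOO error
  surface is nearly flat, different tie-break conventions can select
  different (equally predictive) target sets.
* The predicted-synergy scale is a convention (HSA-on-predictions by
  default); absolute values are not comparable across conventions,
  only rankings.
* Bliss scoring inherits the margin-handling choice (fitted vs raw);
  both are exposed because published scores rarely state which was
  used.
* The growth model abstracts the cell cycle to a single exponential
  clock gated by one species; it cannot represent checkpoint dynamics,
  apoptosis as a distinct fate, or cell-cell interactions.
* The ODE twin's dilution term uses the instantaneous Hill gate; in
  regimes where TP53 fluctuations are large and strongly skewed the
  twin can deviate from stochastic means by more than the few percent
  seen on the shipped networks.
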