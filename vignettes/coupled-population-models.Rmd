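---
title: "Functional coupling, coupled encoding models and population decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional coupling, coupled encoding models and population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcoupling)
```

## The scientific question

Single neurons in visual cortex respond very differently to repeated
presentations of the same stimulus. This package asks how much of that
single-trial variability is explained by three candidate sources — the
visual stimulus, the animal's locomotion, and the coactivity of the
neuron's local *functional group* — and whether knowledge of local coupling
helps a downstream readout decode the stimulus. The analyses operate on
trial-structured population fluorescence recordings: a neurons × frames
matrix of per-neuron normalized traces, per-frame stimulus labels (twelve
drifting-grating directions plus grey), per-frame running speed, and
repeated identical stimulus blocks.

## Functional weights, lags and groups

The coupling between two neurons is measured, not fitted. For each block
(trial), the **functional weight** of a pair is the partial correlation
between the two trial traces, conditioned on three nuisance series: each
neuron's leave-one-out mean trace (its average response in all *other*
trials, which carries the stimulus-locked component) and the within-trial
population mean excluding the pair (which carries population-wide,
locomotion-driven coactivity). With `\(\Omega\)` the 5×5 correlation matrix
of these series (pair in positions 1 and 2),

$$\rho_{xy} = -\frac{(\Omega^{-1})_{12}}
  {\sqrt{(\Omega^{-1})_{11}\,(\Omega^{-1})_{22}}},$$

and the weight is the mean of `\(\rho_{xy}\)` across blocks. This is a
noise-correlation-like quantity: what remains after stimulus and global
state are conditioned away. `trial_partial_correlation()` implements the
precision-matrix contract and is tested against an independent
residual-regression oracle (regress each trace on the conditioning series,
correlate the residuals) to `1e-8`.

Temporal structure comes from the cross-correlogram of the pair's
block-mean traces over integer lags up to ±17 frames: the lag maximizing
the coactivity *magnitude* (the absolute normalized cross-correlation) is
the **functional lag**, its sign gives the edge direction, and lag 0 marks
a bidirectional edge. Taking the magnitude rather than the signed maximum
matters only for negatively coupled pairs: their correlogram attains its
signed *minimum* at the true lag, so a signed argmax would systematically
assign them an uninformative lag; for positively correlated pairs the two
rules coincide. Two tie rules are fixed (the field leaves them unstated):
among tied lags the smallest |lag| wins, and among tied ±|lag| the
positive lag wins. The **functional group** of a neuron is the set of
neurons with edges directed toward it; bidirectional edges place each
endpoint in the other's group. **Strong edges** are those whose weight
magnitude lies in the pooled top quartile, inclusive of ties at the 75th
percentile.

Numerical guards: the 5×5 correlation matrix gets a `1e-8` ridge when its
condition number exceeds `1e12` (near-duplicate conditioning series
otherwise explode the precision matrix); blocks with degenerate
conditioning sets are dropped from the trial average; a pair degenerate in
every block reports weight 0 with a flag.

## The encoding-model ladder

For neuron \(i\) with incoming lag-0 and lag-1 weight vectors
\(W_i^0, W_i^1\), the unrestricted linear model is

$$\hat r_i(t) = c + \beta_0\, W_i^{0\top} r(t) + \beta_1\, W_i^{1\top} r(t-1)
  + \Psi\, s(t) + \Gamma\, v(t),$$

with at most five free parameters: the coupling scalars are *features built
from measured weights*, so the coupling structure cannot be re-learned to
absorb stimulus or running mis-specification. The stimulus term `\(s(t)\)`
is either the average response (per-condition grand mean for tuned neurons,
the across-condition mean for untuned ones, zero on grey; grey frames stay
in the fit) or the block-averaged trace (framewise average across a split's
presentations, preserving within-presentation dynamics; grey frames are
excluded and a 50/50 presentation-balanced split is used so both halves
average over equal presentation counts). The running term is the rotary
encoder speed or, to allow nonlinear locomotion drive, the average
population response excluding the target neuron.

Restricted variants drop one term (stimulus-, run-, coupling-restricted),
keep one coupling lag (`lag0_only`, `lag1_only`), or split coupling by
weight sign pooling all lags as lag 0 (`positive_only`, `negative_only`).
Controls include an all-lag model (coupling features at every lag up to
17), a nonnegative variant (term coefficients constrained ≥ 0 — the
intercept stays free because it models baseline fluorescence — solved
exactly by active-set enumeration over the handful of terms), and
reciprocal (\(1/Y = X\beta\)) and cube (\(Y^3 = X\beta\)) links fit by
damped Gauss–Newton with linear predictors floored at `1e-6` in magnitude.
All models are fit by least squares on the training split (default 70/30
at block granularity, earliest blocks to train; a seeded random-block mode
is provided because the original analysis does not state whether its split
respected block order). The first frame of each block is excluded from
fitting since the lag-1 feature would cross the block boundary; lagged
features never cross blocks.

Comparison is by percent change in test-set MSE relative to the
unrestricted model, evaluated on identical frames, optionally restricted to
grating frames, running frames (speed > 0 by default, threshold
configurable), or the first second after each stimulus onset. Unconstrained
nested fits are asserted on every suite run to never beat the unrestricted
model on training MSE (the nesting property) — a violated assertion would
indicate a numerical defect, so it aborts the run.

## Permutation stress tests

Two nulls probe how much predictions depend on the precise strong-edge
structure. The **weights scheme** applies a uniform random permutation to
the (weight, lag) pairs of the strong edges jointly — topology preserved,
weights shuffled, direction following the permuted lag. The **edges
scheme** permutes the strong edges' terminal neurons, keeping each weight
and lag attached to its source, which rewires functional-group membership.
Because the functional graph is complete over pairs, a permuted terminal
list almost surely maps several strong edges onto pairs that already carry
an edge; these duplicates are allowed and their weights simply sum inside
the incoming-weight vectors (the coupling feature is a sum over incoming
edges, so this is the natural composition). Self-edges are repaired by
bounded random target swaps, which preserve the terminal-neuron multiset.
Whole-permutation rejection sampling on duplicate collisions is not viable
here: with \(K \approx 1200\) strong edges over 100 neurons the collision
probability is astronomically close to 1.

Without refitting, the original coefficients are kept and the change is
measured on *training* MSE (refitting would let the coefficients absorb
the shuffle); the summary is the median of per-permutation medians with the
IQR of medians. With refitting, coefficients are re-estimated per
permutation and test MSE is summarized as a grand median and IQR over all
neuron × permutation cells. Permutation \(k\) draws its permutation from
`seed + k`, so any single permutation is reproducible in isolation.

## Decoders

Both decoders are Bayesian MAP classifiers over the 13 conditions with a
uniform prior, decoding every frame by default (a test-only mode gives an
honest generalization readout). The **coupled decoder** models the
population response for candidate condition \(s\) as multivariate Gaussian
whose mean is the unrestricted-LM prediction with the stimulus term
evaluated at \(s\) (coupling and running terms use the observed data at
that frame — no iterative joint decoding) and whose covariance is the
training-frame covariance of the traces during \(s\). With up to a few
hundred neurons and only a few hundred frames per condition that covariance
needs regularization: a Ledoit–Wolf-style shrinkage toward the diagonal
with a data-driven intensity (forced fully diagonal when a condition has
fewer training frames than neurons) plus `1e-8` diagonal loading. The
original analysis is silent on covariance conditioning, so the shrinkage is
configurable down to none. The **uncoupled decoder** assumes conditional
independence: per-neuron condition means and variances (floored at `1e-6`),
with the likelihood factorizing over neurons. Posterior ties break toward
the lowest condition index (grey, then ascending direction). Grey is
treated as a candidate condition whose stimulus term is zero. In the limit
of a diagonal covariance and a stimulus-only LM the two decoders coincide,
which is asserted in the tests.

Performance is summarized by overall accuracy (chance is 1/13 ≈ 7.69%), a
row-normalized percent confusion matrix, and the plug-in mutual information
of the empirical joint of true and decoded labels, in bits (0·log 0 := 0;
bounded by log₂13 ≈ 3.7004).

## What the synthetic generator emulates

`simulate_population()` generates populations with *known* structure so
every estimator above can be validated against planted ground truth. The
latent drive of neuron \(i\) is baseline + direction-tuned response
(von-Mises-shaped, preferred directions on the 12-direction grid) +
running gain × speed + private Gaussian noise + the coupled drive of its
sources: lag-0 couplings are simultaneous and solved jointly via
\((I - A_0)^{-1}\), lag-1 couplings enter from the previous frame. The
drive is then convolved with a causal single-exponential calcium kernel
(initialized at steady state so constant drive yields constant
fluorescence) and per-neuron z-scored; zero-variance traces are flagged
and left centred rather than divided by zero. Running is a two-state
renewal process with positive speeds during bouts. If the planted lag-0
coupling approaches instability (spectral radius ≥ 0.95) all planted
weights are scaled down uniformly and written back into the returned
ground truth, so the recorded truth always matches the realized dynamics.

A deliberate design choice: the private noise enters the drive *inside*
the coupling recursion, not after the kernel. Trial-to-trial variability
that propagates through the planted edges is precisely the structure the
partial-correlation estimator measures; purely post-hoc observation noise
would be independent across neurons and carry no coupling signature, making
planted-structure recovery impossible in principle. An optional
post-kernel observation noise (`obs_noise_sd`, default 0) is still
available.

Default scale and conditions (chosen once as a realistic desk-scale
emulation of the study conditions): 100 neurons, 10 identical blocks of
900 frames at 30 Hz (12 presentations of 35 frames, each preceded by 40
grey frames — about 9,000 frames in total), calcium time constant 0.5 s
(a fast-end value for a slow indicator; slower kernels blur lag estimation
further), drive noise SD 1, planted edge density 0.03 over pairs with
weight magnitudes uniform on [0.12, 0.42], 80% positive, lag mass 0.7/0.3
on lags 0/1, 60% of neurons direction tuned with peak gain 0.4 and
concentration 4 (sharp, distinct tuning curves: enough per-condition
distinctness for the stimulus term to carry unique information, while
keeping total stimulus power in the block-mean traces low enough not to
swamp the coupling signature the lag estimator relies on), and zero
running gain by default so locomotion acts as a pure nuisance regressor.
Running bouts start at 0.2/s and last 1 s on average: frequent short
bouts give the irrelevant running regressor enough effectively
independent observations that it is not spuriously fit — with rare long
bouts the regressor has only a handful of independent values per split
and restricted-vs-unrestricted comparisons near 0% become dominated by
that overfitting noise. The presentation length is fixed within a
protocol so block-averaged traces align framewise without truncation.
Locomotion statistics and presentation durations are placeholders in the
underlying description, so all of them stay configurable.

What passing tests on these simulations do **not** show: real recordings
have slower, nonlinear indicator dynamics, non-Gaussian shared variability,
unequal block lengths, drift, and neuropil contamination; recovery rates
measured here are upper bounds for idealized conditions, not claims about
any particular dataset.

## Problem sizes used by the tests

The unit tests run on small populations (15–30 neurons, 2–4 short blocks).
The acceptance suite additionally runs the full default scale above once
and reuses it across checks: graph estimation, the model ladder, 200
permutations per scheme (scaled down from the study's 1000 to keep the
suite brisk; the statistic is a median over permutations and stabilizes
well before 200), and both decoders over all frames. The
`scripts/acceptance.R` entry point recomputes the same quantities from
scratch under a caller-supplied seed.

## Known limitations

- The correlogram direction estimate for genuine lag-1 edges is noisy when
  the target neuron's own stimulus response dominates its mean trace;
  recovery rates are reported per run rather than assumed.
- The ordering of the stimulus-restricted versus run-restricted medians is
  a contrast between two numbers that are both fractions of a percent once
  coupling is conditioned on; on some simulated populations the ordering
  can flip within that noise band even though the coupling-restricted
  contrast stays one to two orders of magnitude larger.
- The reciprocal link on z-scored (sign-changing) responses is intrinsically
  ill-posed near zero; the documented `1e-6` floor stabilizes it, so its
  error magnitudes are not comparable to an unstabilized implementation.
- `summarize_graph()` reports single-graph summaries; the group-size-vs-
  population-size slopes need several graphs and live in
  `group_size_scaling()`.
- Tuning classification ships as a simple Kruskal–Wallis surrogate
  (`classify_tuning()`); synthetic datasets carry ground-truth flags.

## A minimal run

```{r, eval = FALSE}
sim <- simulate_default_population(n_neurons = 40, n_blocks = 6, seed = 1)
graph <- build_functional_graph(sim$dataset)
suite <- run_model_suite(sim$dataset, graph)
suite$summaries

perm <- permutation_mse_change(sim$dataset, graph, suite, "weights",
                               n_permutations = 100, seed = 2)
perm$summaries

coupled <- fit_coupled_decoder(sim$dataset, suite, graph)
uncoupled <- fit_uncoupled_decoder(sim$dataset, suite$split$train)
evaluate_decoding(decode_coupled(coupled, sim$dataset, graph))$accuracy
evaluate_decoding(decode_map(uncoupled, sim$dataset))$accuracy
```
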