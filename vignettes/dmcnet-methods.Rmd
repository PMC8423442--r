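---
title: "Methods: synthetic DMC data, selectivity statistics, and two-module networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic DMC data, selectivity statistics, and two-module networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

dmcnet studies how sequential category decisions -- deciding whether a
test stimulus belongs to the same category as a remembered sample --
could be computed across a parietal-like sensory stage and a
prefrontal-like decision stage. It provides three layers: a synthetic
delayed match-to-category (DMC) data generator with known ground
truth, the single-unit and population statistics used to characterize
match/nonmatch (M/NM) and category coding, and trainable two-module
excitatory/inhibitory recurrent networks with in-silico inactivation
experiments. This vignette documents the modelling choices, defaults,
and limitations.

## The DMC task and the synthetic generator

A trial presents a 650 ms sample motion stimulus after 500 ms of
fixation, a 1000 ms delay, and a 650 ms test stimulus; if the test's
category matches the sample's the subject releases a lever during the
test period, otherwise it holds through a 150 ms second delay and
releases on the second test (always a match). Six motion directions
(15, 75, 135, 195, 255, 315 degrees) are split by a boundary oriented
at 45 degrees, so 75/135/195 form one category and 255/315/15 the
other. `dmc_task()` encodes this; `enumerate_conditions()` yields the
36 sample-by-test direction combinations and 4 category conjunctions.

`generate_trials()` balances conditions by round-robin assignment
(remainder random), draws outcomes from per-trial error rates, and
draws reaction times from a normal truncated to [50, 350] ms after
test onset (defaults 250 +/- 15 ms, in the range of trained macaques).
The nonmatch error rate is a free parameter (default 0.02) because
subjects make very few errors of that type and no precise value is
established.

`simulate_population()` draws inhomogeneous Poisson spikes on a 1 ms
grid from the rectified sum of tuned components declared in a
`tuning_spec()`: baseline, sample-category gain, test-category gain,
M/NM gain, a single-conjunction interaction gain, and a motor ramp
locked to the lever release. Components switch on at a per-component
latency with an exponential rise (time constant 25 ms) -- a simple,
controllable model; real onset dynamics are richer. Two choices
matter downstream:

* **Decision-linked components follow the choice.** On simulated
  error trials the M/NM and motor components follow the erroneous
  report while sensory components follow the stimulus. This gives the
  error-trial ROC analysis a recoverable signal, as it has in real
  decision-linked neurons.
* **Rectification after summation.** Negative gains are allowed;
  the summed rate is clipped at zero before spikes are drawn.

The generator emulates trial structure, tuning classes, Poisson
variability, and reaction-time coupling. It does **not** emulate
correlated noise between units, non-Poisson spiking statistics,
adaptation, or eye-position effects, so passing tests demonstrate
correctness of the statistics, not robustness to every property of
real recordings. The surrogate LFP (`simulate_lfp()`) is a
phenomenological channel -- 1/f background, causal evoked deflections
(alpha functions, so no energy precedes the stimulus), a
condition-dependent test-period deflection, and an injected 60 Hz
line component for the band-stop stage -- not a biophysical model.

## Selectivity statistics

All sliding-window analyses use half-open windows `[t, t + width)`
relative to an alignment event, timestamped at their centers; the
default grid is 50 ms width, 5 ms step. PSTHs are smoothed with a
20 ms Gaussian; normalized traces divide by the unit's maximum rate.

**Unbiased FEV.** For a one-way ANOVA decomposition with `k` levels,

  FEV = (SS_factor - (k - 1) MSE) / (SS_total + MSE).

The correction makes the statistic approximately mean-zero under the
null, so units with different firing rates are comparable. It is
returned as 0 when `SS_total + MSE = 0` (constant input). The two-way
variant (`fev_twoway()`, sample and test category as factors) uses
type-II sums of squares -- identical to the sequential decomposition
on balanced designs, well-defined on the nearly balanced designs the
generator produces -- with the shared two-way MSE in each term's
correction. How many conditions the interaction correction should
count is not established; the default corrects with `(4 - 1) * MSE`
(four conjunction conditions) and `interaction_k = 2` switches to
`1 * MSE`.

**ROC.** `auroc(a, b)` is the Mann-Whitney statistic scaled to
[0, 1]; ties contribute 0.5, so identical distributions give exactly
0.5. The rCTI combines pairwise `|ROC - 0.5|` terms across the six
directions into between-category minus within-category
discriminability, with weight 2 on the four 180-degrees-apart pairs
and normalization by 8. Binary category-like tuning drives it toward
+0.5; note that a single unit with smooth direction tuning can have a
strongly non-zero rCTI (the index balances angular separations only
on average over preferred directions).

**Latency.** M/NM latency is the start of the first run of at least
two consecutive windows (non-overlapping 20 ms grid) with significant
M/NM selectivity (one-way ANOVA, p < 0.05) whose sign agrees with the
unit's global preference over 50-350 ms after test onset; transient
opposite-signed episodes never trigger it. Undefined latency is a
valid outcome and such units are excluded from latency comparisons.

**Screening and rate equating.** Units enter analysis when their peak
condition-averaged rate (fixation onset to 350 ms after test onset)
is at least 5 spikes/s and at least one task factor modulates them
(p < 0.01) in one of four epochs: sample, earlier delay, later delay
(split at the delay midpoint; the epochs have no established
boundary), test. `decimate_spikes()` equates firing rates between
groups by removing `round((1 - R) x count)` spikes per trial,
rounding half away from zero -- the printed rule specifies rounding
but not the tie convention.

**Error-trial ROC.** Error-match trials are compared with balanced
random subsamples of correct-match trials (100 repeats, averaged),
oriented by the unit's preference so values above 0.5 always mean
"error activity moved toward the nonmatch-like response".

## Pseudo-population decoding

Units are pooled as if simultaneous. Each repeat splits every unit's
trials 66/34 into training and testing pools, resamples 120 training
and 60 testing pseudotrials with replacement -- balanced over the two
classes and stratified by motion direction within class (a switch
disables stratification) -- and fits a linear maximum-margin
classifier per window. Three conventions are not established anywhere
and are fixed here: regularization constant 1.0, linear kernel, and
per-unit z-scoring computed on the training pseudotrials only.
Significance is the two-sided bootstrap percentile of the repeat
distribution against chance. The cross-condition variant trains the
test-category classifier within one sample-category context and
evaluates in the other (both directions averaged): above-chance
transfer indicates a context-invariant (additive) code, below-chance
a context-reversing (match/nonmatch-like, XOR) code. Decoding minima
(10 training and 5 testing trials per direction) are enforced when
the pseudo-population is built.

## Nonlinearity index and integration classes

For test-period rates keyed by the four sample-by-test conjunctions,

  NLI = | FEV(S1T1 vs S1T2) - FEV(S2T1 vs S2T2) |,

the absolute difference between within-context test-category FEVs,
computed in a 50-150 ms window after test onset (the window before
the subjects' reactions; the full timecourse is also available).
Purely additive mixing and pure M/NM (XOR) coding both give NLI = 0;
test-category selectivity confined to one context gives values toward
1. A normalized variant divides by the population mean test-category
FEV so populations with different overall selectivity can be
compared; normalization is a positive constant within a population,
so it never reorders units. Both raw and normalized values are
reported because published area comparisons are ambiguous about which
entered the test.

Integration classes come from the two-way ANOVA on 0-250 ms
test-period activity at p < 0.01: NIN (both mains + interaction), LIN
(both mains, no interaction), NMN (a single effect; an
interaction-only unit is a pure M/NM cell, labeled `NMN_mnm`). A unit
with one main effect plus an interaction is labeled by its main
effect, matching the definition of non-mixed cells by their single
significant factor.

## The two-module recurrent network

Architecture: 24 motion-tuned inputs (von Mises tuning, concentration
2, peak activity 4), 100 hidden units (80 excitatory, 20 inhibitory),
3 outputs (fixation, match, nonmatch). Half the excitatory and half
the inhibitory units form an input-proximal "LIP" module, the rest an
output-proximal "PFC" module. Structural constraints (built once,
enforced at every step because every raw weight passes through
`ReLU x mask x Dale sign`): no self-connections, no cross-module
inhibition, at most 50% of possible cross-module excitatory entries
in each direction, inputs onto at most half the LIP-module units and
none in PFC, outputs from at most half the PFC-module excitatory
units and none from LIP or from inhibitory units.

Dynamics (20 ms steps, membrane time constant 100 ms, so
`a = 0.2`):

  r(t+1) = (1 - a) r(t) + a ReLU(W_in u(t) + W_rec (s(t)) + b + noise)

with per-step Gaussian noise of SD `0.1 * sqrt(2/a)` and short-term
synaptic plasticity: each presynaptic unit carries two-variable
(u, x) dynamics, alternating facilitating (U = 0.15, tau_u = 1500 ms,
tau_x = 200 ms) and depressing (U = 0.45, tau_u = 200 ms, tau_x =
1500 ms) parameters, and the effective presynaptic signal is
`u * x * r`. These constants and the dynamics follow the established
training framework for excitatory/inhibitory rate networks on
cognitive tasks; STP can be disabled by `stp = FALSE`.

Trials mirror the monkey task -- same directions, boundary, and epoch
durations (rounded to the 20 ms integration grid) -- and end with the
first test period, where the decision is scored; the second delay and
second test add no training signal. The loss is (1) the masked
categorical cross-entropy between the softmax outputs and the target
class (fixation until test onset, match/nonmatch during the test),
(2) a metabolic rate cost (2e-2 times mean squared activity), and
(3) a wiring cost (1e-2 times mean squared effective weight). Two
mask conventions matter: 40 ms after each stimulus onset is excluded
(no penalty for transmission delay), and test-period steps carry
weight 5 -- the decision report is the scored behavior, and with
uniform weights the fixation epochs (about three quarters of the
trial) dominate the gradient and networks plateau at chance M/NM
performance. Training uses Adam at learning rate 0.01, batch size
256, global gradient-norm clipping at 0.1, and initial weights drawn
from a gamma distribution (shape 0.1, scale 1.0) times the masks;
input weights are fixed after initialization. Training stops when
mean behavioral accuracy over the last 50 batches exceeds 95% (the
convergence criterion), typically within 150-400 batches. The
backward pass is analytic (backpropagation through time through the
STP variables and clip operations, implemented in compiled code) and
is verified against finite differences in the test suite.

Accuracy scores a trial as correct when the modal output argmax over
scored test-period steps is the required class and the modal argmax
over scored pre-test steps is fixation.

## In-silico experiments

Analyses mirror the spiking ones: unit screening during the test
period (peak condition-averaged activity >= 0.001 and one task factor
at p < 0.01), per-timestep FEV timecourses, and the NLI on a
test-period window expressed in timesteps. The RNN latency rule is
different from the spiking one by construction: a timecourse must
exceed its own pre-test baseline mean by 3 SDs (baseline over the
first 100 timesteps) for a run longer than 10 timesteps.

Graded inactivation multiplies targeted PFC-module units' activities
by levels from 1 to 0 during the test period (parameters frozen);
units are ranked by NLI and split into equal-sized more/less
nonlinear halves (the median unit is dropped when the count is odd),
optionally excluding direct output projectors. Feedback ablation
multiplies the PFC-to-LIP entries of the effective recurrent matrix
by the level during the test period and measures the LIP-module M/NM
FEV per timestep. All levels share one evaluation seed, so the
level-1 row is bit-identical to baseline.

Significance of a feedback effect at a timestep: correlate the middle
six levels with the six observed selectivities, enumerate all 720
orderings, weight each permutation's correlation by its similarity to
the true ordering -- similarity is not established; the default is
the Spearman correlation of the orderings mapped to [0, 1] via
`(1 + rho)/2`, with Kendall available -- Fisher z-transform the
correlations, and compute the upper-tail normal p-value of the true
(transformed) correlation under the weighted null. The z-transform is
essential twice over: an empirical rank among 720 permutations cannot
fall below about 1/360, and the raw-correlation null for six values
has an SD near `1/sqrt(5)` whatever the data, capping upper-tail
probabilities around 1e-2 -- while the flagging criterion (p < 0.001
for at least 5 consecutive test-period timesteps) requires finer
resolution. A network is flagged when that criterion is met.

## Problem sizes and determinism

The bundled analyses and tests run on desk-scale problems chosen to
exercise every code path with stable statistics: populations of a few
dozen units and 240-1500 trials; one full-size (100-unit) network
trained per the convergence criterion; five reduced networks
(60 units, shortened epochs: 200/300/400/300 ms) for cross-network
properties (module encoding asymmetry, inactivation ordering). The
published experiment trained 50 full networks; the test-category and
match/nonmatch module asymmetries and the inactivation ordering
reproduce at the reduced scale, while the sample-category module
asymmetry -- the weakest module effect at full scale -- reverses in
reduced networks (their output-proximal module ends up holding more
of the sample memory), so conclusions about that effect should be
drawn from full-size networks only. The full architecture remains
the default for single-network work. Every
stochastic stage takes an integer seed and restores the caller's RNG
state, so pipelines are bit-reproducible end to end; with `noise = 0`
the network dynamics are deterministic.

## Known limitations

* Poisson spiking without cross-unit noise correlations makes
  pseudo-population decoding optimistic relative to simultaneous
  recordings.
* The two-way FEV's type-II sums of squares assume near-balanced
  designs; heavily unbalanced data would need cell-mean weighting
  that is not implemented.
* The RNN omits the second test period, so it cannot model
  behavior or activity after a nonmatch decision is reported.
* Serialization uses CSV/JSON; spike data round-trips exactly at
  the printed precision but very large populations would be better
  served by a binary container.
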