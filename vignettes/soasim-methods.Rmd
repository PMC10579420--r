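---
title: "Modeling the sense of agency and its breakdown with simulated lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the sense of agency and its breakdown with simulated lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soasim)
```

## The scientific question

The sense of agency (SoA) — the feeling of causing and controlling one's own
actions and their external consequences — is systematically altered in
schizophrenia, and in a bidirectional way: paranoid-type patients tend to
report agency too often (excessive SoA), while patients with predominant
negative symptoms report it too rarely (diminished SoA). A long-standing
hypothesis attributes this to temporal delays in the sensory-motor
prediction signals (efference copy) that normally let the brain compare
predicted and actual consequences of an action.

`soasim` packages a computational test of that hypothesis. It trains small
continuous-time recurrent neural networks (CTRNNs) to reproduce
healthy-control behavior on an agency-attribution task, then perturbs the
trained networks at run time — random one-step temporal delays in different
signal pathways, multiplicative state noise, or a reduced activation gain —
and asks which perturbation reproduces the bidirectional
schizophrenia-pattern change in agency judgments.

## The behavioral task and its synthetic stand-in

In the agency-attribution task an on-screen piece rises at constant speed;
the participant presses a button on hearing a beep, and the piece jumps
upward after a latency of 0–1000 ms (in 100 ms steps) linked to the press.
After each trial the participant judges "yes/no: did I cause the jump?".
Besides these 11 action-linked conditions there are three
event-prior-to-action (EPA) conditions in which the jump is time-locked to
the beep (−100, 0, +100 ms), not the press. Every condition is repeated 10
times, giving 140 trials per subject.

The original human data are not publicly deposited, so the package starts
from a synthetic-cohort generator that is itself first-class, tested code.
Each synthetic subject is a four-parameter logistic psychometric curve over
the jumping latency

$$p(\mathrm{yes} \mid L) \;=\; \ell + (u - \ell)\,
  \sigma\!\big(-k\,(L - L_{0.5})\big),$$

with lower/upper asymptotes $\ell, u$, steepness $k$ (per ms) and
inflection latency $L_{0.5}$; EPA conditions get constant per-condition
yes-probabilities; reaction times are normal, truncated at 1 ms by
rejection (negative RTs are physically impossible). The logistic is the
simplest monotone family with an explicit inflection point, which is the
feature the training stage is asked to recover. Cohort-level defaults
(inflection 300–700 ms, steepness 0.008–0.02 /ms, asymptotes near 1 and 0,
EPA yes-probability around 0.2, RT mean 250–450 ms with SD 30–80 ms) are
chosen so the cohort answers "yes" almost always at 0–200 ms latencies and
almost never at 800–1000 ms, the signature healthy pattern. All of them are
configuration, not estimates of any real cohort: no HC EPA rates are
published for this task, so the 0.2 default in particular is a documented
placeholder.

Trials become sensorimotor sequences on a 100 ms grid (latency conditions
are exact multiples of 100 ms, and the lesion model below applies delays in
whole steps, so a finer grid would buy nothing). A trial is 22 steps
(2.2 s): channel values live in [0.1, 0.9]; the beep (step 3) and button
press (beep + RT) are single-step 0.9 pulses; the object position ramps
linearly from 0.1 to 0.9 with an extra one-step increment (+0.2 before
renormalization) at the jump; the judgment target starts neutral at 0.5 and
ramps linearly to 0.9 (yes) or 0.1 (no). The window length deserves a
note: it is the shortest that accommodates the beep, the reaction-time
tail and a 1000 ms latency, so the judgment is read out soon after the
jump, while the output is still in transit — as when a subject answers
shortly after seeing the outcome. With a much longer settling window the
judgment output saturates so deeply that run-time perturbations can no
longer move it, and the delay/noise lesions lose all effect; the
trade-off this buys is discussed under limitations. How, or whether, the jump
discontinuity should appear in the position channel is not fixed by the
task description; the one-step increment is this package's choice and is
configurable. RTs round to the nearest step with ties up.

## The network

The model is a conventional firing-rate CTRNN: three input units (beep,
button, position), ten fully recurrent context units (every context unit
projects to every context unit, including itself), and four output units
(one-step predictions of the three inputs, plus the SoA judgment). Inputs
and outputs connect only via the context units. Context membrane potentials
leak with time constant $\tau = 10$ steps,

$$u_i(t) = \Big(1 - \tfrac{1}{\tau}\Big) u_i(t-1)
  + \tfrac{1}{\tau}\Big[\textstyle\sum_j w^{cx}_{ij} x_j(t)
  + \sum_k w^{cc}_{ik} c_k(t-1)\Big],
  \qquad c_i(t) = f(u_i(t)),$$

with the gained sigmoid $f(u) = 1/(1 + e^{-a u})$, $a = 1$ for the healthy
model. Outputs read the context activations of the previous step,
$o_i(t) = f\big(\sum_j w^{oc}_{ij} c_j(t-1)\big)$. Histories before the
first step are fixed (membrane potentials 0, activations $f(0) = 0.5$,
inputs at the 0.1 baseline) so that delayed reads at the start of a
sequence are well defined. All dynamics run in 64-bit floating point; the
compiled forward pass is checked against a naive R loop implementation to
1e−12 in the test suite.

A trial's judgment is decoded from the final step of the judgment output:
strictly above 0.5 counts as "yes". 0.5 is the channel's neutral starting
value; the strict inequality makes the tie case explicit.

## Training

Each synthetic subject's 140 sequences train 10 replicate networks
("M-subjects") end to end by backpropagation through time, in full batch
(one update per pass over all sequences), minimizing the mean per-step
squared error of the four output channels. The judgment channel carries
loss weight 3 (the three sensory channels weight 1): the behavioral readout
is one channel out of four and a single readout step per trial, and with
uniform weights it is dominated by the sensory-prediction error. Weights
initialize uniformly in ±0.1.

The default optimizer is iRprop− — per-weight sign-based step adaptation
(steps multiplied by 1.2 on gradient-sign agreement, halved and the update
skipped on a flip, clipped to [1e−8, 1]) — with 12,000 epochs. Plain
gradient descent with momentum and full-batch Adam are available through
the same configuration object; in this package's experiments on the default
task both needed several times more epochs to reach the same reproduction
quality, which is why the signed method is the default. The BPTT gradient
is verified against central finite differences (relative error below 1e−6)
in the test suite.

Training is intentionally pushed into a mild interpolation regime: at
intermediate latencies and in EPA conditions the same stimulus condition
carries both yes and no labels, and a deterministic network can only
reproduce intermediate yes rates by letting its decision boundary interleave
with the reaction-time variation. The over-learning check (Mann–Whitney U
between cohort training and generalization errors, expected non-significant)
guards the other side of this trade-off.

After training, each M-subject runs a reproduction test on 100 freshly
sampled sequences per condition (1400 sequences, RTs resampled from the
subject's RT distribution). The generalization error is the RMSE between
the model's and the subject's empirical 14-condition yes-rate curves;
M-subjects above the pass threshold are excluded from lesion experiments
and logged. The default threshold is 0.2, and its size is a statistical
argument, not a tuning knob: the empirical curve it is compared against is
itself a binomial sample (10 repetitions per condition), so even a perfect
model of the generating curve scores a median RMSE of 0.10 (99th
percentile 0.17) against it; on top of that, judgments are read through a
100 ms event grid from a deterministic network, so per-condition yes rates
can only take a few values per subject (mixtures over the 2–3 reachable
press steps), adding roughly another 0.1 in quadrature. Honest
reproductions therefore cluster around 0.15–0.18, and a gate at 0.2 keeps
them while still rejecting degenerate fits. The cohort-level curve
averages over replicates and subjects and is much smoother than any
single model's.

## The simulated lesions

All lesions act at run time only; weights are never modified.

* **Temporal delay in context (the hypothesis):** the recurrent read of
  each context unit uses $c_k(t-1-\Delta_i)$, with $\Delta_i \in \{0, 1\}$
  resampled independently per receiving unit per step
  ($\Pr[\Delta = 1] = 0.5$ by default). The published description does not
  disambiguate whether the delay varies per source unit, per receiving
  unit, or per pair, nor the schedule of the "random change over time"; per
  receiving unit with i.i.d. per-step resampling is the reading adopted
  here, and both the probability and the schedule granularity are
  configurable.
* **Random noise (control):** every membrane potential is multiplied by
  $(1 + \eta)$, $\eta$ zero-mean uniform on ±0.01 by default ("level 0.01"
  read as an amplitude; a Gaussian with SD 0.01 is available since the
  distribution is not specified). Resampled per unit per step; the
  perturbed potential is the state that carries to the next step.
* **Temporal delay in output (control):** only the judgment output unit
  reads $c_j(t-1-\Delta)$, one $\Delta$ per step.
* **Temporal delay in input (control):** each input channel is read as
  $x_j(t-\Delta_j)$, per channel per step.
* **Reduced gain (supplementary probe):** the sigmoid gain $a$ is lowered
  (0.99, 0.9 or 0.5) everywhere, flattening unit responses — a
  complementary way to damp the accumulation of context activity.

Lesion randomness runs on its own seeded stream, independent of the
behavior and training streams, so a lesion experiment is reproducible given
a trained model.

## Evaluation

Yes-rate curves are summarized by their short-window (0–200 ms) and
long-window (800–1000 ms) means, the two intervals where the clinical
groups separate most clearly. Cohorts of window averages become normalized
11-bin histograms on [0, 1] (values on a bin edge go to the upper bin, 1.0
to the last; the published figures do not state their binning). Two
histogram distances are reported per comparison: the mean squared error
between bin probabilities, and the Kullback–Leibler divergence
$\mathrm{KL}(P\|Q)$ with the reference distribution as $P$ and the model
distribution as $Q$, after adding 1e−6 to every bin and renormalizing so
empty bins are defined. Short- and long-window values are averaged into one
number per index, since a single number per lesion is what the original
analysis prints.

Each lesioned M-subject is classified by its windowed change score

$$Y = \tfrac{1}{3} \sum_{j} \big(x^{\mathrm{lesioned}}_j
  - x^{\mathrm{healthy}}_j\big) \times 10,$$

summed over the three conditions of a window, with rates put on a
count-equivalent 0–10 scale (the behavioral repetition count) so that the
published ±2 thresholds correspond to a 0.2 mean rate change — on raw
rates those thresholds would be unreachable, so the scale convention is a
documented package choice, and both scale and thresholds are configurable.
`Y_long > 2` labels an M-subject excessive, `Y_short < −2` diminished,
both at once the schizophrenia pattern.

Because no real patient data ship with the package, distribution distances
are computed against a synthetic mixed reference cohort (30 paranoid-type
curves with elevated long-latency and EPA yes rates; 20 negative-symptom
curves with reduced short-latency yes rates). These reference curves are
qualitative stand-ins with the right signatures, not clinical ground truth,
and the headline distances published for the real patient distribution
(MSE 0.0042, KL 0.0287) are therefore out of reach by design; what the
package tests is the *ranking* — the recurrent-delay lesion should sit
closer to the bidirectional reference than the noise and input-delay
lesions, which collapse judgments toward chance.

Functional involvement of the hidden units is measured on the healthy
models: each context unit's activation at the step immediately before the
jump is compared between yes- and no-judged action-linked trials
(two-sided Mann–Whitney U, α = 0.05) and rank-correlated with the latency
condition (Spearman, α = 0.01), without multiple-testing correction —
deliberately per-unit α, matching how the distributed-coding counts are
reported in the literature this reproduces. Near-ceiling counts
(≈ 9.5 of 10 units on both tests) indicate distributed rather than
localized coding.

## Problem sizes and numerical choices

The full study configuration is 17 subjects × 10 replicates = 170
M-subjects with 1400-sequence test sets. The package's own acceptance
script and test suite run scaled-down versions of the same pipeline — about
a dozen M-subjects with full 1400-sequence test sets for the
window-average and unit-correlation summaries, and a 50-M-subject cohort
with reduced test sets for the classification and distance-ranking
analyses; these sizes were chosen as the smallest cohorts at which the
group-level statistics are stable. Ties in the judgment decode (output
exactly 0.5) count as "no"; Mann–Whitney tests use the tie-corrected
normal approximation, with p = 1 returned for degenerate all-tied inputs
rather than an error.

## Known limitations

* Learning across trials is deliberately ignored (batch training), as is
  any uncertainty estimation of sensory inputs; both are known directions
  in which richer models differ.
* Delays come in whole 100 ms steps, so the lesion's effect size cannot be
  fine-tuned; this granularity is inherited from the modeled design.
* The synthetic reference cohort makes the distance *ranking* meaningful,
  not the absolute MSE/KL values.
* The multiplicative membrane noise at its default level 0.01 barely moves
  the trained networks' judgments (short-window yes rates stay near 1,
  long-window near 0): their attractors are robust at that amplitude, and
  randomized judgments appear only at levels an order of magnitude larger.
  A network regime that is simultaneously noise-fragile in its dynamics
  and settled at readout — which would also make a one-step delay on the
  judgment output's read exactly invisible — is not reached by training on
  these synthetic cohorts; with the short readout window the output delay
  flips a small number of borderline judgments instead of none. Both
  departures from the modeled findings are deliberate subjects of the
  acceptance suite rather than hidden.
* The per-subject psychometric curves of the generator are stationary and
  logistic by construction; real curves need not be either, so passing
  parameter-recovery tests here demonstrates the pipeline, not clinical
  validity.
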