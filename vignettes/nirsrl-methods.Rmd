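---
title: "Decoding hemodynamic desirability signals and learning from a noisy reward channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hemodynamic desirability signals and learning from a noisy reward channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsrl)
```

## Overview

`nirsrl` implements a complete in-silico version of a brain-machine
interface experiment built around two linked questions:

1. Can the *desirability* of a trial outcome (reward vs penalty) be decoded
   from frontal-lobe hemodynamics measured with dual-wavelength near-infrared
   spectroscopy (NIRS), one trial at a time?
2. Can a reinforcement-learning agent still solve a motor task when its only
   reward feedback is such a decoder - i.e. a binary reward channel that is
   wrong on a substantial fraction of trials?

Raw animal recordings for this paradigm are not publicly available, so the
package ships a synthetic session generator with known ground truth. The
pipeline is: simulate dual-wavelength optical density -> recover hemoglobin
concentration changes via the modified Beer-Lambert law -> peri-event
statistics and a single-trial SVM decoder -> feed the decoder's accuracy
into a tabular SARSA($\lambda$) agent on a 7x7 rake-and-pellet gridworld.

## The synthetic session generator

`generate_session()` emulates a cued conditioning protocol: a 10 s
pre-cue baseline, a visual cue whose color predicts the outcome, an 8 s
cursor travel (16 steps of 0.5 s), outcome delivery, a 15 s post-outcome
window, and an exponential inter-trial interval with mean 20 s (truncated
at 5 s). An uncued mode delivers outcomes at pseudo-Poisson times with
mean interval 60 s and a hard 40 s minimum. Event times are snapped to the
6 Hz sampling grid so that peri-event extraction is exact.

Hemodynamic responses are difference-of-gamma kernels per outcome class
and hemoglobin species (`hrf_params()`). The source study reports only
qualitative shapes, so the amplitudes and latencies are free parameters of
the generator; the defaults were chosen once to encode the reported sign
pattern at physiologically plausible micromolar magnitudes:

* oxyhemoglobin (HbO) rises ~1 uM above baseline after rewards but not
  after penalties, with a deeper initial dip for penalties;
* deoxyhemoglobin (HbD) dips similarly for both classes over the first
  seconds, but returns to baseline much more slowly after penalties
  (`return_tau_s` 10 s vs 3.5 s);
* a small anticipatory ramp develops between cue and outcome in both
  species, because the cue color already predicts the outcome.

`return_tau_s` governs the recovery timescale of the terminal phase of the
kernel - the peak when one is present, otherwise the dip itself.

Noise (`noise_params()`) has two structurally different parts. White
detector noise is independent per channel and wavelength. The
physiological components - random-walk drift, cardiac (2 Hz), respiratory
(0.6 Hz) and Meyer (0.1 Hz) oscillations - are *systemic*: one realization
is shared by all live channels, as vascular signals are in real
recordings. This matters downstream: channel averaging suppresses detector
noise by $\sqrt{n_\text{channels}}$ but leaves systemic noise untouched,
which is exactly what limits single-trial decoding. A multiplicative
per-trial amplitude jitter (`trial_amp_sd = 0.35`) models the large
trial-to-trial variability of hemodynamic responses; without it synthetic
decoding saturates at 100%, which no single-trial NIRS decoder achieves in
practice. With the defaults, jackknife decoding accuracy lands in the
0.8-0.9 band on 120-trial sessions - deliberately in the regime where the
reward channel is informative but substantially noisy.

What the generator does *not* emulate: photon transport and partial-volume
effects, probe geometry, raw intensity counts (it emits optical density
directly), aliased cardiac harmonics, or motion artifacts beyond a simple
broadband burst on tagged trials. Passing tests on synthetic data
therefore validate the *pipeline*, not the biological effect size.

## Preprocessing

`process_session()` mirrors standard fNIRS practice:

* 0.01-1 Hz zero-phase Butterworth band-pass (`bandpass()`; order 2 per
  band edge, i.e. a 4th-order band-pass, applied forward-backward).
* Channel quality control (`snr_reject()`): SNR is defined as spectral
  power in 0.01-1 Hz over power above 1 Hz, per wavelength, on the raw
  series; a channel is dropped when either wavelength falls below the
  threshold (default 2). White-noise-only channels sit near 0.5 on this
  metric and are rejected; live channels under the default generator sit
  near 10.
* Per-trial baseline referencing (`baseline_reference()`): optical density
  minus its mean over the 10 s pre-cue window, in the log (OD) domain.
* Chromophore inversion (`mbll_invert()`): the 2x2 extinction-coefficient
  matrix maps OD changes at 760/850 nm to (HbD, HbO) concentration changes
  assuming a 1 cm path length. Default coefficients are from the Prahl
  spectra compilation and are configurable; all validation uses round-trip
  identities rather than absolute values, so the conclusions do not hinge
  on a particular tabulation.
* Unweighted channel averaging (`average_channels()`), with total
  hemoglobin defined as the sum of the species.

Two ordering decisions were genuinely open. Filtering is applied before
per-trial baselining (filtering a short baselined segment would be
dominated by edge transients). And because the 0.01 Hz high-pass has a
~100 s time constant, the band-pass necessarily attenuates the slow
hemodynamic waveform itself by roughly 10% in relative L2 norm; the exact
forward/inverse identity of the chain is therefore validated with the
filter disabled (`filter = FALSE`), where it holds to ~1e-12, while the
filtered chain is validated for shape preservation.

## Peri-event statistics

`extract_peri_event()` cuts cue-aligned windows (default cue onset to
15 s post outcome; at 6 Hz a 23 s window has exactly 139 samples) and
`group_stats()` computes per-timestep class means, SEMs and Welch's
unequal-variance t-test, flagging timesteps at $\alpha = 0.05$ per
timestep with no multiple-testing correction by default (a Bonferroni
option exists). The same grouping machinery serves movement-tagged trials
via `group_by = "tag"`.

## Single-trial decoding

`build_features()` concatenates the HbO and/or HbD waveforms from cue
onset to $\tau$ seconds past the outcome into one row per trial.
`jackknife_cv()` evaluates a support-vector machine by 100 rounds of
hold-one-trial-out: each round samples one trial uniformly (with
replacement across rounds), trains on the rest, and classifies the
held-out trial. Defaults: linear kernel, C = 1, unstandardized features
(per-trial baselining already centers them; z-scoring each feature
destroys the amplitude information carried across timesteps). The
headline metric is balanced accuracy - the mean of the per-class correct
rates - which is also the quantity handed to the reward channel.

Two small-sample properties of this estimator matter for interpreting the
tests. First, holding out one trial of a balanced design leaves its class
a minority in training, which biases any single split pessimistically;
with hundreds of trials (as in the real protocol) the bias is negligible,
so the package's decoding checks run on 120-trial sessions. Second,
because slow systemic noise is shared between temporally adjacent trials,
accuracy under label shuffling is overdispersed across shuffles relative
to a binomial; the chance-level control therefore averages over several
shuffles rather than testing one.

## The rake task

`rake_env()` is a deterministic MDP. The state is three-dimensional -
pellet depth 1..7 (1 = front edge), lateral rake-pellet offset -6..6, and
depth offset -6..6 - giving 7 x 13 x 13 = 1183 states, the unique small
factorization consistent with the task's published state count; the
pellet's column never changes because the rake cannot move it sideways.
Four actions move the rake one cell. The T-shaped rake's 3-cell crossbar
sweeps the pellet one cell along a depth move when it arrives exactly at
the pellet's cell with lateral offset at most 1; the rake-pellet offset is
preserved by a sweep, so repeated pulls from behind drag the pellet to the
front edge (+1, trial success) and repeated pushes from in front shove it
off the back (-0.2, trial failure). Moves that would exceed the +/-6
workspace are no-ops; a lateral move may place the crossbar on the
pellet's cell without moving it.

The rake starts behind the pellet at offset (0, +3). The per-step reward
defaults to -0.005: a tiny movement cost that makes endless wandering
strictly worse than finishing the trial. Without it there is a concrete
failure mode at intermediate channel accuracies: if the agent's first few
successes happen to be misreported as penalties, the whole pellet region
acquires negative value while untouched parts of the workspace stay at
zero, and the agent settles into permanent 1000-step zero-reward episodes.
The movement cost removes that absorbing state while leaving the terminal
reward ordering untouched.

## SARSA($\lambda$) with per-pair annealing

`sarsa_update()` implements on-policy TD($\lambda$) control with
eligibility traces (replacing by default, accumulating by flag), traces
cleared at episode start, $\epsilon$-greedy selection with uniform
tie-breaking, and a visit-count-annealed learning rate
$\alpha(s,a) = \alpha_0 / (1 + n(s,a))$. Crucially, each traced pair is
updated with its *own* annealed rate. Using one shared rate for the whole
trace vector - the rate of the pair just visited, which stays at
$\alpha_0$ for rarely visited pairs - is numerically unstable at
$\alpha_0 = 0.5$: the effective update gain over a trace of mass
$\approx 1/(1-\gamma\lambda)$ exceeds the contraction limit and Q-values
diverge. Per-pair annealing makes every entry a Robbins-Monro average of
the rewards credited to it, which is also what absorbs reward
misclassification: early flips matter less and less as visits accumulate.

Defaults: $\epsilon = 0.05$, $\lambda = 0.9$, $\gamma = 0.95$,
$\alpha_0 = 0.5$, zero-initialized Q. Episodes are capped at 1000 steps;
a capped episode is truncated with no terminal update, flagged, and
counted as a non-success.

The training loop runs in compiled code (`run_training()`), using R's own
RNG so runs are bit-reproducible from a seed; the test suite replays the
compiled loop's logged transitions through the R-level `sarsa_update()`
and requires agreement to 1e-8.

## The noisy-reward robustness experiment

`reward_channel()` delivers the true outcome's reward with probability
$p$ and the other class's reward otherwise. At accuracy $p$ the expected
delivered reward is $1.2p - 0.2$ for a true success and $1 - 1.2p$ for a
true failure, so success remains the better outcome for every $p > 0.5$ -
the structural reason a SARSA learner with reward averaging can tolerate
large misclassification rates.

Convergence is operationalized behaviorally (`detect_convergence()`): the
convergence trial is the first trial after which the 100-trial moving
success fraction stays within 0.05 of its final value. `run_accuracy_sweep()`
trains one fresh agent per (accuracy, seed) for 200,000 environment steps
- the full protocol takes seconds thanks to the compiled loop - and
evaluates the true-success fraction over all post-convergence trials.
Sweeps below 200,000 steps are flagged `scaled_down`.

Problem sizes used by the test suite: 120-trial sessions for decoding
checks, 100-200 jackknife rounds per cell, 200,000-step training runs
with 5-8 seeds per accuracy for the robustness properties, and a 40,000-step
scaled-down sweep for the ordering check.

## Known limitations

* The generator's effect sizes are assumptions, not measurements; decoded
  accuracy on synthetic data is a property of those defaults.
* Per-timestep Welch tests are reported uncorrected by default, mirroring
  per-timestep significance marking practice; treat isolated flags
  accordingly.
* The decoder is strictly trial-synchronous; there is no sliding-window
  or asynchronous decoding.
* The RL agent is tabular; nothing here addresses continuous state
  spaces or function approximation.
* At channel accuracies at or below 0.6 the value margin between the two
  terminal outcomes is only a few hundredths of a reward unit, and
  individual training runs can still converge on the wrong policy; the
  robustness claims are about means over seeds, not every run.
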