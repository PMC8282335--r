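---
title: "Translating immature cardiomyocyte action potentials with a multitask LSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating immature cardiomyocyte action potentials with a multitask LSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptranslate)
```

## The problem

Induced pluripotent stem cell-derived cardiomyocytes (iPSC-CMs) are the
workhorse of human in-vitro cardiac electrophysiology, but they are
electrically immature: they beat spontaneously, rest at depolarised
potentials, and express a different balance of repolarising currents than
adult ventricular myocytes.  Whether a drug effect measured on an immature
action potential (AP) predicts the effect on the adult AP is therefore a
standing question.  `aptranslate` implements a sequence-to-sequence answer:
a multitask recurrent network that *translates* an immature AP waveform
into the corresponding adult AP waveform and simultaneously *classifies*
the input as drug-free or drugged (hERG/I~Kr~ block), trained entirely on
simulated AP populations.

The package contains the full pipeline as separately usable pieces: an
ionic-model simulator with a stochastic noise current and two drug-block
schemes, a paired-population builder, zero-phase preprocessing, the
network with hand-derived reverse-mode gradients, ADAM training,
evaluation metrics, and the feature/model ablation experiments.

## The reduced ionic model

The published iPSC-CM and adult ventricular models that motivated this
package are large (dozens of state variables) and their equations live in
their original papers.  `aptranslate` instead ships a reduced
Hodgkin-Huxley-style surrogate with eight currents

$$ I_x = G_x \cdot (\text{gates}) \cdot (V - E_x), \qquad
   x \in \{\mathrm{Na}, \mathrm{CaL}, \mathrm{Kr}, \mathrm{Ks},
   \mathrm{to}, \mathrm{K1}, \mathrm{f}, \mathrm{bNa}\}, $$

with two-parameter Boltzmann gate steady states and voltage-dependent time
constants, integrated by Forward Euler at an internal step of 0.01 ms and
resampled to the 1-ms network grid.  What is *normative* about the
surrogate is not any particular parameter value but the morphology
contract its two phenotypes satisfy at baseline (no noise):

* the **immature** set beats spontaneously (I~f~ plus a small background
  Na^+^ leak drive diastolic depolarisation against a weak I~K1~), with a
  maximum diastolic potential (MDP) in [-80, -70] mV and an intrinsic
  cycle length within 10% of the 982 ms used for matched pacing;
* the **adult** set is quiescent until stimulated, rests in [-92, -84] mV,
  has a faster upstroke than the immature cell, and a shorter APD~90~ at
  the matched cycle length;
* adult APD~90~ is strictly increasing in the I~Kr~ block fraction over
  the 0-50% sweep.

These relations are asserted in the test suite.  The calibrated defaults
(`immature_params()`, `adult_params()`) give, at baseline, an immature
cell with cycle length about 940 ms, MDP about -80 mV and APD~90~ about
360 ms, and an adult cell with resting potential -88 mV and APD~90~ about
223 ms at a 982-ms cycle length — shorter, faster-upstroke adult APs, as
required.  Under 50% I~Kr~ block the adult APD~90~ grows to about 276 ms
and the immature cell slows its spontaneous rate, mirroring the
prolongation the full published models show.

### Stochastic noise current

Cell-to-cell variability is produced by a stochastic voltage increment

$$ V_{t+\Delta t} = V_t - \frac{I(V_t)\,\Delta t}{C_m}
   + \xi\, n \sqrt{\Delta t}, \qquad n \sim \mathcal N(0, 1), $$

with diffusion coefficient $\xi = 0.3$.  The deterministic drift uses the
0.01-ms integration step; the stochastic increment is applied on the 1-ms
output grid with that grid's $\sqrt{\Delta t}$, which leaves the diffusion
(variance per unit time) identical to injecting noise at every internal
step while keeping the random-number stream short and reproducible.
`euler_noise_step()` exposes the update itself so its statistics can be
checked directly (the Monte-Carlo standard deviation of the increment at
$\Delta t = 1$ ms is 0.3 to within 1%).

Noise is applied only during the final 100 beats of each simulation
(`noisy_beats`); conditioning beats before that run noise-free.  Because
the package stores calibrated near-limit-cycle initial conditions, the
surrogate settles within 3-4 beats, and 20 conditioning beats are a
comfortable default (the published full models need thousands of beats to
reach steady state; the surrogate does not).

### Drug-block schemes

Simple block scales `G_Kr` once by $1 - \text{block fraction}$, swept
over 1-50% in 1% increments.  The state-dependent scheme is a two-state
open-channel-block surrogate,

$$ \frac{db}{dt} = k_\text{on} [D]\, p_\text{open} (1 - b)
   - k_\text{off}\, b, \qquad G_{Kr}^{\text{eff}} = G_{Kr} (1 - b), $$

with $p_\text{open}$ the instantaneous I~Kr~ open probability, so block
accumulates use-dependently over beats and deepens during the plateau.
The shipped rates ($k_\text{on} = 7.4\times10^{-4}$ per ng/mL per ms,
$k_\text{off} = 8\times10^{-4}$ per ms at 2.72 ng/mL) were chosen once so
that steady-state block is roughly 35%, which places the resulting APD
prolongation inside the simple-block sweep range (bound fraction 0.39 in
the immature cell, 0.31 in the adult).  The binding rates of the
drug-channel interaction of a multi-state Markov model is not reproduced here; this
scheme is a deliberately simple surrogate with the same qualitative
character.

## The paired population

`build_population()` builds the reference population design: 208 drug-free
pairs, 250 simple-block pairs (50 block levels x 5 beating rates), and
300 state-dependent pairs — 758 in total, labelled 0 (drug-free) or 1
(drugged).  For every pair an immature spontaneous trace is simulated
first; its last-beat cycle length is detected from maximum-dV/dt upstroke
markers, and the adult partner is then paced at exactly that cycle length,
so the pairing is rate-matched by construction.  The "five beating rates
per block level" arise naturally: five immature replicates with distinct
noise seeds have distinct last-beat cycle lengths.  Both traces are
cropped to a 701-sample window starting 5 ms before the upstroke.
Per-sample seeds are derived deterministically from the master seed, so a
population is reproducible from its manifest.

## Preprocessing

Traces are filtered forward and backward with a 4th-order low-pass
Butterworth filter (100 Hz cutoff at 1 kHz sampling) so the net phase
shift is zero; the cutoff removes the $\xi = 0.3$ noise while leaving AP
content (below roughly 50 Hz) untouched.  The filter family and cutoff are
package choices for the forward-backward filtering stage.  Because the filter starts from zero state, each trace is
linearly detrended to zero at both edges and extended by odd reflection
before filtering; the transients then die inside the discarded padding.
The test suite asserts the operational form of the zero-phase claim:
per-trace APD~90~ changes by less than 1 ms.

Normalisation is per population and cell type: subtract the mean over all
*training* traces, divide by the maximum absolute centered value.
Training traces therefore lie in $[-1, 1]$, held-out traces may exceed
it, and the inverse transform (needed to read translated outputs in mV)
is exact.  Per-population rather than per-trace statistics make that
inverse well defined for network outputs.

## The multitask network

Two stacked LSTM layers scan the normalized 701-sample input; at each
step the gates follow the standard equations (forget, input, candidate,
output; cell state $C_t = F_t \circ C_{t-1} + I_t \circ S_t$; hidden
state $h_t = O_t \circ \tanh C_t$).  The full flattened hidden sequence
$\{h_1 \dots h_m\}$ of the top layer — not just the final state — feeds
two fully connected heads: a translation head (one ReLU hidden layer,
then a linear 701-sample output) and a classification head (one ReLU
hidden layer, then a sigmoid probability).  The loss is the unweighted
sum of the batch-mean translation MSE and the batch-mean binary
cross-entropy.

Hidden sizes are package choices: 32 LSTM units per layer, 128
translation-head units, 32 classification-head units.  These are the
smallest sizes that reached the reported performance regime in pilot
runs on the surrogate populations; all are configurable through
`net_config()`, and the translation-ahead capacity can be raised for
harder data.  Dropout (probability 0.2) acts on LSTM outputs and FC
hidden activations with inverted scaling, so evaluation needs no
rescaling.  The scan is forward in time only.

Training uses ADAM exactly as specified ($\alpha = 10^{-3}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), mini-batches
of 64 (the final short batch is used, not dropped), at most 300 epochs,
and early stopping on the validation total loss with a patience of 20
epochs; the returned parameters are those of the best-validation epoch.
The stopping/selection signal is a 3-epoch moving average of the
validation total loss: on a nearly separable validation split the
cross-entropy term fluctuates by more than the translation term ever
improves, and a raw single-epoch minimum can be a fluke that freezes the
network long before the translation head has converged.  Smoothing makes
the selected epoch representative of a sustained optimum; with it, the
full-population run selects an epoch whose held-out translation MSE is
several-fold lower than the raw-minimum epoch's.
Gradients are hand-derived reverse-mode backprop-through-time,
implemented in compiled code and verified against central finite
differences to a relative error below $10^{-4}$; the ADAM step is checked
against an independent scalar oracle to $10^{-12}$.

## Evaluation

`evaluate_network()` reports, for the translation task, the MSE on the
normalized scale, the pooled coefficient of determination
$R^2 = 1 - SS_\text{res}/SS_\text{tot}$, and the mean absolute APD~90~
prediction error in percent (features are extracted after denormalizing
with the training statistics).  For the classification task it reports
AUROC (rank formulation, exact under ties and cross-checked against
exhaustive pair counting), accuracy in percent at threshold 0.5, recall,
precision (undefined, not zero, when nothing is predicted positive) and
the confusion counts.  APD~90~ error is aggregated as the mean absolute
percentage error, recorded as such in the report.

## Ablation experiments

Feature ablation zeroes one input time window (after normalisation, so
zero is the population mean), retrains from scratch with identical seeds
and configuration, and evaluates on the ablated test set; the window grid
is seven non-overlapping 100-ms windows with the last one extending to
701 ms.  Model ablation builds two variants: a single-LSTM-layer encoder (a
reduced recurrent encoder rather than none, so the heads still receive a
hidden sequence), and a translation-only network whose loss is the MSE
alone.  `high_resistance_window()` locates the ablation
window containing the plateau phase where the membrane resistance
$dV/dI$ diverges (net current nearly constant); because the diastolic
interval of a spontaneous cell also has a near-zero net current, the
search is restricted to windows overlapping the action potential itself.
The membrane-resistance series caps $|dV/dI|$ at $10^4$ where
$|\Delta I| < 10^{-6}$, since the divergence must be finite in software.

## What the synthetic data do and do not show

The generator emulates the reference data-collection conditions:
spontaneous immature
vs. rate-matched stimulated adult APs, Gaussian noise current with
$\xi = 0.3$ on the last 100 beats, a 1-50% conductance-scaling block
sweep, and a state-dependent binding condition at a clinical
concentration.  It does **not** reproduce the published ionic models'
quantitative APD and cycle-length values digit for digit, calcium
handling,
tissue-level effects, or experimental artefacts such as electrode drift.
Passing tests therefore demonstrate that the pipeline recovers the
expected *relations* — translation fidelity, classification
from the high-resistance plateau phase, multitask benefit, zero-phase
preprocessing, reduced adult APD dispersion — on populations with the
stated design, not that it reproduces any specific published number.

## Numerical choices and degenerate inputs

* Forward Euler at 0.005-0.01 ms is stable for the surrogate's fastest
  gate (tau >= 0.03 ms); 0.01 ms is the default and the upper bound.
* Gate kinetics are tabulated on a 0.05-mV grid with linear
  interpolation; differences from direct evaluation are below the
  integration error.
* Upstroke detection: dV/dt > 10 mV/ms with a 250-ms refractory window,
  ties broken by the earliest maximum-slope sample.
* APD~90~ uses the trace minimum as the diastolic reference (robust for
  upstroke-aligned windows that begin only 5 ms before the upstroke) and
  linear interpolation at the crossing; traces that never cross the
  level raise an error rather than returning a truncated value.
* Traces failing the AP validity range (min < -40 mV, max > 0 mV), cells
  that stop beating, and numerical blow-ups (|V| > 200 mV) abort with the
  offending sample/beat identified.
* Probabilities entering the cross-entropy are clipped to
  $[10^{-7}, 1-10^{-7}]$.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the pipeline end to end at
sizes chosen to keep a complete desk run comfortable: the full 758-pair
population for dataset-construction and preprocessing checks; a training
run on that population for the headline metrics; a 100-sample, 50-epoch
smoke training run; and the ablation battery on a stratified subset with
a proportionally smaller network, five seeded replicates for the
multitask-vs-translation-only comparison.  These sizes are recorded in
each script and manifest, so any of them can be scaled up by changing one
configuration argument.

## Known limitations

* The surrogate's absolute APD/CL numbers differ from the published
  models'; only the contract relations above are calibrated.
* The state-dependent scheme is a two-state approximation of a
  multi-state drug-channel Markov model; it produces use-dependent block
  but no conformation-specific trapping.
* Early stopping monitors the summed validation loss; on very small
  validation splits the cross-entropy term remains noisy even after the
  3-epoch smoothing, and training can end while the translation MSE is
  still improving.  Larger validation sets (the default 10% of 758)
  mitigate this.
* APD~90~ is anchored at the maximum-dV/dt sample on the 1-ms grid.  For
  the slow immature upstroke the anchor can move by one sample when the
  trace is smoothed, so per-trace APD~90~ comparisons across filtering
  carry a quantisation floor of about one grid step even though the
  APD~90~ *distributions* before and after filtering superimpose.
* On the surrogate populations the drug-free/drugged classes are nearly
  separable, which makes the classification task easy; in this regime the
  auxiliary cross-entropy objective does not measurably improve the
  translation head (a shared-structure benefit needs a task the classifier
  cannot almost solve outright), and the
  drug-discriminative information is spread over the 200-500 ms span
  rather than concentrated in a single 100-ms window.
* No calcium transients, no tissue-level simulation, no attention or
  bidirectional variants.
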