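---
title: "A firing-rate model of basal-ganglia action selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A firing-rate model of basal-ganglia action selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgselect)
```

## The circuit

`bgselect` implements a neural mass model of the basal ganglia as a gating
device. Four segregated action channels each comprise a cortical unit (C),
Go and NoGo striatal units, GPe and GPi pallidal units and a thalamic unit;
a single subthalamic unit (STN) and a single cholinergic interneuron unit
(ChI) act globally on all channels. The GPi (merged with the SNr) is
tonically active and holds the thalamus inhibited; action selection is the
*disinhibition* of one thalamic unit, which closes an excitatory
cortico-thalamic loop and drives the winning cortical unit to saturation.
Cortical lateral inhibition makes the competition winner-takes-all.

Every unit obeys the same three-equation scheme: a weighted-sum net input,
first-order leaky integration with time constant $\tau$ (the lateral
inhibition state uses a slower $\tau_L$), and a sigmoidal activation with
slope $a$ and center $u_0$ keeping activity in $(0,1)$. The model's
behaviour is therefore fully determined by its connection table (18
matrices/scalars, `bg_weights()`) and a dozen scalar constants
(`bg_params()`).

Dopamine is an input signal with one tonic level and optional rectangular
phasic events. Its three points of action and their signs are the
functional heart of the model:

* **Go (D1)**: $\alpha \cdot DA \cdot (y^G - \vartheta_G)$ — excitatory
  above the contrast threshold $\vartheta_G = 0.3$, inhibitory below, so
  dopamine sharpens the difference between active and quiet Go units;
* **NoGo (D2)**: $\beta \cdot DA$ with $\beta < 0$ — uniform inhibition;
* **ChI**: $\gamma \cdot DA$ with $\gamma < 0$ — dopamine suppresses
  cholinergic tone. The ChI itself inhibits Go and excites NoGo, so a
  dopamine dip *disinhibits* the ChI, which then amplifies the dip's
  pro-NoGo effect. This cholinergic relay is what makes punishment-driven
  depression of the direct pathway possible at all: without it the Go dip
  barely clears the learning threshold.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tau`, `tau_L` | 10, 50 | ms | membrane / lateral-inhibition dynamics |
| `a`, `u0` | 4, 1 | — | sigmoid slope and center |
| `theta_G` | 0.3 | activity | Go contrast-enhancement threshold |
| `alpha`, `beta`, `gamma` | 1, −1, −1 | — | dopamine gains (Go, NoGo, ChI) |
| `I_E`, `I_I`, `I_H` | 1, 3, 1.25 | input | tonic drives (GPe, GPi, ChI) |
| `action_threshold` | 0.95 | activity | cortical gating criterion |
| tonic DA | 0.45 | — | healthy basal level; 0.35 depleted, 0.55 elevated |
| `sigma` | 0.1 | — | Hebb learning rate |
| `theta_pre`, `theta_post` | 0.5, 0.5 | activity | Hebb eligibility / direction thresholds |
| `w_max` | 1.2 | weight | trainable-synapse saturation |

The tonic drives fix the rest state: GPe about half-maximal (0.48), GPi
near saturation (0.89), cortex, striatum and thalamus silent. These values
follow directly from the connection table; we validate them as an ordering
contract (GPi high and above GPe; cortex/thalamus below 0.05) rather than
as exact constants.

**Choice of `w_max`.** The saturation bound of the trainable synapses is a
free constant. We use 1.2 — just above the largest pretraining trainable
weight (the cortex-to-NoGo diagonal, 1.08) — so that the pretraining state
itself satisfies the $[0, w_{max}]$ constraint and the NoGo synapse of a
punished channel keeps headroom to potentiate slightly, as it should. The
learning endpoints that matter (rewarded-channel NoGo weight driven to the
lower clip; rewarded-channel Go weight driven to the upper clip) are
insensitive to the exact value.

## Numerical scheme

Integration is synchronous explicit Euler with `dt = 0.1` ms, two orders of
magnitude below $\tau$; the constructor enforces `dt ≤ tau/10`. The scheme
and step are our choice, made for transparency and reproducibility: at this
step the trajectory error relative to the closed-form relaxation is first
order (halving `dt` halves it), and halving `dt` moves no end-of-trial
activity by more than $10^{-3}$. All membrane states start at zero — the
silent baseline, activity $\approx 0.018$ — which reproduces the intended
rest behaviour. The sigmoid's exponent is clamped at $\pm 500$ purely as an
overflow guard; sigmoid outputs are strictly inside $(0,1)$ throughout the
operating range, though double precision necessarily rounds them to 0 or 1
for membrane states far outside it.

**Trial length.** We default to 500 ms. A single-candidate decision settles
within ~100 ms, but conflict resolution with an intact STN is much slower:
the winner only crosses the action threshold at ~350 ms and the network
settles by ~450 ms. A 300 ms trial would misreport that scenario as "no
response gated"; 500 ms leaves margin while keeping a trial at 5,000 steps.
End-of-trial activities are the decision readout everywhere ("final value"
semantics); they are insensitive to further lengthening because every
scenario reaches a fixed point.

**Lesions** clamp *activities*, not inputs, after each step: the STN lesion
fixes $y^{STN} = 0$; the ChI clamp fixes $y^H$ at its analytic tonic fixed
point $\varsigma(I_H + \gamma \cdot DA_{tonic})$, so the clamp level adapts
consistently when the tonic dopamine level is itself manipulated.

**Conflict energy** is implemented as the full double sum over ordered
pairs, $E = (\sum_i y_i)^2 - \sum_i y_i^2$; the STN gain $k_E$ absorbs the
factor of two relative to an unordered-pair convention.

**Ties** in gating latency are broken toward the lowest channel index; the
default experiments never produce exact ties, but a deterministic rule is
needed for testing.

## The training protocol

Each epoch draws the context stimulus with additive Gaussian noise
(sd 0.25, clamped back to $[0,1]$) — the exploration that lets non-prepotent
responses occasionally win — and simulates a decision trial under tonic
dopamine. If a response gates, feedback follows: a dopamine peak to 0.9
(reward) when the winner is the target channel, a dip to 0 (punishment) for
any other winner, delivered over 100–150 ms of a re-simulated feedback
window. Pre- (cortex, stimulus) and postsynaptic (Go, NoGo) activities are
read at the end of that window, where striatal displacement is maximal, and
one Hebb update is applied simultaneously to the four trainable matrices
(diagonal masks for the cortex pairs, full masks for the stimulus pairs).
An epoch that gates nothing delivers no feedback and, by default, no
update; applying the rule anyway is available behind
`update_without_feedback` and moves winner-channel synapses by less than
0.005, but would slowly drift loser-row stimulus synapses, which is the
substantive reason the default skips it.

Punishment is delivered for *any* wrong winner, not only the prepotent
channel: the feedback rule is defined by the target, not by a list of
forbidden responses.

One hundred epochs on the context `[0.15, 0.15, 0.9, 0.7]` with target
channel 4 reliably (across seeds) drive the rewarded channel's NoGo synapse
to 0, its Go synapse to saturation, and flip the noiseless decision from
channel 3 to channel 4.

## What the experiments show — and what they do not

The bundled scenarios (`bg_stimuli()`, `run_scenario()`, `run_da_sweep()`,
`run_latency_curve()`) exercise: default single-winner gating; conflict
with and without the hyperdirect brake; reward/punishment striatal
displacement with and without the cholinergic relay; the full training
study; the direct/indirect balance across tonic dopamine 0.35/0.45/0.55;
and gateability/latency across stimulus amplitude 0.31–1.00 at four
dopamine levels (step 0.01 — the grid resolution, not a claim about
behavioural precision). Simulated problem sizes throughout are the model's
native scale: 4 channels, 300–500 ms trials, 100-epoch training runs.

These are demonstrations of circuit-level sufficiency, not fits to data:
stimuli are idealized 4-vectors, noise enters only through the stimulus,
reward timing is fixed and exogenous, and there is no reward-prediction
error — a well-expected reward still triggers a full phasic peak, which is
why the stimulus-to-NoGo matrix drifts downward late in training. Passing
tests show the mechanisms behave as designed under these idealized
conditions; they do not show that real basal-ganglia circuits are
quantitatively captured.

## Known limitations

* No temporal-difference or actor–critic learning; feedback is an external
  schedule.
* No thalamostriatal or GPe-to-striatum feedback; GPi and SNr are merged;
  dopamine neurons are not modelled explicitly.
* Overlapping (non-orthogonal) contexts trained to different responses will
  interfere; the model has no stimulus-orthogonalizing front end.
* Absolute latencies depend on the (unitless) weight scale and should be
  read comparatively, not as millisecond predictions.
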