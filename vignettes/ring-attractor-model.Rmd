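---
title: "The ring-attractor compass model and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ring-attractor compass model and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringcompass)
```

# The circuit and its model

The fly's compass is a ring of EPG neurons whose localized activity bump
encodes head direction (HD). Two forces move the bump: an angular-velocity
input that rotates it with the animal's turns (path integration), and
inhibitory ring-neuron (ER) inputs tuned to the positions of sensory cues.
Each cue's ER population projects all-to-all onto the ring through a
plastic, non-negative weight matrix. Where presynaptic cue drive and
postsynaptic bump activity coincide, associative depression weakens the
inhibition, carving a "notch" into the weight matrix; everywhere else,
postsynaptically gated potentiation restores the weights toward a ceiling
`w_max`. The notch is the circuit's memory of the cue-to-heading mapping:
a deep notch anchors the bump to the cue, and when cues move or conflict,
the same learning rule re-carves it.

`ringcompass` implements the rate model of this circuit:

$$\tau \dot f_n = -f_n + \Big[\alpha f_n + D(f_{n-1}+f_{n+1})
  + \frac{v}{2 v_\mathrm{rel}}(f_{n+1}-f_{n-1})
  - \beta \textstyle\sum_l f_l + I_{n,1} + I_{n,2} + 1\Big]_+$$

with circular indexing, inhibitory cue input $I_k = -W_k g_k$, ER activity
$g_{k,m} = \varepsilon + A_k \exp[\kappa_k(\cos(\theta_k-\theta_m)-1)]$, and

$$\dot W_{k,nm} = \eta\,|v|\,f_n\big(w_\mathrm{max}(1 - g_{k,m}/g_0) - W_{k,nm}\big).$$

Everything is integrated by explicit Euler steps of $\Delta t$ = 2.5 ms in
compiled code; all user-facing inputs and outputs are tibbles.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `N`, `M` | 32, 32 | – | EPG neurons; ER neurons per cue |
| `tau` | 0.05 | s | rate time constant |
| `alpha`, `D` | −8.93, 5.19 | – | local self-interaction, neighbor excitation |
| `beta` | 0.11 | – | global inhibition (keeps one bump) |
| `v_rel` | 3.64 | rad/s | advection scaling; yields near-unity closed-loop gain |
| `eta` | 0.34 | – | learning rate, multiplied by \|v\| |
| `w_max`, `g0` | 1/17, 1 | – | weight ceiling; LTP/LTD balance point |
| `b_ER` | 0.45 | – | ER baseline-noise factor |
| `w_k` | 0.8 | rad | ER tuning width; `kappa = log2/(1−cos(w/2))` ≈ 8.78 |
| `sigma_u` | 8 | rad·s^−1/2 | HD random-walk scale |
| `sigma_AV` | 1 | rad/s | driving-velocity noise (after smoothing) |

The trial begins with a 20-s relaxation from a raised cosine with zero
velocity and zero input, which defines the steady-state bump `f_ss`
(amplitude ≈ 1.062 at the defaults; the global inhibition pins the trough at
zero, so amplitude ≈ peak rate). ER amplitudes are specified as
dimensionless scales multiplied by this amplitude, so "cue intensity 2"
means an ER peak of ≈ 2.12. Weight matrices start uniform-random with
Frobenius norm exactly 1.5.

# Design choices

Several elements of the published equations admit more than one reading, or
are unstated. The package fixes each by requiring the circuit to function as
a compass; all were settled before the test suite was frozen.

**Advection difference scheme.** The velocity term is implemented as the
central difference $\tfrac{1}{2}(f_{n+1}-f_{n-1})$. With the one-sided
difference $\tfrac{1}{2}(f_{n+1}-f_{n})$ and `v_rel` = 3.64 the bump's
path-integration gain is ~0.53 — the bump rotates at half the fly's turning
speed and even a bright cue cannot anchor it reliably. The central
difference gives gain ≈ 1.0–1.05, which the closed-loop tracking tests
validate, and is the standard discretization in this model family.

**ER baseline-noise scale.** The noise bound is `b_ER × mean(f_ss)` ≈ 0.16.
Two alternative readings fail structurally: a bound proportional to the
*summed* steady-state activity (≈ 5.1) makes the mean inhibition exceed the
tonic drive, so the rate equation has no active steady state and every
learning target is negative (no notch can exist); a bound proportional to
the bump *amplitude* (≈ 0.48) supports single-cue protocols but the
inhibition budget of two simultaneously bright cues still extinguishes the
bump. The mean-rate scale is the only one under which `g0` = 1 separates
baseline noise from tuned peaks — the separation the LTP/LTD decomposition
requires — and under which all five protocols keep a live bump.

**Noise independence.** Baseline ER noise is drawn independently per neuron
and per step. A single shared draw per step preserves rotational symmetry
exactly; once the bump collapses into the uniform state (which a noise
excursion eventually causes at zero cue amplitude) nothing can re-form it.
Independent draws break the symmetry and continuously reseed the bump.

**Velocity noise scale.** `sigma_AV` describes the smoothed noise process:
raw white noise is scaled by the square root of the 0.04-s window span so
that the noise actually driving the network has s.d. 1 rad/s. Read instead
as the raw per-step s.d., smoothing leaves only ~0.25 rad/s; path
integration is then nearly perfect and cue intensity cannot improve
accuracy, inverting the central intensity-sweep trend.

**Weight clipping.** The learning target `w_max(1 − g/g0)` is negative
wherever `g > g0`, while the weights are inhibitory magnitudes and must stay
non-negative. Weights are clipped at zero after each Euler step, which
reconciles the two statements and defines the notch floor.

**Running-average boundaries.** Centered windows span `round(window/dt)`
samples (the 0.04-s window spans 16 steps at the default `dt`), truncated
symmetrically at sequence ends; truncation avoids phantom zero-padding
transients. For even spans the extra sample sits to the right of the
center.

**Bump readout.** The bump position is the angle of the circular argmax
(lowest index on ties), matching the accuracy definition; the index-to-angle
map runs clockwise (negative slope) so that the bump follows +HD — a sign
validated by the tracking tests, not assumed. Model bump width is the full
width at half maximum with linear interpolation between the 32 angular
samples, verified against the closed-form von Mises width on noiseless
profiles.

**Seeding.** Every trial derives independent sub-streams (heading draw,
velocity noise, weight initialization, ER noise, shift directions) from one
root seed, so toggling any noise source leaves the others bit-identical,
and protocol runners are reproducible from `(config, seed)` in any
execution order.

# Analysis pipeline

HD encoding accuracy is the vector strength (1 − circular variance) of
bump-to-heading offsets; for model traces it is evaluated over a causal 8-s
window, with early frames using the partial window. Imaging-convention
recordings are analysed by fitting $a\,e^{\kappa\cos(x-\mu)}+c$ to each
frame. The fit solves `(a, c)` in closed form for fixed `(kappa, mu)` and
optimizes only the outer pair, multi-started at the activity-weighted
circular mean of the angles and its antipode because the residual landscape
is bimodal in `mu`; `kappa` is bounded to [0, 500] with overflow-safe width
and amplitude formulas; fits with adjusted R² (4 parameters) below 0.5 are
flagged invalid. Frames with rotational speed below a configurable
movement threshold (default 0.05 rad/s — the immobility criterion is not
quantified anywhere, so it is explicit configuration) are excluded from
accuracy and remapping indices. All pre/post-shift offsets are circular
means; arithmetic means fail near ±π.

The conflict regression $\mu_n = a\theta_n + b$,
$\phi_n \sim \text{vonMises}(\mu_n,\kappa)$ uses priors $a \sim N(0,1)$,
$b \sim U(-\pi,\pi)$, $\kappa \sim \text{InvGamma}(1.91, 6.47)$ in the
(shape, scale) convention — the one for which the prior leaves roughly 1%
of its mass below 1 and 1% above 50, its stated design property. Sampling
is component-wise random-walk Metropolis on $(a, b, \log\kappa)$: four
chains, 1000 warm-up and 1000 retained iterations by default, two
parameter sweeps per iteration, proposal scales adapted toward ~44%
acceptance and frozen before sampling. The circular likelihood has aliased
local modes in the slope, so chains start jittered around a grid-scan
estimate of the dominant mode rather than anywhere on the slope axis.
`b` is proposed, stored, and summarized circularly. Every fit carries
split-Rhat and effective-sample-size diagnostics; Rhat > 1.01 marks the
result unreliable with a warning. On small datasets the sampler is checked
against a dense 3-D grid posterior in total variation after coarse binning,
and retrodictive checks compare observations with circular quantile bands
of replicated data.

# Synthetic recordings

The generator emulates only the statistical structure the analyses assume:
a frames × ROIs matrix at ~9.18 frames/s over 25–40 ROIs, a von Mises bump
at $\mu(t) = \mathrm{wrap}(-\mathrm{hd}(t) + \mathrm{offset})$, i.i.d.
Gaussian ROI noise, immobile epochs that freeze heading and zero speed, and
cue traces with ±120° shift events in which the bump preserves its offset to
a designated cue. Behavioral motion comes from the same trajectory module as
the simulator, keeping one source of motion statistics. It deliberately does
*not* emulate raw-movie artifacts, motion correction, the two-copy
protocerebral-bridge geometry, or structured (non-i.i.d.) imaging noise — so
passing recovery tests demonstrate that the pipeline is correct on data
satisfying its assumptions, not that it is robust to real imaging noise.
Generator truth fields travel in attributes read only by tests.

# Problem sizes and known limitations

The test suite exercises the figure-level behaviors at 10 trials per
condition (the runners default to 100, a config flag), 5 cue-intensity
levels instead of 41, two gain-inversion amplitudes, and a 22-trial subset
of the 132-trial two-cue enumeration; parameter-recovery checks use 40
repetitions at 500 warm-up/500 retained draws. These sizes reproduce the
direction of every trend; full-scale runs change only the sampling error.

Known limitations: rate-based dynamics only (no spiking, no
connectome-derived weights); learning is gated by |v| with no
neuromodulatory modulation; the explicit Euler scheme is first-order (the
dt-halving test bounds the end-of-trial bump displacement by one neuron
spacing); accuracy saturates near 1 for strongly anchored cues, where ER
noise acting through the deep notch causes a sub-percent non-monotonicity
across the top intensity levels — invisible at figure resolution but worth
knowing when comparing saturated conditions; and the von Mises frame fit
assumes a single bump, so it gates out (rather than models) multi-peaked or
flat frames.
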