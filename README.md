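# ringcompass

Simulation and analysis of the *Drosophila* head-direction (compass) system
as a ring attractor with Hebbian-plastic sensory synapses.

The fly's EPG neurons tile the ellipsoid body as a ring; a localized bump of
activity among them encodes head direction (HD), moved around the ring by the
fly's angular velocity and anchored by inhibitory ring-neuron (ER) inputs
that convey the positions of sensory cues (a visual landmark, a wind
direction). The ER→EPG synapses are plastic: associative depression carves a
"notch" of weakened inhibition where cue position and bump position coincide,
which is how the circuit learns — and relearns — the mapping from each cue to
heading. `ringcompass` implements this model, the simulation protocols that
probe it (cue-intensity sweeps, two-cue conflicts, cue combination,
closed-loop gain inversion), and the circular-statistics pipeline used to
quantify the results, entirely on simulated and synthetic data. It is aimed
at systems neuroscientists who want to explore multisensory cue weighting and
remapping in attractor circuits without any experimental data.

## The model

EPG rates `f_n` (N = 32 neurons on a ring, circular indexing) follow

    tau df_n/dt = -f_n + [ alpha f_n + D (f_{n-1} + f_{n+1})
                           + (v / v_rel) (f_{n+1} - f_{n-1}) / 2
                           - beta sum_l f_l + I_{n,1} + I_{n,2} + 1 ]_+

with `tau` = 50 ms, `alpha` = −8.93, `D` = 5.19, `beta` = 0.11,
`v_rel` = 3.64, and `[.]_+` the rectifier. Each cue k provides inhibition
`I_k = -W_k g_k` through a non-negative N×M weight matrix, where the M = 32
ER neurons are tuned to cue direction,

    g_{k,m} = eps + A_k exp[ kappa_k (cos(theta_k - theta_m) - 1) ],

with amplitude `A_k` proportional to cue salience, tuning width 0.8 rad
(`kappa = log 2 / (1 - cos(w/2))`), and uniform baseline noise `eps`. The
synapses evolve by a postsynaptically gated, velocity-gated rule

    dW_{k,nm}/dt = eta |v| f_n ( w_max (1 - g_{k,m}/g0) - W_{k,nm} ),

non-associative potentiation toward `w_max` = 1/17 balanced against
associative depression — the weight notch that anchors the bump. Analyses
use vector strength (1 − circular variance) of bump-to-heading offsets as
HD encoding accuracy, von Mises fits of activity profiles for bump position,
width and amplitude, preference/stickiness/remapping indices around cue
shifts, and a Bayesian linear–circular regression of offset change on cue
conflict with von Mises noise (priors `a ~ N(0,1)`, `b ~ U(-pi,pi)`,
`kappa ~ InvGamma(1.91, 6.47)`).

## Worked example

Simulate a bright-cue trial (120-s burn-in, 30-s assessment) and fit the
conflict regression on synthetic data:

```r
library(ringcompass)

tr  <- generate_trajectory(trajectory_params(duration = 150), seed = 1)
sch <- build_schedule("intensity_sweep", list(A_scale = 2))
sim <- simulate_trial(tr, sch, seed = 1)
sim
#> <ring_sim> protocol: intensity_sweep | duration: 150 s | 3000 recorded frames
#> steady-state bump amplitude: 1.062

m <- sim_metrics(sim)
w <- m[m$t > 120, ]
c(accuracy = mean(w$accuracy), width_deg = mean(w$width) * 180 / pi)
#>  accuracy width_deg
#>     0.989      92.9
notch_depth(sim$final_W[[1]])
#> [1] 0.0458
```

The bump tracks heading with accuracy 0.99 (1 = a perfectly constant
offset), is ~93° wide at half maximum, and has carved a weight notch of
depth 0.046 — an untrained matrix sits at ~0.015. Weaker cues give lower
accuracy, wider bumps and shallower notches (`run_intensity_sweep()`).

```r
d   <- generate_conflict_dataset(a = 0.8, b = 0.5, kappa = 8, n = 36, seed = 2)
fit <- fit_conflict_model(d, seed = 3)
tidy(fit)
#> # A tibble: 3 × 4
#>   term  estimate conf.low conf.high
#> 1 a        0.809    0.758     0.857
#> 2 b        0.481    0.386     0.572
#> 3 kappa    9.56     6.21     13.4
```

The posterior recovers the generating slope, circular offset, and noise
concentration; `glance(fit)` reports split-Rhat and effective sample sizes,
and `posterior_retrodictive()` checks the fit against replicated data.
Protocol runners (`run_intensity_sweep()`, `run_two_cue_shift()`,
`run_cue_combination()`, `run_gain_inversion()`) return tidy per-trial and
condition-level tables; `autoplot()` displays each result type.

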