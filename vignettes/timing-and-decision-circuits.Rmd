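---
title: "Interval timing and the speed-accuracy trade-off in coupled cortical circuit models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval timing and the speed-accuracy trade-off in coupled cortical circuit models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`timingnet` simulates a local cortical circuit as a fully recurrent network
of leaky integrate-and-fire neurons: `N_E` pyramidal cells arranged on a
ring and `N_I = N_E/4` fast-spiking interneurons (reference size
1000/250). Pyramidal-to-pyramidal conductance is a Gaussian function of
ring distance,

    w_ij = W+ * exp(-d_ij^2 / (2 sigma_w^2)),   d_ij = min(|i-j|, N-|i-j|),

while every other connection block (E to I, I to E, I to I) is uniform.
Excitation is carried by AMPA and NMDA receptor conductances, inhibition
by GABA-A; NMDA activation saturates through the auxiliary-variable
kinetics `ds/dt = -s/tau_NMDA + alpha x (1-s)`, `dx/dt = -x/tau_x + sum of
spikes`, and its voltage dependence is the standard magnesium-block
sigmoid `1/(1 + [Mg] exp(-0.062 V)/3.57)`. Each membrane follows

    C_m dV/dt = -g_L (V - V_L) - I_syn(t),

with spike-and-reset at threshold and an absolute refractory period.
Background bombardment is the point-conductance model: two per-neuron
stochastic conductances (excitatory and inhibitory) following
Ornstein-Uhlenbeck processes, integrated with the exact discrete update.
Sampled noise conductances may transiently be negative under that update;
they are clamped to zero where they enter the current, not in the state,
so the published stochastic process is preserved while currents stay
physical.

All constants live in a single configuration object
(`default_network_config()`); no operation hard-codes a biophysical
value. Membrane and synaptic kinetic constants are the classic
working-memory ring-model values (pyramidal `C_m` 500 pF, `g_L` 25 nS;
interneuron 200 pF, 20 nS; `V_L` -70, `V_th` -50, `V_reset` -60 mV;
refractory 2/1 ms; `tau_AMPA` 2 ms, `tau_NMDA` 100 ms, `tau_x` 2 ms,
`alpha` 0.5/ms, `tau_GABA` 10 ms; `V_E` 0, `V_I` -70 mV; `[Mg]` 1 mM).
Noise parameters are the standard point-conductance values (`tau_e` 2.728,
`tau_i` 10.49 ms; diffusion coefficients from per-channel standard
deviations 3.0 and 6.6 nS; mean excitatory conductance 12.1 nS onto
pyramidal cells). The mean excitatory noise conductance of interneurons
and the mean inhibitory noise conductance of both populations are zero:
recurrent connectivity itself supplies those backgrounds. Receptor
conductance strengths and the Gaussian footprint have no published
single source; they were chosen once so that the circuit reproduces the
qualitative operating points described below, and are recorded in full in
the configuration: AMPA is stronger and faster onto interneurons (0.45 nS,
1 ms) than onto pyramidal cells (0.10 nS, 2 ms); NMDA is stronger and
slower onto pyramidal cells (0.24 nS, 100 ms vs 0.12 nS, 50 ms); GABA is
several times stronger than the excitatory conductances and stronger onto
pyramidal cells (2.8 vs 0.5 nS); `W+ = 1`, `sigma_w = 60` ring units.
These per-unit-weight strengths are defined at the reference size;
`scale_network_config()` multiplies them by `N_ref/N` when the ring is
shrunk so summed recurrent drive is preserved, and scales the footprint to
the same ring fraction.

## Timing by climbing activity

A single factor `rho` scales NMDA conductance onto both populations. At
`rho = 1` the network sits in a stable background state (a few Hz,
irregular). As `rho` grows the uniform state first becomes bistable with a
bump state and then loses stability altogether: from then on activity
*must* climb away from the background toward the stable bump, at a rate
set by the unstable eigenvalue. The interval estimate of a trial is the
first time the mean spike-density function (SDF) of the bump population
reaches a fixed 20 Hz threshold. The bump population is found post hoc:
the neuron with the highest trial-mean SDF is the centre, flanked by a
configurable number of neighbours on each side (`bump_halfwidth`; the
analyses here use roughly the bump core, e.g. 35 neurons per side on a
250-cell ring).

SDFs convolve spike trains with the causal rise-and-decay kernel
`(1 - exp(-t/tau_g)) exp(-t/tau_d)` (`tau_g` 1 ms, `tau_d` 20 ms). The
kernel is used unnormalized and traces are then scaled by `1000 /
integral(kernel)` so a sustained train of `r` Hz plateaus near `r` Hz;
this calibration is what lets thresholds be stated in Hz. SDFs are
sampled at 1 ms; threshold crossings use the first at-or-above sample,
with no interpolation.

Trial-to-trial learning adjusts the scale factor after each trial,

    rho[n+1] = rho[n] + eta * (T[n] - T_desired),

which moves the estimate toward the target because the estimate decreases
monotonically in `rho` (an estimate that is too long calls for stronger
recurrence and faster climbing). Trials without a crossing leave `rho`
unchanged and are logged. Learning rates of a few 1e-4 per ms of error
keep `eta * |dT/drho|` well below the stability bound of the fixed-point
iteration, so learning converges within a handful of trials; the floor on
`rho` is placed at the lower edge of the climbing regime so that noisy
updates cannot strand the network where estimates are unreliable.

Start and stop signals are conductance pulses: a brief rise of the mean
excitatory noise conductance of all pyramidal cells recruits blanket
feedback inhibition and resets the network regardless of its state (one
mechanism for both starting and stopping), or the same pulse applied to
the interneurons stops the estimate through disynaptic inhibition. A
pulse is specified as a factor on the *reference* excitatory noise
conductance, which keeps the mechanism well defined for the interneuron
population whose resting mean is zero.

## The reduced model

Because `tau_NMDA` far exceeds every other time constant, the fast
variables (AMPA and GABA gating, firing rates) can be slaved to their
steady states and the NMDA activation field `S(x)` carries the dynamics:

    dS/dt = -S/tau_NMDA + gamma (1 - S) r_E(x) / 1000,

with `r_E = phi(I)` solved self-consistently from the current field
(Gaussian-kernel convolution of `S` for NMDA, of `r_E` for AMPA, global
linearized interneuron feedback for GABA) and `phi` the smoothed
threshold-linear activation `(aI - b)/(1 - exp(-d(aI - b)))`. The
effective strengths of the reduction are tuned once to mirror the spiking
circuit's qualitative behaviour and exposed in `reduced_params()`. The
Jacobian of the field equation is assembled analytically (the rate
self-consistency is linear in perturbations), with a finite-difference
version retained as an independent cross-check; at a flat state the
linearization is circulant plus a rank-one term, so Fourier modes give the
spectrum in closed form and serve as a second oracle.

Sweeping the NMDA strength reproduces three regimes: (1) a single stable
flat state; (2) bistability, where a small unstable bump (the saddle) and
a large stable bump coexist with the flat state; (3) an unstable flat
state whose largest eigenvalue is positive, plus the stable bump. The
leading eigenvector of the unstable flat state is a zero-mean spatial
patterning mode at the kernel's favoured wavelength; noise excites it at
an arbitrary phase and the nonlinear evolution localizes it into a single
bump, which is why climbing occurs at arbitrary, trial-varying locations.
The stable bump's largest eigenvalue is zero (the translation mode along
the ring). Eigenvalue magnitudes below 1e-6 are treated as the translation
mode, not instability. Steady states are found by scalar root-finding for
flat states and damped Newton iteration from bump-shaped seeds; the grid
default is 256 points, and doubling the resolution moves eigenvalues by
less than 1 percent.

## First-passage theory of the scalar property

Near the unstable flat state the system expands along the leading
eigenvector; the amplitude of that mode follows a one-dimensional OU
process with positive drift, `dz = lambda z dt + sigma dW`, from `z0` to
the threshold `theta_z`. Because the threshold is defined as a firing
rate, it is mapped into activation units by scaling with the ratio of the
maxima of activation and rate at the stable bump state
(`nmda_threshold_from_rate()`), which preserves the fixed 20 Hz rule
across `rho`. For positive drift the accumulated noise saturates, giving
the closed-form first-passage density
`f(T) = lambda theta exp(-lambda T) dnorm(theta exp(-lambda T); z0, s)`
with `s = sigma/sqrt(2 lambda)`; reported moments are the exact integrals
of that density (leading order: mean `ln(theta/z0)/lambda`, SD
`s/(lambda z0)`).

The initial amplitude `z0` is the scale the noise itself establishes
before exponential growth takes over, a fixed multiple (default 5) of the
stationary linear-mode scale `sigma/sqrt(2 lambda)`. With `sigma` held
constant across the `rho` family (the spiking network uses identical
noise parameters at every `rho`), stronger NMDA conductance raises
`lambda` and lowers `theta_z`, and the family traces out an approximately
linear SD-versus-mean relation with near-constant coefficient of
variation - the scalar property. It rests on three ingredients: the
threshold falls with excitation, the feedback is linear near the flat
state, and the noise is independent of excitation; making `sigma` grow
with `lambda` (the negative control in the test suite) destroys the
constancy of the CV.

## The coupled decision task

Two circuits with byte-identical parameters except the NMDA scale factor
are run concurrently. The decision network's factor is one quarter of the
timing baseline - too weak for autonomous decisions - and only it
receives stimuli: target and distractor Poisson inputs with Gaussian
response fields (centres at the quarter points of the ring, width equal
to the recurrent footprint), with one population-level rate drawn per
stimulus per trial from a normal distribution truncated at zero.
Difficulty multiplies the distractor's mean rate: 0 silences it, 1 makes
the stimuli indistinguishable on average. Every timing-network pyramidal
cell drives an AMPA-only, spatially non-selective conductance onto every
decision-network pyramidal cell at one fifth of the extrinsic AMPA
strength (scaled by ring size so the summed drive matches the reference
network). The decision is the first of the two response-field populations
whose mean SDF reaches 20 Hz, the crossing time is the decision time, and
simultaneous same-sample crossings are broken by the higher SDF and then
by coin flip. Stimuli switch on after a settling window (default 300 ms)
so both circuits are in their background states at stimulus onset, and
decision times are measured from onset. Non-decision components of
reaction time are not modelled.

Speed and accuracy conditions impose a tight or loose temporal constraint
by running the timing network at the scale factor learned for a short or
a long interval. Trials that never cross are excluded from accuracy and
decision-time statistics and reported separately.

## What the synthetic protocols do and do not show

All inputs are generated: there is no experimental data anywhere in the
pipeline. The analyses in the test-suite and in `scripts/acceptance.R`
run at reduced scale - a 250-cell (timing) or 200-cell (coupled) ring,
0.1 ms Euler steps, tens of trials per condition - with conductances
rescaled as described so the population-level operating points match the
reference-size network. Two consequences of that scale are worth
stating plainly:

* Finite-size fluctuations are roughly twice those of the reference
  network. Interval estimates at a fixed `rho` have a coefficient of
  variation around 0.3 at 250 cells, dominated by stochastic nucleation
  of the bump; the mean estimates and their ordering in `rho` are robust,
  but per-trial precision targets inherited from larger networks (for
  example, learning to within 10 percent of a target interval measured
  over five trials) may not be reachable at this size.
* The spatially non-selective output of the timing circuit is strongly
  normalized by feedback inhibition at this scale: when the bump forms,
  background suppression cancels most of the bump's contribution to the
  summed pyramidal activity, so the gain-modulation contrast between
  speed and accuracy conditions is weak. Within-condition regularities of
  the decision task (accuracy falling and decision time rising with
  difficulty, chance performance for indistinguishable stimuli, positively
  skewed decision-time distributions, slower errors) do not depend on that
  contrast; the between-condition orderings do, and are correspondingly
  fragile at reduced scale.

## Numerical choices

* Forward Euler with `dt` 0.02 ms at reference scale, 0.1 ms in the
  reduced-scale protocols; halving `dt` changes threshold-crossing times
  by less than the across-trial standard deviation. Initial membrane
  potentials are spread uniformly between rest and just below threshold
  to avoid a synchronized onset volley.
* The noise-conductance update is exact for any `dt` (it is an OU bridge,
  not an Euler step).
* Ties in bump identification break toward the lowest neuron index;
  threshold crossings use the first at-or-above SDF sample.
* The dip statistic scans candidate modes with greatest-convex-minorant /
  least-concave-majorant deviations on the two step-corner sequences of
  the empirical CDF; p-values are Monte Carlo against the uniform null
  (the least favourable unimodal distribution). Fewer than four distinct
  values is reported as degenerate rather than tested.
* Gaussian profile fits rotate the profile so its maximum sits at the ring
  midpoint (deterministic initialization at the argmax), fit in rotated
  coordinates by Levenberg-Marquardt least squares, and map the centre
  back; fits are therefore invariant to shifts across the ring seam.
* The bootstrap for CV confidence intervals uses 2000 percentile
  resamples under the ambient RNG state.
* First-passage Monte Carlo uses Euler-Maruyama with `dt` 0.05-0.1 ms;
  paths that have not crossed by `mean + 12 SD` are counted and excluded,
  with a warning above 0.1 percent.

## Known limitations

Single-compartment neurons; no conduction delays, short-term plasticity,
or non-ring topologies. The reduction linearizes the interneuron
activation and ignores AMPA/GABA fluctuations, so its regime boundaries
correspond only qualitatively to the spiking network's. The timing-to-
decision coupling is unidirectional. The first-passage theory is the
saturating-noise approximation, accurate when `z0` exceeds a few multiples
of `sigma/sqrt(2 lambda)` and the threshold sits well above `z0`
(relative corrections are of order `(theta_z/z0)^-2`, a few percent at a
ratio of five); it is not an exact boundary-value solution of the OU
first-passage problem.
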