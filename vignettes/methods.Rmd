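---
title: "Mean-field prediction of population rate spectra and the anatomy of oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field prediction of population rate spectra and the anatomy of oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popspectra)
```

## The problem

Networks of spiking neurons generate oscillations that are visible in every
population's firing-rate power spectrum, even when the oscillation is
produced by a small sub-circuit and merely imposed on the rest of the
network. `popspectra` implements an analytical pipeline that (i) predicts
the population rate spectra of multi-population leaky integrate-and-fire
(LIF) circuits from their anatomy and physiology, (ii) decomposes the
dynamics into eigenmodes whose eigenvalue trajectories explain where the
spectral peaks come from, and (iii) computes an eigenvalue *sensitivity
measure* that attributes each peak's amplitude and frequency to individual
anatomical connections. The bundled worked example is an 8-population
model of a cortical column (layers 2/3, 4, 5, 6, one excitatory and one
inhibitory population each, 77&#8239;169 neurons).

## The model and its reduction

Each neuron is an LIF unit with exponentially decaying synaptic currents
(membrane time constant $\tau_m$, synaptic time constant $\tau_s$,
refractory period $\tau_{ref}$, threshold $V_{th}$ and reset $V_r$
relative to rest). The reduction proceeds in two steps.

**1. Stationary state (diffusion approximation).** The synaptic input to
population $i$ is summarised by its mean and variance,
$$\mu_i = \tau_m \Big(\sum_j K_{ij} W_{ij} \bar r_j
        + K_{ext,i}\, w_{ext}\, r_{ext}\Big),\qquad
\sigma_i^2 = \tau_m \Big(\sum_j K_{ij} W_{ij}^2 \bar r_j
        + K_{ext,i}\, w_{ext}^2\, r_{ext}\Big),$$
where $K$ is the indegree matrix (rows = targets), $W$ the synaptic
weight matrix in mV (PSC amplitude $\times \tau_s / C_m$), and the last
terms describe external Poisson drive. The stationary rates solve
$\bar r_i = \nu(\mu_i, \sigma_i)$ self-consistently, with $\nu$ the
first-passage-time rate of the LIF neuron under colored (synaptically
filtered) noise: the white-noise Siegert integral with threshold and reset
shifted by $\sigma\,(\alpha/2)\sqrt{\tau_s/\tau_m}$,
$\alpha = \sqrt{2}\,|\zeta(1/2)|$. `solve_selfconsistent()` finds the fixed
point by damped pseudo-time iteration (adaptive step, tolerance
$10^{-12}$ spikes/s), which follows the basin of the operative
low-rate state rather than jumping across it.

**2. Linear response.** Small fluctuations around the stationary state
obey a linear rate model with output noise. In Fourier space
$$Y(\omega) = P(\omega) X(\omega), \qquad
P(\omega) = (I - \tilde M_d(\omega))^{-1},$$
with white noise of spectral density $D_{ii} = \bar r_i / M_i$
(population size $M_i$; the flat "Poisson baseline"). The effective
connectivity combines anatomy, the transfer function $H_i(\omega)$ of the
receiving population, and the delay-distribution filter
$B_{ij}(\omega)$:
$$\tilde M_{d,ij}(\omega) = \tau_m\, K_{ij}\, W^{eff}_{ij}\,
H_i(\omega)\, B_{ij}(\omega).$$
The spectra are the diagonal of $C(\omega) = P D P^\dagger$.

### Transfer function

$H_i(\omega)$ is the modulation of a population's instantaneous firing
rate per mV of mean-input modulation. It is computed from the
Fokker-Planck linear response of the LIF neuron as a ratio of parabolic
cylinder functions of complex order $-\tfrac12 + i\omega\tau_m$ evaluated
at the (shift-corrected) threshold and reset, multiplied by the synaptic
low-pass $1/(1+i\omega\tau_s)$ and by the refractory compression factor
$(1-\nu\tau_{ref})$, so that $H(0) = \partial\nu/\partial\mu$ holds
exactly. A white-noise variant (no boundary shift) is available via
`transfer_function(..., synaptic_filter = FALSE)` for cross-checks.

Parabolic cylinder functions of complex order are not provided by any
R package; `popspectra` evaluates them in C++ through the
confluent-hypergeometric representation. The Kummer series suffers
catastrophic cancellation when both the order and the argument are large
(digit loss $\sim e^{2\sqrt{|a| z^2/2}+z^2/2}$); the implementation
estimates the loss per evaluation and switches from 80-bit to 128-bit
arithmetic where needed. This matters in practice: mean-driven working
points (e.g. $\mu \approx 14$ mV, $\sigma \approx 2.7$ mV) otherwise
produce spurious spectral resonances above 200 Hz. The implementation was
validated against an arbitrary-precision reference over the full working
range and against stochastic single-neuron simulations.

### The variance transmission channel

A presynaptic rate increment $\delta r_j$ changes both the mean
($\propto W_{ij}$) and the variance ($\propto W_{ij}^2$) of the input.
The classical formulation keeps only the mean channel,
$W^{eff} = W$. By default `popspectra` uses
$$W^{eff}_{ij} = W_{ij} + W_{ij}^2\,
\frac{\partial\nu_i/\partial\sigma^2}{\partial\nu_i/\partial\mu},$$
which makes every zero-frequency entry of $\tilde M_d$ equal the *full*
static gain $\partial \bar r_i / \partial r_j$ of the stationary map.
For inhibitory sources the two channels oppose each other, which weakens
effective inhibition onto strongly noise-driven populations by
10–20% in the bundled circuit. The variance channel is given the same
normalised frequency profile as the mean channel (a quasi-static
approximation; the exact noise-modulation response rolls off more slowly,
so high-frequency observables are approximated slightly conservatively).
`variance_channel = FALSE` restores the classical mean-only form. The
default was chosen because (a) it reproduces the static gain exactly and
(b) in a direct spiking simulation of the isolated layer-2/3 circuit the
resonance sits near 86 Hz, which the mean-only theory misses by ~20%
while the augmented theory reduces the error substantially.

### Delay averaging

Synaptic delays are Gaussian with mean $d_{ij}$ and spread
$\sigma_{d,ij}$, truncated to positive values. The filter
$B_{ij}(\omega)$ is the characteristic function of that truncated
density; it is evaluated through the scaled complementary error function
so that the Gaussian envelope $e^{-\sigma_d^2\omega^2/2}$ and the growing
truncation term cancel analytically (no overflow, valid at complex
$\omega$, which the stability analysis exploits). Wider delay spreads
compress the eigenvalue trajectories radially and thereby damp
high-frequency peaks; truncation matters whenever
$\sigma_d \gtrsim d$ (as for inhibitory connections of the bundled
circuit, $0.75 \pm 1$ ms, whose *effective* mean delay becomes
$\approx 1.14$ ms).

## Eigenmodes, sensitivity, stability

`decompose_modes()` diagonalises $\tilde M_d(\omega)$ per frequency into
bi-orthonormal left/right pairs ($v_i^T u_j = \delta_{ij}$) and relabels
modes across frequencies by greedy matching on the eigenvector overlap
$|v_i(\omega_k)^T u_j(\omega_{k+1})|$ (threshold 0.5, falling back to
nearest-eigenvalue matching at near-degeneracies; there is no canonical
tracking rule for such trajectories, so overlap matching is this
package's choice, validated by trajectory smoothness). Each trajectory
$\lambda_i(\omega)$ acts as the transfer function of its mode; the factor
$p(\omega) = 1/|1-\lambda_i(\omega)|$ sets the mode's contribution to
every population's spectrum, so peaks occur where a trajectory approaches
the critical value one.

The sensitivity of a tracked eigenvalue to a fractional change of one
indegree is
$$Z_{kl} = \frac{v_{c,k}\, \tilde M_{kl}\, u_{c,l}}{v_c^T u_c},$$
whose entries sum to $\lambda_c$ (used as a numerical invariant at
$10^{-10}$). Projecting each complex entry onto the unit vector from
$\lambda_c$ towards $1$ ($Z^{amp}$) and its perpendicular ($Z^{freq}$)
separates control of peak amplitude from control of peak frequency.
`minimal_circuit()` ranks connections by $|Z^{amp}|$ and $|Z^{freq}|$
(absolute values; signed variants are conceivable, and signs are retained
in all reports), accepts them greedily subject to a
stability guard (no trajectory with $\Re\lambda \ge 1$ and
$|\Im\lambda| < 0.05$ anywhere on a 4-Hz guard grid), rebuilds the
reduced circuit with `isolate_subcircuit()` — which moves the removed
connections' mean and variance into the external drive so every working
point is preserved exactly — and reports per-population recovery of peak
frequency and log-amplitude. Log-amplitude recovery is defined on
$L = \log_{10}(C_{peak}/(\bar r/M))$, i.e. relative to the Poisson
baseline; the reference level is configurable because "logarithmic peak
amplitude" admits several reasonable definitions.

For stability, the delay filter and transfer function are continued
analytically to complex frequency and `find_critical_frequency()` solves
$\lambda(\omega') = 1$ by damped complex Newton iteration started from
the real-axis closest approach (three nearby starts; residual target
$|\lambda-1| < 10^{-8}$). A mode is stable when $\Im(\omega') > 0$ —
perturbations decay at $\Im(\omega')$ per second while oscillating at
$\Re(\omega')/2\pi$ Hz; `hopf_scan()` bisects a perturbation strength for
the boundary $\Im(\omega') = 0$, the onset of sustained oscillations.

## The stochastic simulator (what it does and does not show)

`simulate_rates()` integrates the *same* delayed linear rate model with
output noise that the analytics describe: per-connection impulse-response
kernels (inverse FFT of $\tau_m H_i B_{ij}$, truncated at $10^{-6}$ of
their maximum, sampled so that tap $m$ carries the kernel value at exactly
lag $(m+1)\,dt$), Euler integration at $dt = 0.1$ ms, and white noise of
density $\bar r_i/M_i$. In the default averaged-kernel mode the simulated
system is mathematically identical to the analytic one, which makes the
Welch periodogram (`periodogram()`, non-overlapping 500-ms windows,
two-sided density normalisation) a sharp oracle: analytic spectra agree
with simulated ones within sampling error, and the suite requires at
least 90% of 40–300 Hz bins within three standard errors across ten
seeds. A per-draw delay mode exists as a realism check. What this does
*not* validate is the linear-response approximation itself: rectification
and saturation of real spiking neurons, oscillation-induced rate shifts
near instability, and shared-input correlations are all outside the
simulated model.

## The bundled microcircuit and its study conditions

The fixture transcribes the published parameter table of the companion
spiking model: pairwise connection probabilities (converted to real-valued
indegrees via $n_{syn} = \ln(1-p)/\ln(1 - 1/(N_{post}N_{pre}))$,
$K = n_{syn}/N_{post}$), population sizes, external indegrees with 8 Hz
Poisson drive, PSC amplitude 87.8 pA ($g = 4$, doubled 4E$\to$2/3E
weight), delays $1.5$ ms (excitatory) / $0.75$ ms (inhibitory), and
homogeneous neuron parameters ($\tau_m = 10$ ms, $\tau_s = 0.5$ ms,
$\tau_{ref} = 2$ ms, $V_{th} - V_r = 15$ mV, $C_m = 250$ pF). The loader
applies three stabilising modifications by default: the 4I$\to$4E
indegree is reduced by 15%, every delay spread is set to 1 ms, and the
external drive to 4E is reduced by 19%.

Two caveats are worth stating plainly. First, the three modifications do
not exactly preserve the working point under the mean-field equations:
exact mean-channel compensation of the 4I$\to$4E removal would require a
16.5% (not 19%) external reduction at the original rates, so the modified
model settles at somewhat lower rates (minimum $\approx 0.5$ spikes/s)
than the original circuit. `compensate_external()` is provided for
protocols that require exact working-point preservation. Second,
published analyses of this circuit report a low-$\gamma$ peak near 64 Hz
(reproduced here within a few Hz), a dominant high-$\gamma$ mode near
275 Hz (this pipeline places it near 240 Hz under the stated 1-ms delay
spread; with the companion model's original delay spread the same
machinery yields $\approx 287$ Hz, matching the interneuron-loop formula
value of 288 Hz), and an isolated layer-2/3 resonance at 87 Hz (a direct
spiking simulation agrees; the linear theory places the trajectory's
closest approach near 102 Hz in a regime where the spectrum is nearly
flat and the argmin is poorly conditioned). These residuals are inherent
to the reconstruction — the exact transfer-function variant and
compensation calibration behind the published numbers are not fully
specified — and are reported as-is rather than tuned away.

## Numerical choices at a glance

* Frequency grid: 0–500 Hz at 1 Hz, shared by all objects; peaks refined
  by quadratic interpolation on log-power (reported bands: low-$\gamma$
  30–90 Hz, high-$\gamma$ 150–400 Hz, both configurable).
* Stationary solver: adaptive damped iteration, tolerance $10^{-12}$
  spikes/s, budget $10^5$ iterations; non-convergence is flagged, not
  thrown.
* Siegert integrand evaluated via the scaled complementary error
  function; for shifted thresholds more than 25 noise units above the
  mean, the closed-form subthreshold asymptotic replaces quadrature.
* Transfer function: exact ratio form up to $|\omega\tau_m| = 60$, then
  the $1/\sqrt{i\omega\tau_m}$ asymptotic matched continuously at the
  switch point.
* Problem sizes used by the test-suite oracles: two- and three-population
  circuits, 8–20 s of simulated time at $dt = 0.1$ ms, ten seeds; the
  full microcircuit pipeline runs on the 1-Hz grid in a few seconds.

## Known limitations

The framework is linear: peaks whose eigenvalue crosses unity (the
high-$\gamma$ regime of the bundled circuit verges on this) are predicted
only in tendency. Single-neuron statistics (CVs, autocorrelations) are
outside the scope of the rate-level description. The variance channel's
frequency profile is quasi-static. Only Gaussian (truncated) delay
distributions ship, although the delay filter accepts any density in
principle. Sensitivity is first-class for indegrees only; weights,
delays, and the excitation-inhibition ratio would require the analogous
derivative through their own parametrisation.
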