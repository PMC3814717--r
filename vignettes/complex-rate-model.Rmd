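---
title: "A complex-valued firing-rate reduction of integrate-and-fire populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A complex-valued firing-rate reduction of integrate-and-fire populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cvrate)
```

## The problem

The average firing rate of a large population of spiking neurons is often
modeled by a single relaxation equation, the *classic rate model*

$$\frac{dr}{dt} = \lambda\,(r - r_\infty(t)), \qquad \lambda < 0,$$

which pulls the rate toward the steady-state value $r_\infty$ set by the
instantaneous input. This description fails whenever spikes across the
population transiently align: a step of the common input to a
weakly-noisy population produces *ringing* of the population rate at the
firing frequency (partial spike synchronization), which no single real
exponential can represent.

`cvrate` implements a minimal extension that captures this: the rate is
promoted to a complex variable $\hat r(t)$,

$$\frac{d\hat r}{dt} = \lambda\,(\hat r - r_\infty), \qquad
  \lambda \in \mathbb{C},\ \mathrm{Re}\,\lambda < 0,$$

and the observable population rate is $\mathrm{Re}\,\hat r$. The complex
$\lambda$ is not fitted ad hoc: it is the dominant nonzero eigenvalue
$\lambda_1$ of the Fokker-Planck operator governing the
membrane-potential density of the underlying integrate-and-fire
population. Truncating the eigenfunction expansion of the density to the
stationary mode plus the $\lambda_1$ mode (and its conjugate) yields
exactly the complex ODE above. Its imaginary part sets the frequency of
rate transients, its real part their decay.

## Spiking models and input

Three integrate-and-fire variants share the membrane equation
$\tau_m\,dV/dt = f(V) + I(t)$ with

* LIF: $f(V) = -(V - E_L)$, hard threshold $V_{th}$;
* QIF: $f(V) = V\,(V - V_T)/\Delta_T$, spike at $+\infty$, reset at
  $-\infty$;
* EIF: $f(V) = -(V-E_L) + \Delta_T\,e^{(V - V_T)/\Delta_T}$, spike at
  $+\infty$.

Default parameters (mV, ms): LIF $V_{th}=20$, $V_r=10$, $E_L=0$; QIF
$V_T=0$, $\Delta_T=10$; EIF $V_T=10$, $\Delta_T=1$, $E_L=0$, $V_r=3$,
$\tau_{ref}=2$; all with $\tau_m=10$. The input is
$I(t) = I_0(t) + \sigma(t)\sqrt{\tau_m}\,\eta(t)$ with unit-intensity
white noise $\eta$, so a free (thresholdless) membrane has voltage
variance $\sigma^2/2$. Internally everything is in mV and ms; rates are
reported in Hz at the interface.

The infinite QIF/EIF thresholds are truncated at a numerical ceiling
($V_T + 10\,\Delta_T$ for the EIF, $\pm 300$ mV for the QIF). For the QIF
the deterministic traversal time of the discarded tails,
$\tau_m\!\int\! dV/(f+\mu)$, is added back analytically as a spike
latency and reset hold (`tail_times()`); noise is negligible there
because the drift grows quadratically.

## Fokker-Planck machinery

`fp_steady_state()` integrates the stationary flux/density pair downward
from the absorbing boundary (density zero at threshold; flux
discontinuity equal to the firing rate at the reset potential), with the
refractory probability mass $r_\infty\tau_{ref}$ included in the
normalization. `fp_isi_cv()` obtains the rate and ISI CV from the first
two first-passage-time moments, computed by stable exponentially-weighted
recursions of the backward equations. Within every grid cell the
integrating-factor exponent is quadratic (drift linear in $V$); the cell
updates expand around the cell's upper edge to second order, which keeps
the recursions accurate in strongly drift-dominated (stiff) regions where
a midpoint rule loses an order of accuracy. Default grid spacing is
$2^{-4}$ mV (steady state/CV) and $2^{-6}$ mV for the eigenvalue solver,
whose real part converges more slowly; halving either spacing moves the
results by well under 0.1%.

`fp_eigenvalue()` locates $\lambda_1$ three ways:

* **LIF/EIF** -- complex threshold integration of the eigenmode equations
  with a reset-flux factor $e^{-\lambda\tau_{ref}}$, giving a
  characteristic function $F(\lambda)$ (the flux at the lower boundary)
  whose root is found by Newton-Raphson from the universal-fit initial
  guess plus a lattice of 15 perturbed restarts. Nearby subdominant and
  spurious roots exist, so all converged roots are collected and the one
  with the largest real part is reported. The analytic special-function
  (Kummer) route for the LIF is avoided deliberately: its scaled argument
  $(V-\mu)^2/\sigma^2$ reaches $10^2$--$10^3$ at low-noise operating
  points and overflows IEEE doubles; the threshold-integration
  characteristic equation is exact for the linear drift and numerically
  bounded.
* **QIF** -- the substitution $V = b\tan(\theta/2)$ maps the quadratic
  model (spike at $+\infty$, reset at $-\infty$) onto a diffusion on the
  circle with no reinjection discontinuity; the generator, expanded in a
  truncated Fourier basis (100 modes by default, converged to <0.5%), is
  diagonalized directly. The Itô correction of the coordinate change is
  included in the drift.
* **PDE oracle** -- `fp_pde_transient()` integrates the full
  Fokker-Planck PDE (Crank-Nicolson in time with a short backward-Euler
  startup to damp the initial shock, Scharfetter-Gummel exponential
  fluxes in voltage, delayed reinjection) after a 1% step of the mean
  input; `fit_damped_cosine()` recovers decay and frequency from the rate
  transient. This route shares no code with the spectral solvers and is
  the acceptance oracle: agreement is a few percent at low CV.

`fp_linear_response()` computes the first-order rate modulation for a
sinusoidal perturbation of the mean input by two threshold-integration
sweeps per frequency (LIF/EIF) or a linear solve in the Fourier basis
(QIF). At the 50 Hz / CV 0.1 baseline all three spiking models show a
gain resonance at the firing rate; at CV 0.7 the resonance is gone.

## The universal eigenvalue map

Expressed as a function of the *output* statistics $(r_\infty, CV)$, the
dominant eigenvalue collapses across models onto

$$\lambda \approx 2\pi r_\infty\left(-\pi\,CV^2 + i\right)
  \qquad (r_\infty \text{ in kHz}),$$

implemented by `lambda_fit()` / `lambda_from_fit()`. The imaginary part
equals the firing rate because the ringing after a transient is spaced by
the interspike interval; the quadratic real part is the Gaussian-ISI
renewal limit (phase diffusion accumulates variance $CV^2$ per period).
Our own reproduction puts the real coefficient within $[0.78, 1.05]\pi$
and the imaginary ratio at $1.00 \pm 0.05$ for CV up to $\approx 0.4$.

**Validity domain.** Above CV $\approx 0.45$ the collapse degrades: the
decay grows faster than quadratically, the LIF/EIF eigenvalue can become
purely real, and the QIF oscillation frequency rises above the firing
rate (ratio 1.31 at CV 0.5, 1.96 at CV 0.72 -- a parameter-free property
of the quadratic model, which we verified against the PDE oracle to 1%).
The package therefore treats $CV \le 0.75$ as the nominal fit domain but
quantitative accuracy holds below $CV \approx 0.4$; one deliberately
strict validation test in the suite asserts a $\pm20\%$ band on the
imaginary ratio over the whole domain and fails, by design, at its
high-CV edge -- the measured dispersion there is genuine physics, not a
solver artifact.

## Rate models in practice

`integrate_complex()` advances the complex ODE with the quasi-static
closure: at every 0.1 ms step the instantaneous drive
$(\mu(t), \sigma(t))$ is mapped through a precomputed `operating_table`
(bilinear interpolation on a $(\mu, \sigma)$ grid; inverse lookups by
Newton on the interpolant; no silent extrapolation) to
$(r_\infty, CV)$, $\lambda$ follows from the map, and the linear ODE is
advanced exactly over the step. Negative transient rates are reported
as-is (the model is linear) but floored at zero wherever they feed a
variance. `integrate_classic()` provides the single-time-constant
baseline, with `fit_classic_lambda()` reproducing the least-squares
step-response calibration of its decay rate against a simulated
population. The linear response of the complex model is

$$G(\omega) = \tfrac12\left[\frac{\lambda}{\lambda - i\omega} +
  \frac{\lambda^*}{\lambda^* - i\omega}\right],$$

with DC gain $dr_\infty/d\mu$, a peak at $\omega \approx |\mathrm{Im}\,
\lambda|$ (i.e. at the firing rate), and phase lag strictly inside
$(0, \pi)$ -- which is why a single excitatorily self-coupled unit cannot
sustain oscillations.

## Monte-Carlo simulators

`simulate_population()` and `simulate_spiking_network()` integrate the
stochastic membrane equations with a Heun (trapezoidal) drift update and
additive Euler-Maruyama noise, linear interpolation of threshold-crossing
times with sub-step carryover at reset, and -- for the hard LIF threshold
only -- the Broadie-Glasserman-Kou continuity correction (the barrier is
lowered by $0.5826\,\sigma\sqrt{dt/\tau_m}$ to compensate the
within-step excursions a discretely monitored diffusion misses). These
choices matter: plain Euler with step-granularity thresholds biases the
EIF rate by $\approx 0.35\%$ at $dt = 0.02$ ms and the LIF rate by
$\approx 1\%$, far above the Monte-Carlo error of the validation runs,
whereas the implemented scheme agrees with the Fokker-Planck predictions
within ~2 standard errors at $2000 \times 20$ s scale. Default steps:
0.05 ms (LIF), 0.02 ms (QIF/EIF). Every neuron draws from its own
counter-based xoshiro256++ stream (stream index = neuron index), so
enlarging a population does not reshuffle existing neurons' noise and
runs are bit-reproducible across platforms independently of R's RNG.

## Excitatory-inhibitory networks

Two populations of $N = 5000$ neurons each are coupled by instantaneous
(delta) synapses with fixed in-degree $K = 200$ per synapse class; a
presynaptic spike augments each target's potential by the connection
strength at the next step. The in-degree and the
reduction of the four synaptic strengths to the scanned pair are
configuration choices of the package: strengths onto excitatory
neurons are $J_{EE} = w_E$, $J_{EI} = w_I$; strengths onto inhibitory
neurons are scaled by the fixed ratio $g = 0.5$. We verified that some
asymmetry between the E and I drives is *required*: with perfectly
symmetric drive the two-unit complex rate network collapses to one unit,
whose phase-lag constraint forbids a Hopf bifurcation at any coupling.

Mean-field coupling (`coupled_drive()`): with rates in kHz,

$$\mu_a = \mu_x + K\tau_m\,(J_{aE}\,r_E - J_{aI}\,r_I), \qquad
  \sigma_a^2 = \sigma_x^2 + K\tau_m\,(J_{aE}^2\,r_E + J_{aI}^2\,r_I).$$

The two-unit rate network (`simulate_rate_network()`) refreshes
$(r_\infty, CV, \lambda)$ from the instantaneous drives every step.
`find_fixed_point()` solves the self-consistency by damped Newton;
`stability_at()` builds the $4\times4$ Jacobian over the real and
imaginary rate components by central finite differences of the full
right-hand side (relative step $10^{-4}$); `scan_stability_map()` sweeps
$(w_E, w_I)$, recording per-cell failures (e.g. runaway excitation)
without aborting. The default scanned region, $w_{E,I} \in [0, 0.05]$ mV
with $K = 200$, brackets the bifurcation line: the external drive is
calibrated so each population fires at 50 Hz with CV 0.1 when uncoupled,
and the synchrony instability then sets in at couplings
$K\tau_m w\,dr_\infty/d\mu \sim |\mathrm{Re}\,\lambda| / |\lambda|$,
i.e. at weights of a few hundredths of a mV.

Phenomenology reproduced by the scan and the forward simulations: the
purely excitatory row is entirely stable; increasing $w_E$ at moderate
$w_I$ crosses a single bifurcation line into a limit-cycle region; inside
it both units oscillate in phase (inhibition trailing excitation by
0.5--2 ms) at a frequency tied to the baseline firing rate, approaching
50.0 Hz for the least-perturbed limit-cycle cells. Scaled-down spiking
networks ($N = 1000$, $K = 40$, weights $\times 5$ so the mean coupling
is preserved; the variance is then $5\times$ larger, which shifts the
line) agree with the analytic verdicts away from the bifurcation line.
Synchrony in a spiking raster is declared when the spectral peak of the
population rate exceeds $1000\times$ the flat Poisson shot-noise floor
$\bar r / N$: finite-size noise filtered by the weakly damped resonance
reaches $\sim10^2\times$ the floor in asynchronous cells, genuine limit
cycles $\sim10^4\times$, so the threshold sits in an order-of-magnitude
gap. (For the noiseless rate network the simpler 10$\times$-median rule
is used.)

## Stimulus protocols and the model-fidelity score

`stimulus_spec()` renders constant, step, piecewise-constant and
five-sinusoid inputs (61, 50, 33, 13.1, 7.9 Hz, random phases from a
dedicated seeded stream). The per-sinusoid amplitude is a free parameter
of the protocol; the package default of 1 mV drives rate excursions of
order $\pm50\%$ of the 50 Hz baseline, large enough that partial
synchronization is clearly expressed above the finite-population
sampling noise of the reference PSTH. `compare_rate_models()` scores both rate models
against a simulated population PSTH (1 ms bins, 2 ms Gaussian smoothing)
with the shifted correlation coefficient (`shifted_correlation()`,
Pearson maximized over $\pm5$ ms shifts; sensitivity at 2/10 ms is
similar). At CV 0.1 the complex model scores $\approx 0.89$ against
$\approx 0.61$ for the CV-optimal classic model; at CV 0.8 both exceed
0.94 (2000 neurons, 10 s).

```{r example}
p  <- neuron_params("eif")
op <- calibrate_operating_point(p, rate_hz = 50, cv = 0.1)
fp_eigenvalue(p, op$mu, op$sigma)          # lambda_1 ~ -0.0099 + 0.3144i /ms
compare_rate_models(p, 50, 0.1, n_neurons = 500, duration = 3000, seed = 1)
```

## What the synthetic conditions do and do not show

All validation data are generated by the package itself under the
diffusion approximation the theory assumes: white-noise input, identical
neurons, instantaneous synapses, fixed in-degree. Passing tests
demonstrate internal consistency of the reduction (spectral solvers vs
direct PDE vs Monte-Carlo) and reproduction of the claimed phenomenology;
they do not speak to conductance synapses, synaptic filtering,
heterogeneity, or correlated inputs, all of which are outside the model
class. The diffusion approximation itself requires high input rates;
results at very low noise ($\sigma \lesssim 0.2$ mV) or deep
subthreshold drive are increasingly delicate numerically and
scientifically.

## Numerical choices and degenerate inputs

* $\sigma = 0$ is rejected by the Fokker-Planck solvers (deterministic
  closed forms apply); calibration keeps $\sigma > 10^{-3}$ mV.
* First-passage recursions that overflow (escape times beyond double
  range) report rate 0 and CV 1 rather than NaN, so operating tables
  remain usable in deeply subthreshold corners.
* The damped-cosine fit restricts its spectral initialization to
  < 300 Hz and bounds $|\omega| < 2.5$/ms to avoid aliased optima.
* Operating-table lookups refuse to extrapolate outside the grid hull;
  the network integrator reports the time at which a trajectory left the
  hull.
* Problem sizes of the validation suite (grid resolutions, 2000-neuron
  populations, 20 s runs, $11\times11$ stability scans, $N=1000$ spiking
  networks) were chosen so each check resolves its target quantity
  comfortably; the methods scale to larger runs unchanged.

## Known limitations

* Only the dominant eigenvalue pair is kept; multi-mode corrections and
  the extra time-dependent terms of a fully time-dependent Fokker-Planck
  treatment are omitted by design (they matter only for very fast, large
  input swings).
* The universal map underestimates the decay above CV $\approx 0.75$
  (faster-than-quadratic regime) and misses the QIF's rising oscillation
  frequency above CV $\approx 0.45$.
* The quasi-static closure breaks for drives that traverse the operating
  table hull faster than the membrane time constant.
* The voltage-domain PDE oracle cannot resolve ringing for the QIF above
  CV $\approx 0.3$ within its blanking window; spot checks with shorter
  windows were used there instead.
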