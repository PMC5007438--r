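---
title: "Models and methods behind optoloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optoloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoloop)
```

optoloop is a desk-scale re-creation of an automated optogenetic
feedback-control platform: a turbidostat culture of *E. coli* carrying
the green/red light-switchable CcaS/CcaR two-component system, sampled
by flow cytometry every 10 minutes, with a digital controller choosing
the green LED intensity applied until the next sample.  Everything that
was hardware in the laboratory — culture, cytometer, pumps, LEDs — is
replaced here by explicit stochastic models, so that the control and
estimation algorithms can be exercised, dissected and stress-tested in
seconds.  This vignette records the models, the parameter choices and
the design decisions, and what conclusions the simulations do and do
not support.

## The gene-expression plant

Expression of the fluorescent reporter is described by three coupled
linear ODEs for mRNA $r$, immature protein $p$ and fluorescent protein
$g$:

$$
\dot r = b_{r0} + b_{r,\mathrm{gain}}\,u - d_r r, \qquad
\dot p = b_p r - (d_p + k_m) p, \qquad
\dot g = k_m p - d_p g .
$$

Transcription has a basal rate $b_{r0}$ (CcaS retains background kinase
activity in the dark) plus a light-driven term; proteins are diluted by
growth at $d_p$ and the fluorophore matures at $k_m$.  Dividing each
species by its un-induced steady state gives the *fold-change* model
used by the controllers:

$$
\dot R = d_r + b_r u - d_r R, \qquad
\dot P = (d_p + k_m)(R - P), \qquad
\dot G = d_p (P - G),
$$

with rest state exactly $(1,1,1)$ and steady state
$G_{ss} = 1 + (b_r/d_r)\,u$ under constant $u$.  The production
constants $b_{r0}, b_p$ cancel in the transformation; the four
remaining rates are the ones identified from data.  The form of the
first equation matters: writing the drive as $d_r + b_r u$ (rather
than, say, $b_r(1+u)$) is what the exact coordinate change produces,
and it is the only member of that family whose rest state is exactly
$(1,1,1)$ when $b_r \neq d_r$.  With the nominal maximum-likelihood
rates

```{r}
nominal_model_params()
```

the steady-state gain is $b_r/d_r = 1.0094$, so $u = 1$ yields
$G_{ss} = 2.0094$ — one unit of input buys one extra fold change, to
within a percent.

Integration uses `deSolve::lsoda` with relative tolerance $10^{-8}$,
segment-by-segment between input breakpoints, because the digital
controllers hold the input constant between samples (zero-order hold).

## Dose-response input map

The controllers think in fold-change input units $u$; the hardware
applies a green intensity $U \in [0, 100]$ %.  The two are linked by a
static dose-response curve $u = f(U)$, modelled as a Hill function with
zero basal offset,

$$ f(U) = u_{\mathrm{sat}}\frac{U^n}{K^n + U^n}, $$

defaults $u_{\mathrm{sat}} = 2.016$, $K = 20$, $n = 3$.  These were
chosen so that $f(0)=0$, $f(100) = 2$ additional fold changes, and
$f(60) \ge 0.95\,f(100)$ — the curve is almost flat above 60%
intensity, which is why the MPC input cap defaults to 60%.
`fit_dose_response()` re-estimates the three constants from
steady-state measurements; inversion (`dose_response_invert()`) clips
to $[0,100]$ and flags requests beyond $f(100)$ as saturated.

## Discretization, delay and the disturbance channel

`discretize()` converts the fold-change model to the exact
zero-order-hold discrete system at $T_s = 10$ min.  The system matrix
is lower-triangular with eigenvalues $-d_r$, $-(d_p+k_m)$, $-d_p$, so
$e^{AT_s}$ and $\int_0^{T_s} e^{As}\,ds\,B$ have closed forms in those
eigenvalues; the implementation evaluates them directly (vectorized
over parameter draws, which is what makes per-particle propagation in
the filter cheap) and nudges eigenvalues apart by one part in $10^7$
in the measure-zero event of coincidence.  The closed form agrees with
dense matrix-exponential and high-accuracy ODE references to
$\sim 10^{-12}$ in the tests.

Two augmentations reflect the physical loop: the applied input acts one
sampling period late (unmodelled CcaS–CcaR activation dynamics), so
commands pass through a one-slot delay buffer; and an additive
disturbance input $d$ enters beside $u$, zero in the nominal system and
estimated online — a persistent non-zero $\hat d$ is the model's way of
saying "something has changed".

## PI control, units and gain scheduling

The PI law is positional with the integral updated first and clamped:

$$
u_I \leftarrow \mathrm{clip}(u_I + K_I e,\ \mathrm{clamp}), \qquad
u = \mathrm{clip}(K_P e + u_I,\ [u_{\min}, u_{\max}]),
$$

with $u_I(t_0) = 0$.  The gains used throughout are the published ones:
$(K_P, K_I) = (80, 8)$ for approach, $(160, 20)$ after gain scheduling,
and $(6000\text{–}10000, 45)$ for the growth loop, whose integral is
clamped to $[0, 60]$.

PI gains only have meaning relative to the units of the error signal.
The platform's measured output is the mean FSC-H-normalized
fluorescence, and the printed channel magnitudes (events around 6,000
a.f.u. of FL1 on 30,000 a.u. of forward scatter for cells induced
roughly 1.4–2-fold above baseline) put the un-induced baseline of that
quantity near 0.14.  The scenario harness therefore runs the
expression-control PI on $y = 0.14\,G$.  This calibration matters: in
raw fold-change units the same printed gains multiply an error seven
times larger and the linearized loop crosses $-180^\circ$ with
magnitude above one.  At the 0.14 scale the loop reproduces the
documented closed-loop phenomenology — settling onto constant targets
in a few hours, damped recovery under the scheduled high gains, and
strong attenuation with a large phase lag on a 2-hour sinusoid.

Gain scheduling swaps in the second gain pair exactly once, triggered
either at a fixed time (the disturbance experiments switch an hour
before the perturbation) or after the output has stayed in the
tolerance band for three consecutive samples; the integral term is
carried over unchanged, so the transfer is bumpless at zero error.

## Model predictive control

Each step, the MPC minimizes over the next $N = 6$ inputs (one hour of
lookahead)

$$
\sum_{j} \big(\hat G_{k+j} - G^{\mathrm{ref}}_{k+j}\big)^2
  + \lambda \sum_j (\Delta u_j)^2,
  \qquad u_j \in [0, f(U_{\mathrm{cap}})],
$$

where predictions run through the delay buffer and the current
disturbance estimate, $\lambda = 10^{-3}$ merely discourages input
chatter, and $U_{\mathrm{cap}} = 60$ %.  The box-constrained problem is
solved with L-BFGS-B, warm-started from the previous solution shifted
by one step; only the first input is applied, after inversion through
the dose-response curve.  An optional quantized mode restricts inputs
to a finite level set and optimizes by batch enumeration — small
instances of that mode are checked against naive exhaustive search in
the tests.  With the increment penalty set to zero the optimal cost is
non-decreasing in the horizon length (longer windows add non-negative
terms), which the tests verify; longer horizons still help the *closed
loop* because they anticipate reference changes.

## Joint state and parameter estimation

Only $G$ is measured, and the culture's dynamics drift between days and
within a day, so the MPC runs on a bootstrap particle filter over the
joint space of states, the four rates and the disturbance $d$
(2,000 particles by default).  Parameters evolve by Liu–West kernel
shrinkage on the log scale (shrinkage 0.98), $d$ follows a bounded
random walk ($\sigma_d = 0.01$ per 10-min step — sized for the
hour-scale perturbations the channel is meant to flag, and kept well
below the per-sample measurement noise so the filter does not chase
single outliers), the likelihood is Gaussian
with $\sigma_y$ equal to 3% of the predicted signal, and systematic
resampling triggers when the effective sample size drops below half the
ensemble.  Missing measurements propagate the ensemble without
reweighting, so the loop coasts over a failed sample.  A degenerate
update (all likelihoods zero) resets the weights uniformly with a
warning rather than dying mid-experiment.

Measurements are mapped into fold-change units by dividing the
normalized fluorescence by the day's un-induced baseline, estimated
from pre-induction samples; the filter and the MPC never see the true
plant, only this signal.

### What is, and is not, identifiable

`fit_model_ml()` calibrates the four rates from characterization traces
(a step response plus a few closed-loop responses) by multistart
nonlinear least squares on the deterministic ZOH predictions.  From
noise-free data the four rates are recovered essentially exactly.  With
realistic (5%) measurement noise, however, the problem is practically
unidentifiable in two directions: the data constrain the steady-state
gain $b_r/d_r$ and the slow pole $d_p$ well, but the fast mRNA pole
$d_r$ (time constant comparable to the 10-min sampling period) and the
maturation rate $k_m$ trade off along a likelihood ridge — solutions
with $k_m \to 0$ and a near-double pole at $d_p$ predict trajectories
within a few hundredths of a fold change of the true model, far below
the noise.  The package treats this honestly: the Monte-Carlo recovery
test documents the ridge, and the closed-loop controllers do not rely
on point identification — the particle filter's continual re-estimation
is exactly what makes control robust to it.

## Synthetic cytometry

`synthesize_sample()` draws correlated log-normal scatter channels
(FSC-H, FSC-A, SSC-A share a latent size factor, reproducing the
positive size–scatter correlation that justifies FSC-H normalization)
and sets `FL1 = FSC_H * (background + gain * G) * noise` with mean-one
log-normal noise of CV 0.3, so the gated normalized mean is an unbiased
estimate of `background + gain * G`.  Gating discards events below an
11,000 a.u. FSC-H threshold or an 800 a.f.u. fluorescence threshold and
outside a wide ellipse in FSC-A × SSC-A; the published gate ellipse
coefficients are not available, so the default is calibrated to retain
about 75% of generated events (≈15,000 of a 20,000-event sample),
and is fully configurable.  The generator emulates event-level spread,
size correlation and gate loss; it does not emulate instrument
compensation, multi-population structure, debris clusters or
acquisition-time drift, so passing tests say nothing about those
aspects of real cytometry data.

For speed, the scenario harness defaults to an equivalent shortcut
(`meas$mode = "direct"`): multiplicative Gaussian noise of 3% applied
to the true fold change, which is the large-$n$ limit of the event
pathway; the full cytometry pathway is exercised explicitly in the
tests and available per scenario.

## Growth-rate control

In the turbidostat, biomass obeys $\dot x = \mu x - (u/V) x$ with
constant volume $V = 17.5$ ml and OD setpoint 0.1.  A fast inner PI
loop (gains set for ~1-min settling, consistent with an inner loop that
is much faster than growth) actuates the dilution rate, so at
regulation equilibrium $u/V = \mu$: the influx pump signal *is* a
growth-rate sensor.  `estimate_growth_rate()` smooths the 1-Hz pump
samples with a causal exponential moving average (5-min time constant)
and divides by $V$; doubling times follow $T_d = \ln 2 / \mu$.

The growth plant maps green light to growth through a first-order lag
(time constant 45 min, the simplest dynamics consistent with
multi-hour settling and PI sufficiency) toward a Hill-shaped steady
state normalized to span exactly $\mu = 0.0035$ min⁻¹ under full red
(doubling ~200 min) to $0.0139$ min⁻¹ under full green (doubling
~50 min).  The published record quotes both ~50 and ~55 min for the
full-green doubling time; the defaults use $\mu = 0.0139$ min⁻¹
(~50 min) and this discrepancy is simply noted.  An optional drift term
raises the minimum rate linearly after 12 h of predominantly red
illumination, emulating the selection-driven loss of light sensitivity;
under drift the outer PI compensates by lowering green — the downward
input trend the tests check.  The outer loop updates once per minute
with the published gains.

## Disturbance models

* **Medium shift** (M9 → LB): the dilution rate jumps to
  $\ln 2 / T_d^{\mathrm{new}}$ (doubling 38 → 25 min).  In raw
  coordinates this halves steady-state expression, so the measured fold
  change (normalized by the pre-shift baseline) collapses — which is
  why the frozen-input comparison culture falls out of the band and
  stays there.  The shipped preset uses a target of 1.4 fold: with the
  output halved, recovering a 2-fold target would need
  $u \approx 3$, beyond the dose-response maximum of ~2; the platform's
  input authority bounds what any controller can rescue.
* **Temperature shift** (37 → 28 °C): all six raw rates are scaled by a
  common factor (default 0.5, ramped linearly over 30 min, leaving the
  post-shift doubling time above an hour) and transcription gets an
  extra factor 0.8.  The uniform part slows everything without moving
  steady states — the generic outcome of rate-balanced cooling — while
  the production penalty produces the slow expression decline seen in
  an uncontrolled culture.
* **Input offset**: from onset, every commanded intensity is reduced by
  half the intensity in effect at the onset, floored at zero —
  mimicking damage to the light-delivery path.
* **Additive output offset**: a constant added to the measurement,
  useful for probing estimator bias.

## Scenario harness and metrics

`run_scenario()` ties everything together at the 10-min cadence:
measure (through the configured noise path), run the controller, log,
and propagate the raw-coordinate plant exactly over the next interval.
All randomness flows from a single scenario seed, so traces are
bit-reproducible; replays apply a recorded input sequence open-loop on
a plant re-drawn with day-to-day variability (each rate and the
dose-response gain multiplied by independent log-normal factors,
σ = 0.15).

`tracking_metrics()` evaluates the ±5% tolerance-band conventions (of
the target level, the reference curve, or the maximum reference level,
per scenario), with "post-transient" defined as the first sample
opening three consecutive in-band samples.  Sinusoid phase is the lag
maximizing the cross-correlation with the reference on a 1-min
interpolation grid, in degrees; amplitude ratio is the SD ratio.
Band metrics are computed on the latent true output: measurement noise
corrupts what the controller sees, not the judgment of where the
culture actually was — at desk scale the latent state is available and
is what the band statement is about.  Polynomial smoothing of plotted
measurements is a presentation device only; metrics here use raw
samples.

## Problem sizes and numerical choices

Simulated experiments are 10–14 h (61–85 samples) for expression
control and 12–18 h at 1-s inner-loop resolution for growth control;
replay comparisons use 10 day-variability seeds and the calibration
study 20 noise seeds — sizes chosen so the whole suite runs in a few
minutes on a laptop while keeping Monte-Carlo error well inside the
asserted margins.  Stiff-capable `lsoda` at rtol $10^{-8}$ integrates
the plant; the exact ZOH closed form propagates the discrete model and
all particles; L-BFGS-B handles both the MPC (warm-started) and the
multistart calibration (log-parameter bounds $[10^{-4}, 1]$ min⁻¹).
Ties in the quantized MPC resolve to the first enumerated minimum;
`which.max` ties in phase estimation resolve to the smallest lag.

## Limitations

The plant is linear: the input-magnitude-dependent response speed of
the real two-component system appears only through the dose-response
nonlinearity, and no photocycle, phosphotransfer or read-through
mechanism is modelled.  Day-to-day variability is a single log-normal
draw per culture, not a within-day drift (except the growth-loop
sensitivity drift).  The cytometry generator is calibrated, not
instrument-derived.  Consequently, passing scenarios demonstrate that
the *algorithms* behave as documented under faithful operating
conditions — sampling cadence, delay, saturation, noise levels,
disturbance magnitudes — not that a wet-lab run would reproduce any
specific trajectory.
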