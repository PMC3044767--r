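---
title: "Models and methods: power-law transfer functions in a V1 hypercolumn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: power-law transfer functions in a V1 hypercolumn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ringcrf)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the parameters that matter and why
they have the defaults they do, and what the synthetic experiments can and
cannot show. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## 1. The scientific problem

Neurons in primary visual cortex (V1) show two robust response properties
that are hard to reconcile in one model. First, the width of the
orientation tuning curve is *contrast invariant*: raising stimulus contrast
scales the tuning curve up without broadening it. Second, the
contrast-response function (CRF) is sigmoidal on log-contrast and
*saturates at lower contrast than the feedforward (LGN) input does*.
Feedforward models explain the first property (with synaptic noise) but not
the second; classical recurrent models explain saturation but distort
tuning. The model family implemented here resolves the tension with a
single ingredient: an accelerating, threshold power-law transfer function,
$\nu = g\,\lfloor I - I_c \rfloor_+^{\beta}$ with $\beta > 1$, which
emerges when synaptic noise smooths the spike threshold.

## 2. The ring rate model

A hypercolumn is a ring of `N` excitatory (E) and `N` inhibitory (I) rate
units labelled by preferred orientation $\theta \in [-\pi/2, \pi/2)$, with
dynamics

$$\tau_A \dot\nu_A(\theta) = -\nu_A(\theta) + g_A\big\lfloor I_A(\theta)\big\rfloor_+^{\beta_A},$$

where the input combines an orientation-tuned LGN drive
$I_0(C)\,G(\theta-\theta_s;\sigma_{A,\mathrm{lgn}})$ (with
$G$ the pi-periodic Gaussian and $I_0(C) = \nu_0 \ln C$) and ring feedback
with pi-periodic Gaussian projection profiles of widths $\sigma_{AB}$ and
strengths $J_{AB}$ (inhibitory inputs carry a minus sign, and the
discretization carries a $1/N$ density factor so the strengths are
comparable across `N`).

**Contrast-invariance conditions.** Because the convolution of two
Gaussians adds variances, and a Gaussian raised to the power $\beta$ is a
Gaussian of width $\sigma/\sqrt\beta$, the total input keeps a single
Gaussian shape — and the output width $\sigma_{A,\mathrm{lgn}}/\sqrt{\beta_A}$
is then *exactly* contrast invariant — precisely when

$$\sigma_{AB}^2 = \sigma_{A,\mathrm{lgn}}^2 - \sigma_{B,\mathrm{lgn}}^2/\beta_B .$$

`design_widths()` returns these widths; `check_width_conditions()` reports
the residuals for arbitrary widths. With equal input widths the conditions
make inhibitory projections broader than excitatory ones (because
$\beta_I > \beta_E$).

**Steady states.** Under the Gaussian ansatz the fixed point reduces to two
scalar equations for the peak rates with *effective* couplings
$\tilde J_{AB} = J_{AB}\sqrt{2\pi}\,\sigma_{AB}\sigma_{B}/(\pi\sqrt{\sigma_{AB}^2+\sigma_B^2})$.
`solve_selfconsistent()` uses damped fixed-point iteration with a fallback
to bracketed root finding (scanning upward from rest for the first stable
crossing), which also captures two non-trivial regimes: exact suppression
($\nu_{E0}=0$ at large drive) and runaway (no reachable fixed point, flagged
`diverged` rather than failing). `integrate_ring()` — a second-order
explicit integration of the full ring with `dt = 1` ms — is the independent
oracle: the tests require solver and ODE to agree within 1%.

**Shape of the CRF.** At large drive the inhibitory rate approaches
$I_0/\tilde J_{II}$, so the excitatory population is eventually suppressed
(the CRF has an interior maximum — *supersaturation*) if and only if
$\tilde J_{EI} > \tilde J_{II}$. `classify_crf_shape()` labels the numeric
curve and reports agreement with this closed-form margin; the tests sweep
the two inhibitory couplings and require the two routes to agree. The
transition from non-saturating through flat-topped to supersaturating is
controlled almost entirely by the inhibitory couplings, not the excitatory
ones.

**Stability.** `stability_spectrum()` linearizes on the grid and returns
the spectrum of the $2N \times 2N$ operator. In the default configuration
the least-stable eigenmode is the *amplitude mode* — each population's
component is proportional to its steady profile — and slowing inhibition
(raising $\tau_I/\tau_E$) destabilizes it monotonically; the bisection
reports the critical ratio.

**Default parameters.** The coupling values of the source model are not
recoverable, so the defaults are the package's own choice, fixed once:
$\beta_E = 1.5$, $\beta_I = 2.2$ (matching the conductance-based fits
below), $g_E = 1$, $g_I = 3$ (inhibitory peak rates several times the
excitatory ones), LGN widths $15\sqrt{\beta_A}$ degrees so both output
widths are 15 degrees, $J = (J_{EE}, J_{IE}, J_{EI}, J_{II}) = (5, 3, 5.6,
4.3)$ and $\nu_0 = 1.5$. This configuration sits just on the
supersaturating side of the shape boundary (a flat-topped CRF, crossing to
the other regimes when $J_{II}$ is moved by roughly $\pm 30\%$), and it is
in the regime where the amplitude mode both dominates and can be
destabilized by slow inhibition, which is what the stability analysis is
about.

## 3. The conductance-based neuron

Single-compartment neurons with leak, transient sodium ($m^3 h$),
delayed-rectifier potassium ($n^4$), persistent sodium (instantaneous
$s_\infty$), A-type potassium ($a^3 b$, $\tau_b = 20$ ms) and slow
adaptation potassium ($z$, $\tau_z = 50$ ms) currents; $C = 1\,\mu F/cm^2$.
The conductance densities and reversal potentials of the two profiles are
in `channel_set()`: the profiles differ only in those densities (the
excitatory cell has double the delayed rectifier, a third of the A-current
and ten times the adaptation conductance of the inhibitory cell).

The gating curves themselves are a reconstruction. They were chosen, once,
to satisfy the qualitative constraints that define this model class — a
type-I (continuous) excitatory onset; a lower rheobase, lower high-input
gain and much stronger adaptation for the excitatory profile; spike
heights well above the -20 mV detection threshold — and, subject to those
constraints, to give the noisy transfer functions their convex, power-law
shape over the physiological range. The decisive element is the A-current window: a gently sloped
activation ($a_\infty$, midpoint $-50$ mV, slope 16) against a partially
non-inactivating availability curve ($b_\infty$ with a floor of 0.1,
midpoint $-58$ mV, slope 10) leaves a smooth, non-regenerative potassium
load of a few tenths of mS/cm² near threshold. That load widens the
current range over which noise smooths the threshold, which is what makes
the fitted exponents come out near 1.5 (E, rates 0–30 Hz) and 2.2–2.4
(I, rates 0–60 Hz) instead of collapsing toward 1.

Three deliberate consequences of this reconstruction are worth knowing.
First, the *inhibitory* cell's noise-free onset is subcritical (it jumps at
rheobase and has a narrow silent band just above it); with the calibrated
noise all operating-regime transfer is smooth, and every network experiment
runs with noise, but the type-I continuity property is only asserted for
the excitatory profile. Second, the same near-threshold conductance that
widens the noisy foot also bends the *noise-free* onset: the excitatory
cell's onset is continuous (rates climb from ~0.4 Hz just above rheobase)
and locally square-root-like only around 1–2 Hz, turning convex above
that, so a power-law fit of the noise-free onset over rates up to 15 Hz
returns an exponent near 1 rather than 0.5 — the corresponding acceptance
check reports this honestly. Third, the inhibitory cell accelerates
slightly during a constant-current trial (slow A-current inactivation)
rather than adapting; the excitatory cell adapts strongly, so the ordering
of adaptation between the two profiles — which is what matters for the
gain difference — is preserved.

**Noise calibration.** The white-noise current amplitude is set by
`calibrate_noise()` so the subthreshold voltage SD is 3–4 mV. The SD is
measured *at rest*, not just below rheobase: near rheobase the persistent
sodium and sodium-window currents cancel most of the membrane conductance,
so a 3–4 mV SD there would imply a several-fold weaker noise current and
the power-law foot of the f-I curve would collapse. The packaged value is
$\sigma_\eta = 2.45\,\mu A/cm^2\sqrt{ms}$ (SD 3.4 mV for E, 3.0 mV for I).

**Integration.** Second-order (Heun) steps at `dt = 0.05` ms, with the
noise sampled once per step at $1/\sqrt{dt}$ scaling and held across both
stages; gating curves are evaluated through fine interpolation tables. The
noise-free f-I curve changes by less than 1% when `dt` is halved (a test).
Spikes are upward crossings of $-20$ mV with a 2 ms lockout; mean-voltage
statistics clip samples above $-50$ mV.

**Leak-shift reduction.** `gl_shift_experiment()` measures how an added
leak $\Delta G$ acts on the noisy f-I curve. The fitted threshold moves
linearly, $\Delta I_c = V_c\,\Delta G$ with $V_c \approx 15$ mV (E) and
$19$ mV (I), with $R^2 > 0.99$. Because the three power-law parameters
trade off strongly on noisy data, the per-condition threshold is fitted
with the gain and exponent pinned to the baseline (the sensitivity of the
gain and exponent is then measured by one-at-a-time profile refits). The
exponent is stable to about 10%; the gain genuinely falls by roughly 20%
(E) to 50% (I) as the leak doubles — in this reconstruction the shunting is
not purely subtractive, and the corresponding acceptance check is reported
honestly rather than forced.

## 4. The spiking hypercolumn

400 E and 400 I neurons (tests and the acceptance script use documented
reduced sizes) on the same ring, all-to-all, with weights
$(G_{AB}/N_B)\,G(\theta_i-\theta_j;\sigma_{AB})$. The Table of integrated
conductances is $(G_{EE}, G_{IE}, G_{EI}, G_{II}) = (1, 1, 4, 2.6)$ in
mS·ms/cm²: each presynaptic spike injects that *integral* of conductance
through a difference-of-exponentials kernel ($\tau_{rise} = 1$ ms,
$\tau_{decay} = 3$ ms, reversal 0 mV for E and $-80$ mV for I — package
defaults, flagged as such). Projection widths come from `design_widths()`
evaluated at the fitted single-neuron exponents (1.47, 2.2) and the LGN
widths below.

**The LGN drive** (`cbm_lgn_drive()`) is the one place where this package
commits to a structural reading that the source text leaves open. Each
neuron receives an *untuned, contrast-independent baseline* near its
population's noisy current threshold (3.4 and 9.6 µA/cm²) plus a tuned
modulation whose amplitude follows the hyperbolic ratio
$\nu_{max} C^n/(C^n + C_{50}^n)$ with $C_{50} = 17.2\%$, $n = 1.4$,
$\nu_{max} = 7\,\mu A/cm^2$ onto E and 1.7 times that onto I, and tuning
widths 22° (E) and 24° (I). The baseline stands for background
thalamocortical drive: it sits below the noise-free rheobase (so a
noiseless, zero-contrast network is silent — a test), but with the
calibrated noise it produces a ~1–3 Hz spontaneous rate and, crucially, it
places the contrast modulation inside the power-law region of the
transfer function at *all* contrasts. Without it, drive at 1–3% contrast
(2–8% of the saturated amplitude) cannot move any neuron within reach of
threshold and the low-contrast half of every experiment is empty; no
choice of a single amplitude fixes that, because the same H-ratio has to
span a 43-fold range. The per-population amplitudes mirror the rate
model's per-population drive $I_{0A}$. The heterogeneity experiments
interpret their dimensionless peak-drive range [3.5, 4.5] relative to the
midpoint 4, i.e. as $\pm 12.5\%$ around $\nu_{max}$.

**What the network reproduces, and what it does not.** With these
conditions the simulated hypercolumn shows: an inhibitory CRF with
$C_{50}$ close to the LGN input's (15–17%); a total synaptic conductance
on excitatory cells rising by ~0.14 mS/cm² (about 70% of the resting leak)
between 1% and 64% contrast; voltage tuning substantially broader than
spike tuning; and spike-tuning widths stable to within roughly 10–20%
over 1–64% contrast once the responses leave the small-signal regime. Two
quantitative properties of the source results are *not* reached, and the
acceptance checks report them red rather than adjusting the conditions:
the excitatory CRF's semi-saturation stays near the input's (~20%) instead
of dropping to ~6%, because with the given integrated conductances and the
condition-matched widths the maximal convex part of the inhibitory
feedback (bounded by the inhibitory cell's convex range and rate ceiling)
is a few µA/cm², too small to cancel the drive's full span; and the width
invariance degrades at the lowest contrasts, where the tuned modulation is
within the noise and the effective transfer is locally linear, so the
width relaxes toward the LGN width before the power-law sharpening
engages. Both are the same physics the model itself predicts when the
power-law approximation fails at the edges of the operating range.

**Effective rate model.** `effective_rate_prediction()` solves, on the
ring, the fixed point of the fitted power laws with each neuron's synaptic
conductance load entering twice: as a current at the resting potential and
as a threshold shift $V_c\,\Delta G$. It reproduces simulated tuning
widths more faithfully than peak rates, and underestimates the excitatory
peak, consistent with the rate-model reduction being exact only where the
power-law fit is.

## 5. Fitting layer

All three fitters (threshold power law, pi-periodic Gaussian tuning curve,
hyperbolic-ratio CRF) profile their linear parameters exactly and optimize
the remaining ones by Nelder–Mead with fixed multi-start grids (recorded in
the objects). Standard errors come from the Gauss–Newton curvature at the
optimum; `bootstrap_hratio_se()` cross-checks them (the tests require
agreement within a factor of two). A CRF fit is `good` when all three
relative errors (SD/estimate) are below 0.15 — the exclusion rule used
throughout. Saturation classes: *supersaturating* if any measured response
below 90% contrast exceeds 1.05 times the fitted response extrapolated to
100% contrast; *non-saturating* if that extrapolation is below
$0.95\,R_{max}$; *saturating* otherwise. The reference for the 1.05 rule is
the extrapolated 100%-contrast response (a choice; the alternative
reference $R_{max}$ differs only for shallow fits). The power-law fitter
constrains the exponent away from zero because the power law degenerates
into a logarithm there (the V-I fits would otherwise slide into that
corner; the inhibitory V-I exponent in fact sits at the 0.2 bound).

## 6. Heterogeneity experiments

`sample_population()` draws per-neuron parameters from uniform ranges whose
widths scale with the mixing parameter: LGN ranges ($C_{50} \in [8,28]\%$,
$n \in [1,1.8]$, peak drive $\pm 12.5\%$) proportional to $P$, intrinsic
ranges ($g_{Ks,E} \in [0.5,6.5]$, $g_{Ks,I} \in [0.1,1.1]$ mS/cm², leak
reversal $[-77.5,-67.5]$ mV) proportional to $1-P$, all about fixed
midpoints. At $P=1$ only the input is heterogeneous; at $P=0$ only the
cells are.

Each neuron's CRF is read out at the stimulated orientation nearest its
preferred one (a handful of evenly spaced stimulus orientations): because
tuning width is contrast invariant, an orientation offset scales a CRF by
a contrast-independent factor, which leaves $C_{50}$, the exponent and the
correlation structure untouched and only costs signal-to-noise. Per-neuron
CRFs are fitted, classified and correlated exactly as above.

At reduced scale (384 neurons, 3 trials of 1.2 s per condition versus the
reference protocol's 10 × 1.5 s) the experiments reproduce the qualitative
diagnostics: supersaturating cells appear only under LGN heterogeneity and
only among excitatory neurons; the excitatory $C_{50}$–$n$ correlation is
clearly positive under intrinsic heterogeneity and near zero to weakly
negative under LGN heterogeneity, so the sign flip sits above $P = 0.5$ in
this reconstruction rather than at it. Good-fit fractions land around
70–75% rather than the reference 84%/92%: with a third of the reference
averaging time the relative-error criterion is simply harder to meet, and
the fraction is dominated by the excitatory cells, whose response
amplitudes are a few tens of Hz at most.

## 7. Reproducibility and problem sizes

Every stochastic step takes an explicit seed, and fixed seeds give
bit-identical rasters (a test). The deliverable contains no stored
simulation output: every number is recomputed at run time. The test suite
runs the network at 48–192 neurons per population with windows of 0.3–1.2
s; `scripts/acceptance.R` uses 400+400 neurons for the tuning/CRF
experiments and 192+192 for the heterogeneity experiments, with 2–4 trials
per condition. These sizes are the package's own desk-scale choices; the
generator defaults remain the reference conditions (400+400, 10 trials,
1.5 s windows).
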