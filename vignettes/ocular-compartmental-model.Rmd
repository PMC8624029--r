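---
title: "Compartmental modelling of ocular drug delivery from a hydrogel depot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental modelling of ocular drug delivery from a hydrogel depot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitreokin)
```

## The problem and the model

`vitreokin` predicts how fast, and how high, drug concentrations build
up in the vitreous humor when a sustained-release hydrogel depot —
a thermo-responsive PNIPAAm-PEG-DA gel loaded with vancomycin — is
placed at one of four ocular sites: on the cornea (topical), under the
conjunctiva, inside the vitreous, or in the subretinal space.

Each route is a chain (or small tree) of well-mixed tissue compartments
exchanging drug by first-order kinetics. Concentrations are in mg/mL,
rates in hr⁻¹, and all compartment surface areas are taken as equal
(1 cm²), so amounts and concentrations are interchangeable up to a
shared constant. Three simplifications define the model class: no
backflow between compartments (reverse edges are carried in the data
model but fixed at zero), no drug metabolism in the ocular tissues, and
no lateral diffusion or choriocapillaris convection. The system is
therefore linear with one time-varying forcing term: the entry
compartment receives $k_{in} \, C_H(t)$, where $C_H$ is the drug
concentration remaining in the gel.

### The depot input function

In vitro release from a 1 mL gel is well described by a logarithmic
decay of the remaining concentration,
$C_H(t) = a\ln t + b$ with $a = -4.709$ mg/mL per log-hour and
$b = 34.822$ mg/mL ([`default_release_fit()`]). Two clamps make the
fitted curve physical:

* **below `t_floor` = 1 h** the curve is held at $b$. $\ln t \to
  -\infty$ as $t \to 0$ is an artefact of the functional form; 1 h is
  the timescale of the first release observations, and the choice only
  affects the first hour of a 1500 h simulation.
* **beyond `t_zero` $= e^{-b/a} \approx 1628$ h** the concentration is
  clamped at zero — the depot is exhausted; extrapolating the log curve
  would produce negative concentrations.

The natural logarithm is used throughout. The intercept 34.822 is the
fitted coefficient and is treated as canonical; a rounded value of 34
circulates in some statements of the route equations, but using it
would merely rescale every prediction by 34/34.822 before calibration
and not at all after it. With these coefficients the model predicts
84% cumulative release at 504 h (three weeks), matching the observed
plateau, and `fit_log_release()` recovers the coefficients from
noiseless profiles exactly (ordinary least squares of remaining
concentration on $\ln t$ is the exact model class).

### Rate constants and their bindings

`default_parameters()` carries the literature permeation constants
(hr⁻¹): cornea 0.0216, conjunctiva 0.0018, aqueous chamber 0.0189,
iris/ciliary 3.6, sclera 0.05472, choroid 1.782, retina 1.782,
vitreous humor 0.0234, RPE 0.000936; plus vitreous elimination
0.008208 and systemic absorption 0.0329. The literature set names
tissues, not edges, so the package binds them with one uniform rule:

> the transfer rate from compartment X into tissue Y is the permeation
> constant "across Y"; exits *from* the vitreous (intravitreal route)
> are governed by the vitreous-humor constant; every loss term without
> a specific constant (subconjunctival, choroidal, retinal, precorneal)
> is bound to the systemic absorption constant 0.0329; the vitreous
> keeps its dedicated elimination constant; the anterior chamber drains
> via the iris/ciliary constant 3.6, the natural sink for the anterior
> segment.

Two bindings deserve comment because they were genuinely open:

* **Precorneal loss.** Tear-film turnover (~16% per minute, i.e.
  9.6 hr⁻¹) is the textbook clearance mechanism for eye drops. For a
  *retained* depot, however, binding the precorneal loss to tear
  turnover caps topical bioavailability at ~0.2% and the vitreous never
  reaches the 0.007 mg/mL therapeutic level — contradicting the
  empirical expectation that a sustained topical depot does reach
  therapeutic levels within tens of hours. The default therefore binds
  the precorneal loss to the systemic constant, like every other
  unspecified loss term; under it the topical route crosses
  0.007 mg/mL at ~29 h. A drop-like scenario remains available via
  `build_model(..., precorneal_loss = "tear_turnover")`.
* **Intravitreal exits.** In the intravitreal route the vitreous is
  the *source*; its exits to the retina and the aqueous chamber use
  the vitreous-humor constant (0.0234 each), giving a total vitreous
  turnover of $0.0234 + 0.0234 + 0.0329 \approx 0.08$ hr⁻¹. Using the
  destination-tissue constants instead (retina 1.782) would drain the
  vitreous with a ~30 min half-life, an order of magnitude faster than
  reported vitreal half-lives for small molecules.

High choroidal blood flow can be explored by raising the choroidal loss
via a parameter override; the default uses the single systemic constant.

### Calibrating the depot coupling rate

$k_{in}$ — the rate coupling the gel's remaining concentration to the
entry compartment — has no literature value. `calibrate_kin()` fixes it
by requiring the intravitreal model's peak vitreous concentration over
1500 h to equal 0.34 mg/mL. Because the system is linear in $k_{in}$,
the root is found in one exact step from any trial value,
$k_{in}^* = k_{trial}\,\cdot\,0.34/\mathrm{peak}(k_{trial})$, giving
$k_{in}^* \approx 1.4\times10^{-3}$ hr⁻¹ (the quasi-steady estimate
$0.34 \cdot 0.0797 / 34.8 \approx 8\times10^{-4}$ confirms the
magnitude). The calibrated value is shared by all four routes — the
same depot is simply placed at different sites — so the subconjunctival,
subretinal and topical predictions are not fitted to anything.

## Numerical choices

* **Integrator.** `deSolve::ode` with `lsoda` (stiff-capable,
  adaptive), relative tolerance $10^{-8}$, absolute $10^{-10}$. The
  systems are small (3–8 states) and only mildly stiff (rate ratio
  $\sim 10^3$); lsoda solves a 1500 h horizon in well under a second.
  The suite cross-checks it against closed forms (constant-input
  compartment, two-compartment cascade) and a fixed-step RK4 integrator
  at 0.01 h.
* **Output grid.** 0.1 h spacing over the first 5 h (where the input
  and the intravitreal crossing move fastest), 1 h elsewhere.
* **Threshold crossings** are located on the grid and refined by linear
  interpolation between the bracketing points — exact for the
  piecewise-linear interpolant, and stable under grid refinement to
  well below the 0.1 h resolution at which times are reported.
* **Peaks** take the grid maximum and refine it with a quadratic
  through the three bracketing points, accepting the refinement only if
  it is concave, lies inside the bracket, and does not fall below the
  grid maximum. A monotone series peaks at the horizon by this rule.
* **Degenerate inputs.** A zero-release (flat) profile fits to slope 0
  and intercept equal to the initial concentration; `t_zero` is
  infinite for non-negative slopes; a threshold never reached yields an
  `NA` crossing time rather than an error.

## What the synthetic data emulate — and what they do not

`generate_release_profile()` reproduces the *statistical structure* the
release analysis assumes: remaining concentration $a\ln t + b$ plus
additive Gaussian noise (default SD 0.5 mg/mL, the scale of the
reported replicate SDs), clamped to $[0, b]$, at the three-week
sampling schedule 5–504 h. Noise is additive on the remaining
concentration because replicate variation is reported as symmetric
mean ± SD; a consequence is that consecutive *cumulative* fractions can
decrease slightly, which the `release_profile()` container deliberately
permits for observed data (the model-predicted release curve is always
monotone). `generate_observed_trajectory()` adds mean-one
multiplicative lognormal noise to simulated vitreous series —
concentrations are positive, so multiplicative noise is the natural
choice.

Passing recovery tests on these generators shows the estimators are
consistent under the assumed noise model. It does not validate the
noise model itself against replicate-level laboratory data (only
summary SDs at selected times are available), nor the log release
form outside the 5–504 h window, nor any in vivo behaviour.

## Known limitations

* The indirect routes (subconjunctival, subretinal, topical) deliver
  their dose into a vitreous whose only printed clearance is
  0.008208 hr⁻¹ — a ~120 h time constant — so over a 1500 h horizon the
  vitreous integrates the inflow and the predicted peaks
  (~0.7–1.7 mg/mL) exceed the intravitreal calibration target. Reported
  experimental peaks for these routes are several-fold lower, which
  suggests additional clearance (e.g. substantial choroidal blood flow,
  or vitreous-side exits active in all routes) not present in this model
  structure. Crossing *times* at the therapeutic threshold, which depend
  on the early inflow rather than the late balance, are much less
  sensitive to this and are the quantities this package is primarily
  trusted for; users comparing peak magnitudes should treat them as
  upper bounds under the stated assumptions.
* Rate constants are small-molecule literature values, mostly measured
  for dexamethasone, not vancomycin specifically.
* The subretinal "route" ignores the geometry of the bleb; compartment
  models cannot say *where* in a tissue the drug resides.
* Release behaviour is that of the non-degradable gel; degradable
  (PEG-PLLA-DA/glutathione) formulations release differently and are
  out of scope.

## Problem sizes used by the test suite

The suite fits 200 replicate release profiles in the recovery studies,
cross-checks the adaptive solver against RK4 over 150 h at 0.01 h
steps, verifies mass balance over 300–400 h horizons, and runs the full
four-route, 1500 h comparison once for the reproduction checks — sizes
chosen so the whole suite completes in seconds while leaving the
Monte-Carlo standard errors well below the tolerances being asserted.
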