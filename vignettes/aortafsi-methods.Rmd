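---
title: "Methods: reduced-order ascending-aortic biomechanics in aortafsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order ascending-aortic biomechanics in aortafsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aortafsi` models the ascending aortic segment of an individual patient as
an axisymmetric, incompressible, anisotropic hyperelastic tube carrying
pulsatile pressure-driven blood flow, personalises that model against CT
lumen volumes and Doppler velocity, and runs a two-sample inference
protocol over a cohort of such models. This vignette records the model,
its assumptions, the parameters that matter, the numerical choices, and
the boundaries of what the package's validation does and does not show.

## The wall model

The wall is homogeneous, incompressible and hyperelastic with the
anisotropic modified Mooney–Rivlin energy

$$W = c_1(I_1-3) + c_2(I_2-3) + D_1\left[e^{D_2(I_1-3)}-1\right]
      + \frac{K_1}{K_2}\left\{e^{K_2(I_4-1)^2}-1\right\},$$

where $I_1, I_2$ are the invariants of the right Cauchy–Green tensor and
$I_4$ is the squared stretch along the fiber direction, taken
circumferential: the exponential $I_4$ term encodes the circumferential
stiffening of collagen recruitment. The baseline constants
($c_1 = -525.16$, $c_2 = 165.9$, $D_1 = 231.8$ kPa, $D_2 = 3.5$,
$K_1 = 33.4$ kPa, $K_2 = 12.6$) are a published fit to human aortic
stress–stretch data; `fit_baseline_params()` reproduces that kind of fit
from uniaxial data by separable least squares (the energy is linear in
the four stress-dimensioned constants once the exponents are fixed, so an
inner linear solve is profiled over a Nelder–Mead search on
$\log D_2, \log K_2$ — far better conditioned than a six-parameter
Levenberg–Marquardt on this strongly collinear basis).

Two deliberate choices:

* **Exact incompressibility.** The tissue is often described as "nearly
  incompressible" with an unstated bulk modulus; enforcing $J = 1$
  exactly removes that free constant and is what makes the semi-analytic
  tube solution below possible. The hydrostatic pressure is eliminated by
  working with the stress differences
  $\sigma_{\theta\theta}-\sigma_{rr} = \lambda_\theta\,\partial\hat W/\partial\lambda_\theta$
  and
  $\sigma_{zz}-\sigma_{rr} = \lambda_z\,\partial\hat W/\partial\lambda_z$
  (`stress_difference()`, analytic derivatives, verified against central
  finite differences of $W$ to $10^{-5}$ relative).
* **Single-ratio personalisation.** Patient stiffness is one ratio $r$
  multiplying $c_1, c_2, D_1, K_1$ only (`scale_params()`). The
  dimensionless exponents $D_2, K_2$ set the *shape* of the response;
  scaling them would change strain-stiffening character rather than
  stiffness magnitude, and would destroy the exact linearity
  ($W \mapsto rW$, all stresses $\mapsto r\,\sigma$) that the calibration
  relies on.

The printed $c_1$ is negative, so the energy is not a priori polyconvex;
`material_params()` therefore checks that the incremental uniaxial
stiffness along the fiber is positive over stretches 1–1.3 and warns (not
errors) when it is not, since the baseline set as printed passes the check
and is in routine use.

## The structural reduction

Instead of a 3-D finite-element model, the vessel is a stack of
axisymmetric rings (`vessel_geometry`: axial position, inner radius, wall
thickness, default 2.0 mm everywhere because patient-specific wall
thickness is rarely imageable). For each ring under internal gauge
pressure $P$ with axial stretch $\lambda_z$, the incompressible map
$r(R)^2 = a^2 + (R^2-A^2)/\lambda_z$ reduces quasi-static radial
equilibrium $d\sigma_{rr}/dr = (\sigma_{\theta\theta}-\sigma_{rr})/r$ to a
single scalar equation for the deformed inner radius $a$:

$$P = \int_a^b \left(\sigma_{\theta\theta}-\sigma_{rr}\right)\frac{dr}{r}.$$

Numerics: the integral uses 16-point Gauss–Legendre quadrature over the
reference wall; the root in $a$ is bracketed by outward scanning and
solved with `uniroot` to $10^{-10}$ relative; transmural $\sigma_{rr}$ is
reconstructed by integrating inward from the traction-free outer surface
with a fresh 16-point rule per sample, so the boundary values
$\sigma_{rr}(b) = 0$ and $\sigma_{rr}(a) = -P$ hold to far better than
$10^{-6}$ kPa. Samples include both wall surfaces. Since principal axes
coincide with the cylindrical axes in this reduction, the maximal
principal stress at a sample is simply
$\max(\sigma_{rr}, \sigma_{\theta\theta}, \sigma_{zz})$; "mean stress-P1"
of a vessel is the plain average over all rings and transmural samples,
and lumen volume is frustum quadrature over deformed inner radii.

Assumptions this buys: no bending, torsion, non-axisymmetric modes,
contact or inertia ($\rho_s$ is recorded but cannot enter a quasi-static
solve); axial pre-stretch defaults to $\lambda_z = 1$ (no tethering data)
and is exposed as a config scalar. The role of the paper-style tetrahedral
mesh-convergence study is played by an axial refinement property: doubling
the ring count on a smooth tapered geometry moves the stress summaries by
well under 2% (the tests assert this; transmural quadrature at 16 points
is already spectrally converged).

## The flow reduction

Blood is Newtonian and incompressible with density 1 g·cm⁻³ and dynamic
viscosity from the clinical regression
$\mu\,[\mathrm{cP}] = 0.12\,\mathrm{hct}[\%] + 0.17\,\mathrm{tpp} - 2.07$
(`viscosity_from_blood()`). Taken literally with total plasma protein in
g/L this yields ~14 cP for normal blood, far outside the physiological
3–10 cP range of the reference cohort; with the conventional clinical
g/dL unit it is physiological. Both dialects are implemented behind an
explicit flag, default `"g_dL"`, and the discrepancy is documented rather
than silently resolved.

Flow is quasi-1D between prescribed inlet and outlet pressure traces:

$$\partial_t A + \partial_x Q = 0,\qquad
  \frac{\rho}{A}\,\partial_t Q = -\partial_x p - \frac{8\pi\mu}{A^2}Q,$$

with $A(p)$ per axial cell tabulated from the structural solver
(`tube_law()`) — that tabulated pressure–area relation *is* the
fluid–structure coupling of the reduction. Choices and their reasons:

* **Waveform.** The inlet trace is a two-phase analytic aortic template
  (sinusoidal systolic phase over the first 35% of the cycle ending at a
  dicrotic-notch level, exponential diastolic decay reaching the minimum
  exactly at end-cycle), normalised to [0, 1] and affinely mapped onto the
  patient's DBP–SBP range, so max = SBP and min = DBP exactly. The
  template is parametric (`t_sys`, `tau`) and any user curve can be
  substituted. Cardiac period defaults to 0.8 s (not recorded per
  patient). The outlet trace is the inlet trace minus a constant offset
  $\delta$ — the minimal parameterisation of "adjust the outlet to match
  the measurement".
* **Friction.** Fully developed Poiseuille (8πμQ/A²). A Womersley
  correction would change the phase of the friction term but none of the
  package's validated limits; it is out of scope.
* **No convective acceleration.** The $\partial_x(Q^2/A)$ term is dropped;
  over a 60 mm segment with prescribed end pressures it is subdominant,
  and dropping it keeps the scheme linearly stable analysis-friendly.
* **Wall viscoelasticity.** A purely elastic tube clamped between two
  prescribed pressure traces is an undamped inertance–compliance
  oscillator; its ring-down time $2\rho A/(8\pi\mu)$ is several seconds,
  so an elastic model keeps ringing across any realistic number of
  cardiac cycles. Real aortic walls are viscoelastic, and a small
  Kelvin–Voigt term (momentum sees $p + \tau_w\,\partial_t p$, default
  relaxation time $\tau_w = 5$ ms, at the low end of reported large-artery
  values) damps the spurious mode physically. It is treated implicitly
  (tridiagonal solve per step) because its explicit stability limit is far
  below the CFL step; `wall_relaxation = 0` restores the purely elastic
  wall.
* **Scheme.** Staggered-grid finite volume, conservative in area (mass
  balance closes to machine precision over a cycle), semi-implicit
  friction, CFL-limited time step from the tabulated wave speed
  $c = \sqrt{A/(\rho\,dA/dp)}$ at CFL 0.8. The initial through-flow is
  seeded at the cycle-mean Poiseuille balance (with the cycle-mean of
  $1/A^2$): the mean-flow mode relaxes on $\rho A/(8\pi\mu) \approx 3$ s,
  so spinning it up from rest would take tens of cycles. With the seed and
  the viscoelastic damping, cycle-to-cycle periodicity of the inlet
  velocity is at the $10^{-4}$ level by cycle 3.
* **Rigid limit.** With `rigid = TRUE` the model collapses to a single
  inertance–resistance ODE integrated by an exact exponential update, and
  its periodic state is computed in closed form from the one-cycle affine
  map; the steady constant-offset case reproduces Poiseuille flow to
  machine precision, which the tests use as the closed-form oracle.
* **Reported velocities.** "Inlet velocity" is $Q/A$ at the inlet face;
  "mean velocity" is the volume-weighted cross-section average. The
  systolic/diastolic instants are the argmax/argmin of the inlet pressure
  over the cycle, and the reported values are instantaneous at those
  instants (phase-window averaging is a plausible alternative reading;
  instantaneous is the convention here).

## The inverse procedures

All three calibrations use one safeguarded scalar root-finder (secant
steps clipped to a maintained sign-change bracket, bisection fallback)
and record a full (iteration, value, residual) trace. Each resolves its
root far tighter than the conventional 5% relative-error acceptance
(volumes to $10^{-4}$, velocity to $10^{-3}$) and then re-verifies the 5%
contract on the converged value, so "converged" is never marginal.

* **Preshrink** (`preshrink()`): the imaged geometry is acquired under
  load, so the stress-free simulation start must be constructed. The
  candidate zero-load geometry scales the in vivo radii by $(1-s)$,
  starting at $s = 5\%$, and — a detail that matters — restores the wall
  thickness by per-ring wall-area conservation, the incompressible
  inverse of the inflation map. Keeping the imaged (thinned) wall instead
  biases the subsequently calibrated stiffness ratio by about $+1.5\%$.
  $s$ is adjusted in $[0, 40\%]$ until pressurising the candidate to DBP
  reproduces the in vivo lumen volume.
* **Stiffness ratio** (`calibrate_material()`): secant on $\log r$ until
  the lumen volume under load matches the systolic CT volume. Both
  constructions are supported: the full systolic pressure applied to a
  recovered zero-load geometry (self-consistent; the default in
  `run_patient()`), or the systolic–diastolic pressure difference applied
  to the imaged diastolic geometry treated as stress-free (the common
  imaging-workflow approximation, `material_mode = "delta_p"`). The
  self-consistent mode is the default because it makes forward–inverse
  recovery of a hidden ratio well-posed; the two modes differ
  systematically because hyperelastic inflation is path-dependent in the
  reference configuration.
* **Coupling.** The zero-load shape depends on stiffness and the
  calibrated stiffness depends on the zero-load shape. `run_patient()`
  treats the calibrated ratio as a fixed point $r = g(r)$ — $g$ being one
  preshrink-then-recalibrate pass — and solves it by secant. Plain
  alternation contracts at roughly 0.55 per pass on representative
  anatomies; the secant needs 3–4 evaluations for 0.1% stationarity.
* **Outlet offset** (`calibrate_outlet()`): $\delta \in [0, 30]$ mmHg is
  adjusted until the cycle-averaged *net* inlet velocity from
  `solve_flow()` matches the Doppler measurement. The net (signed)
  average is matched rather than mean |u| because a compliant tube at
  $\delta = 0$ still carries purely oscillatory storage flow, which would
  make a vanishing measurement unreachable; with the net average,
  measurement $\to 0$ calibrates cleanly to $\delta \to 0$. The velocity
  response is nearly linear in $\delta$, so the secant converges in a few
  flow solves; the pressure–area tabulation is built once and shared
  across them.

A missing Doppler measurement skips outlet calibration and leaves the
velocity metrics `NA` under an explicit `outlet_calibrated = FALSE` flag.

## The statistics protocol

Per metric and pressure phase: Shapiro–Wilk normality per group
(recorded; `NA` for groups of two), Levene's variance-equality test, then
a two-sided pooled Student t-test if the Levene p-value exceeds
$\alpha = 0.05$ and a Welch test otherwise. Two choices deserve emphasis:

* **Levene variant.** The median-centered (Brown–Forsythe) variant is the
  default because it is the one the packaged reference tables were
  produced with — on the max-displacement metric the median- and
  mean-centered variants give clearly different p-values (≈0.19 vs
  ≈0.02), so the variant is observable and tested.
* **Normality does not gate.** The reference protocol applies the t-test
  even where a Shapiro–Wilk p-value falls below 0.05 (one velocity metric
  does); the default follows that, recording normality without acting on
  it. `gate_normality = TRUE` switches such metrics to a Wilcoxon
  rank-sum test for users who want the strict protocol. Categorical
  fields (sex) use a two-sided Fisher exact test.

Groups are formed by ranking the aortic Z score (body-size-normalised
diameter deviation) and splitting evenly, ties broken by patient id, so
the split is deterministic and input-order invariant.

The packaged reference tables are stored as plain CSV exactly as printed
(per-patient values rank-ordered within group). Two source
inconsistencies are handled openly rather than absorbed: the printed
diameter p-value (0.051) is not what a pooled t-test on the printed
per-patient diameters gives (≈0.047), so that single cell is not asserted;
and several printed summary cells are truncated rather than rounded
(e.g. a mean of 63.476 printing as 63.47), so summary cells are verified
to one unit in the last printed digit while all p-values hold at the
strict half-unit.

## The synthetic cohort generator

`generate_cohort()` draws two groups of (by default) 10 patients from
independent truncated normals whose means and SDs are the reference
cohort's summary rows — so the dilated group has systematically larger
Z scores and diameters — plus hematocrit (42 ± 6%) and total plasma
protein (7.2 ± 0.8 g/dL) feeding the viscosity regression. No printed
covariance structure exists, so fields are independent; that is a known
simplification (no height–weight correlation, no diameter–age trend).
Each patient gets an idealised in vivo geometry — a linear 10% taper over
60 mm with mid-segment diameter equal to the drawn AAD and a 2 mm wall —
and hidden truth: a stiffness ratio (log-normal, median 1.0 nondilated
vs 0.7 dilated, encoding softer dilated walls; σ_log = 0.15), a zero-load
shrink (uniform 3–8%), and an outlet offset implied by a physiological
target mean inlet velocity (truncated normal around 200 mm/s).

`synthesize_measurements()` runs the forward model from the truth
(zero-load geometry pressurised to DBP and SBP; pulsatile flow with the
truth offset) and emits the measurement set: diastolic/systolic lumen
volumes and Doppler mean inlet velocity. Measurement noise is
multiplicative Gaussian with a structure that matters scientifically: a
*shared* per-patient volume-scale error (default 2%, since segmentation
and scanner biases hit both phases of one acquisition alike) plus a small
*independent* per-phase error (default 0.3%). The independent component
competes directly with the diastolic-to-systolic volume increment
(~4–5%) that carries the entire stiffness signal; uncorrelated noise at
realistic CT magnitudes makes the stiffness ratio essentially
unidentifiable. That identifiability cliff is a real property of
volume-matching calibration, not an artifact, and it is why recovery
validation is run at zero noise while a separate robustness test
documents graceful behaviour (loose recovery or explicit calibration
failure, never silent nonsense) under the default noise.

What passing the synthetic validation shows: the inverse machinery
recovers what the forward model hid, under the generator's idealised
anatomy, waveform and noise. What it does not show: performance on real
anatomies (non-axisymmetric, curved, moving), real waveform shapes, real
segmentation error structure, or any claim about the clinical populations
the field distributions were summarised from.

## Problem sizes and determinism

The package's own validation runs use 8–13 axial rings, 16 transmural
quadrature points, 8–12 flow cells and 3–5 cardiac cycles; at those sizes
a full structural personalisation takes on the order of a second per
patient and an outlet calibration a few seconds, so a 20-patient cohort
round-trips in minutes on one CPU. All randomness flows through a single
mandatory seed in `cohort_spec()`; calibration and solvers are
deterministic given inputs, and re-running a patient byte-reproduces its
JSON report.

## Known limitations

* One material ratio cannot separate isotropic from fiber stiffness; the
  calibration absorbs geometry and thickness errors into $r$.
* The axisymmetric reduction has no curvature, so bending-dominated
  stress concentrations (e.g. at the sinotubular junction) are invisible;
  stress summaries are transmural/axial averages and extremes of a smooth
  field.
* The constant-offset outlet parameterisation cannot represent wave
  reflection from the arch; $\delta$ is an effective resistance, not a
  physiological afterload model.
* Displacement is reported between the diastolic and systolic solutions
  of the same zero-load model ("diastolic-to-systolic"); if a source
  reports displacement from the zero-load state instead, its values are
  systematically larger.
* The uniaxial fitting target for `fit_baseline_params()` is a declared
  convention (incompressible uniaxial extension along the fiber with free
  lateral faces); raw experimental protocols differ, and fits are
  validated by synthetic recovery only.
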