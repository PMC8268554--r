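---
title: "EIT monitoring of hyperthermia: models, algorithms and design choices"
author: "eitherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EIT monitoring of hyperthermia: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitherm)
```

This vignette is the package's account of the science it implements: the
forward and inverse models, the thermophysiological coupling, the tunable
parameters and their defaults, the numerical choices, and what the
simulation study design can and cannot say about real measurements.

## 1. Problem setting

Mild hyperthermia heats a tumor region to 40–45 °C for about an hour.
Electrical conductivity of tissue increases with temperature, both directly
(electrolyte mobility, captured by a temperature coefficient Tc) and
indirectly (vasodilation raises local blood/plasma volume). EIT measures
boundary voltages under current injection and can image conductivity
*changes* between two states (difference imaging), which is robust to
modelling errors common to both states. The package builds the entire chain
in simulation, from tissue phantom to reconstructed temperature maps, so
that reconstruction schemes can be compared under controlled, known truth.

## 2. Synthetic torso phantom

Licensed anatomical human models cannot be redistributed, so the phantom is
a stylized torso section: an elliptic cylinder (half-axes 15 cm and 10 cm,
height 20 cm) meshed by sweeping a structured triangulated disk, with a
muscle background, fat and skin shells, a spine-like bone cylinder, a
liver-like organ sphere, a urine-filled bladder and a 3 cm tumor beside it.
The tissue list and conductivities are a compact approximation spanning the
real torso's conductivity range (internal air ~0 S/m to urine 3 S/m;
muscle 0.36 S/m at low frequency), which is the property that matters for
the penalty and prior studies. The shells are thicker than anatomical skin
and fat so that they are resolved by centroid labelling at every mesh
resolution the package targets (20k–80k elements); the phantom is stylized,
not anatomical, and the built-in table is deliberately overridable.

Mesh generation is deterministic: prisms between swept disk layers are cut
into tetrahedra with quad-face diagonals chosen through the smallest global
node index, which makes neighbouring prisms agree on shared faces (the mesh
is conforming, verified in the tests by face counting). Boundary nodes lie
exactly on the ellipse, so the two interleaved electrode rings of eight
(heights ±h/4, 45° spacing per ring, 22.5° offset between rings) snap to
mesh nodes with zero snap distance; the element-count heuristic keeps the
layer count divisible by four for exactly that reason.

The five canonical heated-region scenarios place a sphere (diameters 60,
40, 80, 60, 60 mm) at deep and shallow positions; inside the sphere the
conductivity is multiplied by `1 + 0.4·exp(−r²/(2R²))` with R = 3 cm fixed
across scenarios — the smallest sphere therefore has the largest
conductivity jump at its surface, deliberately the hardest case. Scenario
positions are published in the reference anatomy's millimetre frame; the
fixture maps them into the phantom by fixed per-axis linear scaling
(x·150/180, y·100/120, z·1), preserving deep-vs-shallow and left-vs-right
relations. The "air" fixture adds a 5 cm, 0 S/m sphere outside the prior
region to emulate a reference-model error (gas pocket).

## 3. Forward model

Quasi-static conduction `∇·(σ∇u) = 0` is discretized with linear (P1)
tetrahedral finite elements; electrodes are point electrodes at single
boundary nodes and contact impedance is not modelled — difference imaging
is insensitive to electrode modelling shared by both states, and extended
electrode models would only change near-electrode sensitivity. Current is
injected through transversal pairs (offset 7 of 16), voltages read on all
adjacent non-injecting pairs: 16 × 12 = 192 measurements. The system is
grounded at one interior node (differential voltages are invariant to the
choice); nodes electrically isolated inside zero-conductivity inclusions
are pinned too. One sparse Cholesky factorization per conductivity state
serves all drive and adjoint solves. The Jacobian uses the adjoint identity
`J[m,e] = −∫_e ∇u_drive·∇u_meas dV` with unit-current measurement fields;
it matches central finite differences to better than 1e−4 relative and the
forward solver satisfies reciprocity to solver precision and matches the
closed-form series solution for a homogeneous sphere within 5 % at coarse
resolution, converging under refinement.

Measurement noise is white Gaussian on the heated-state frame with standard
deviation set from the SNR of the voltage *change*,
`σ_n = rms(v − v_ref)/10^(SNR/20)`; the reference frame is left noise-free
by default (an option adds independent reference noise). Noise draws are
seeded without disturbing the caller's RNG state.

## 4. Inverse model

The one-step regularized Gauss–Newton update is

`x̂ = R⁻¹Jᵀ (J R⁻¹ Jᵀ + λ² I)⁻¹ y`,

algebraically equal to `(JᵀJ + λ²R)⁻¹Jᵀy` but inverting only a
measurements-sized system. `R_ii = √((JᵀJ)_ii)·penalty_i` scales the
regularization with per-element sensitivity; zero-sensitivity columns
(elements inside insulating inclusions) are floored at `1e−12·max(R_ii)`
and excluded from error statistics. The hyperparameter default λ = 0.01
weights misfit against regularization; λ-monotonicity of the solution norm
is a tested invariant, and noise studies use larger λ (0.1) as mitigation.

**Penalties and priors.** Inside a prior region the penalty (default
0.001) lowers `R_ii`, permitting larger changes there; outside it is 1. A
constant penalty over-reconstructs low-σ tissues and under-reconstructs
high-σ ones, because the solver minimizes voltage misfit, not percentage
error. The tissue-dependent penalty `penalty_i = base·σ_muscle/σ_ref,i`
(clipped to [base/10, base·100]; zero-σ elements capped) equalizes
percentage-scale sensitivity and is anchored at muscle; without muscle in
the mesh the median conductivity anchors it. The exact per-tissue values of
the original scheme are not recoverable from the literature, so this
inverse-proportional form was chosen for matching the documented failure
direction of constant penalties; form and constants are config-exposed.

**Iterations.** Each iteration re-solves the forward problem at the
current estimate, recomputes the Jacobian (full Gauss–Newton; a
frozen-Jacobian mode exists) and accumulates the update; the per-iteration
mean ± sd of |Δv| is recorded and should fall monotonically — divergence
over two consecutive iterations stops the fit with a flag. The adaptive
prior scheme runs 1 unconstrained solve, thresholds the smoothed change
magnitude at 25 % of its maximum (the threshold fraction is a package
choice, config-exposed) to get a mask, refines the mask with one solve at
the relaxed penalty 0.1, then runs 3 strict-penalty iterations: exactly
five inverse solves. An empty mask falls back to the whole domain with a
warning.

**Constraints and smoothing.** The positivity option zeroes negative
accumulated changes before each iteration (heating only increases σ);
voltage rescaling multiplies measured frames channel-wise by
model/measured pre-heating ratios, cancelling global anatomical scale
factors, with near-zero reference channels (below 1e−3 of the median)
passed through and flagged. Gaussian smoothing over element centroids
(radius 1 cm, cutoff 3 radii, volume-weighted, normalized) mirrors the
characteristic thermal length `√(k/(w_b·c_b))` ≈ 1.4 cm of perfused muscle;
whether it is applied per-iteration or only to masks and the final map is
not settled by the source material — the package applies it to masks and
final output only (config flag), keeping intermediate updates sharp.

## 5. Thermophysiology

The Pennes bioheat equation
`ρc ∂T/∂t = ∇·(k∇T) + w_b c_b (T_a − T) + q_m + q_ext` is solved on a
rectilinear grid (default spacing 4 mm; the treatment pipeline uses 8 mm)
by backward-Euler steps with the diffusion operator factored once and the
temperature-dependent perfusion sink lagged one step — unconditionally
stable in diffusion and stable in perfusion for steps far below the
perfusion time constant (minutes); the explicit scheme is kept for
reference and rejects CFL-unstable steps. The solver works in temperature
elevation above the arterial temperature (37 °C, fixed core) with
metabolic heat assumed balanced at baseline, so unheated tissue stays at
exactly 37 °C; the outer surface is fixed at the bolus/arterial
temperature (a convective boundary would need an extra heat-transfer
coefficient that nothing in the study constrains). Verified against the
1-D perfused-slab closed form (2 %) and a steady-state energy balance
(1 %).

The power deposition is an isotropic Gaussian at the tumor centre
(σ = 3 cm, peak 25 kW/m³ by default) standing in for a phased-array SAR
pattern, with the peak chosen so the one-hour pessimistic-perfusion
simulation lands in the hyperthermic 40–45 °C window — the study condition
itself, not a tuned quantity.

**Perfusion curves.** ω(T) rises piecewise-linearly from 1 to ω_max
between an onset and a plateau temperature and is flat beyond; optimistic
(muscle 12×, fat 4×, tumor 2×) and pessimistic (3×, 1.5×, 1×) variants
bound the physiological uncertainty, and only muscle, fat and tumor are
perfusion-responsive. The onset is 40 °C for muscle and fat: deep-tissue
vasodilation responds to hyperthermic, not normothermic, temperatures, and
an onset at 37 °C would make the optimistic and pessimistic models diverge
strongly already at 38 °C, giving the planning-based reference a large
spurious mismatch over the whole mildly heated volume — inconsistent with
planning references being close starting points. Tumor vasculature is
disordered; its weak response starts at 37 °C and plateaus at 43 °C. All
curve parameters are config-exposed.

**Conductivity coupling.** `Δσ/σ = Tc·ΔT + α(√ω − 1)(1 + Tc·ΔT)` with
Tc = 2 %/°C for all tissues and plasma fractions α = 24 % (kHz) and 8 %
(MHz) — at low frequency current flows through the extracellular/plasma
space, so perfusion contributes more. The square root maps relative flow
to vessel cross-section (laminar, constant pressure drive); the raw `ω−1`
reading is available behind a flag. The inverse map `Δσ → ΔT` is linear in
the pure-Tc case and solved by bisection to 1e−6 °C on [−15, 15] °C
otherwise, with out-of-range inputs clipped and flagged.

## 6. Treatment pipeline and two-frequency separation

A treatment run simulates one hour with the pessimistic model (the
"actual" treatment) and with the optimistic model (the "planned"
prediction) under the same deposition. Scenario 1 reconstructs against the
37 °C baseline with no prior mask; Scenario 2 against the planned heated
conductivity with the prior region `T_plan > TMask` (default 39 °C —
higher thresholds exclude real changes, lower ones dilute tumor changes).
Reconstructed changes are re-expressed relative to the 37 °C baseline,
inverted to temperature per frequency, and — when both frequencies are run
— combined through

`Δσ_LF − (α_LF/α_HF)·Δσ_HF = (1 − α_LF/α_HF)·Tc·ΔT`

for temperature and the unweighted difference for perfusion. The weighting
cancels correlated reconstruction errors in the temperature map; the
perfusion map retains them, and it is the temperature estimate that
benefits — the tested asymmetry. For the perfusion step the temperature
estimate is clamped to the physical ±15 °C range so junk estimates in
low-sensitivity elements cannot make `1 + Tc·ΔT` non-positive; negative
radicands floor at ω = 0 with a flag.

## 7. Analysis path and metrics

Error statistics follow a fixed path: per-element changes (in % of the
unheated baseline) are volume-weighted onto the rectilinear grid, a cubic
box filter of 1.2 cm edge mimics the expected smoothness of heat
distributions, and errors are binned by the true change in 1 % bins
(sliding histogram) with mean ± sd per bin, per tissue and overall; bins
with fewer than 10 voxels are dropped as unestimable. Headline statistics
are evaluated inside the prior-region mask. Elements with zero reference
conductivity are excluded (percentage change is undefined there).

## 8. Problem sizes and defaults

The default phantom targets 28 800 elements; the test suite runs at ~7 000
(accuracy checks) and ~12 000 (pipeline checks) elements with an 8 mm
thermal grid, and the acceptance script at ~23 000 elements — sizes at
which the documented error bounds hold with margin while a full suite run
stays in minutes. The key defaults: λ = 0.01, strict penalty 0.001,
relaxed 0.1, 3 iterations (5 adaptive), TMask 39 °C, smoothing radius
1 cm, filter edge 1.2 cm, grid 4 mm (thermal pipeline 8 mm), dt 1 s
(pipeline 10 s, backward Euler), 16 electrodes, offset 7, 1 mA.

## 9. What the simulations do and do not show

Everything here is an inverse-crime-adjacent simulation study: forward and
inverse solves share the mesh and the physics that generated the data, and
noise is the only corruption studied. Passing tests therefore demonstrate
the *relative* merits of penalties, priors, iterations and frequencies
under controlled conditions, and internal consistency of the models — not
clinical accuracy. Not modelled: electrode contact impedance and extended
electrodes, dispersive (complex) admittance, whole-body thermoregulation
and discrete-vessel cooling, core-temperature drift, organ deformation,
anatomical realism of the phantom, and uncertainty in Tc and α (Tc varies
~0.6–2.1 %/°C across tissues in the literature; the constant 2 %/°C is a
modelling choice). The measurement-count bookkeeping of the reference
protocol is adopted as the rule-derived 192 for 16 electrodes.
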