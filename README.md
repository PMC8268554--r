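# eitherm

Electrical impedance tomography (EIT) monitoring of mild hyperthermia
treatment, end to end and entirely in simulation: a synthetic heterogeneous
torso phantom, a finite-element forward solver with adjoint sensitivities,
regularized iterative difference imaging of heating-induced conductivity
changes, a Pennes bioheat treatment simulation with temperature-dependent
perfusion, and two-frequency separation of temperature from perfusion.

## The problem

Hyperthermia therapy heats tumor tissue to 40–45 °C for about an hour as an
adjuvant to radio-/chemotherapy. Noninvasive thermometry in deep tissue is
the hard part. Tissue electrical conductivity rises with temperature
(temperature coefficient Tc ≈ 2 %/°C) and with the perfusion increase caused
by vasodilation, so EIT — imaging conductivity changes from boundary
current-injection/voltage measurements — is a candidate low-cost monitoring
modality. The package is aimed at researchers studying whether, and with
which reconstruction machinery, heating-induced conductivity changes of up
to ~40 % can be imaged accurately enough to be read back as temperature.

## The method

Difference imaging reconstructs the conductivity change `x = σ − σ_ref` from
the voltage change `y = v − v_ref` through the linearization `y ≈ J x`, with
the one-step regularized Gauss–Newton estimate

    x̂ = (JᵀJ + λ² R)⁻¹ Jᵀ y = R⁻¹ Jᵀ (J R⁻¹ Jᵀ + λ² I)⁻¹ y,

where `R` is diagonal with `R_ii = √((JᵀJ)_ii) · penalty_i` (sensitivity
scaling) and λ is the hyperparameter. On top of this one step the package
implements the schemes that make it work in a heterogeneous body:

- **iterative reconstruction** — the reference model is updated and the
  Jacobian recomputed each iteration (3 by default);
- **tissue-dependent penalty** — `penalty_i ∝ σ_muscle/σ_ref,i` inside the
  prior region, equalizing percentage-scale sensitivity between low-σ (fat,
  organ) and high-σ (muscle, urine) tissues;
- **adaptive prior regions** — 1 unconstrained solve, 1 relaxed-penalty
  solve on a thresholded mask, then 3 strict-penalty iterations (1+1+3),
  which rescues reconstruction when the reference model is wrong outside
  the assumed region (e.g. a gas pocket);
- **positivity constraint, measurement-based voltage rescaling, and
  Gaussian smoothing** at the ~1 cm thermal length.

Temperature is coupled to conductivity by
`Δσ/σ = Tc·ΔT + α(√ω − 1)(1 + Tc·ΔT)`, with `ω(T)` the relative perfusion
and `α` the plasma volume fraction seen by the current (24 % at kHz, 8 % at
MHz frequencies). Reconstructing at two frequencies lets the weighted
difference cancel the perfusion term and return ΔT directly.

## Worked example

Reconstruct a 40 % Gaussian heated sphere (6 cm diameter, deep in the
organ) on the default phantom:

```r
library(eitherm)
ph      <- build_phantom(phantom_spec(target_elements = 8000))
mesh    <- place_electrodes(ph$mesh)            # 2 x 8 interleaved ring
pattern <- build_pattern(16, 7)                 # 192 measurements
sc      <- scenario_fixture("P1")
sigma_heated <- apply_gaussian_heating(ph$sigma, sc, mesh)
vref <- solve_forward(mesh, ph$sigma, pattern)
v    <- solve_forward(mesh, sigma_heated, pattern)
fit  <- eit_reconstruct(mesh, vref, v, ph$sigma,
                        recon_config(lambda = 0.01, penalty = "tid",
                                     prior_mask = scenario_prior_mask(mesh, sc)))
fit
#> EIT difference-imaging reconstruction
#>   elements: 6912  iterations (inverse solves): 3
#>   lambda: 0.01  penalty: tid
#>   |dv| residual (mean): 3.63e-05 -> 1.56e-06 -> 3.84e-09 V
#>   delta sigma (% of reference): min -0.204, median 0.000129, max 41
```

The residual falls by four orders of magnitude over the three iterations,
and the reconstructed change tops out at 41 % against the true 40 % peak.
Element-wise, inside the heated region:

```r
err  <- fit$delta_pct - 100 * (sigma_heated - ph$sigma) / ph$sigma
mask <- scenario_prior_mask(mesh, sc)
sprintf("in-region error: mean %.2f%%, sd %.2f%%", mean(err[mask]), sd(err[mask]))
#> "in-region error: mean -0.25%, sd 3.77%"
```

With Tc = 2 %/°C, a conductivity-change error of 2 percentage points
corresponds to a 1 °C temperature error, so this is ~1 °C-class accuracy.
`run_scenario(ht_config())` runs the full treatment pipeline (bioheat
simulation, planning-based reference, two-frequency temperature
separation); see the methods vignette for the model details.

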