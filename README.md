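# tiltcorr

Marker-free correction of rotation-axis misalignment for parallel-beam
tomography, aimed at propagation-based (in-line) X-ray phase-contrast CT of
biological samples, where a misaligned detector or rotary stage blurs
reconstructed slices and rings their edges with artifacts — destroying
exactly the fine soft-tissue structure the modality exists to resolve.

## What it does

In ideal parallel-beam geometry the 180° projection is the mirror image of
the 0° projection about the rotation axis. If the axis is flipped in-plane
by an angle θ and offset by δ pixels from the detector centre line, the
mirror map becomes the reflection

  M(θ, δ) = T(δ) · R(θ) · diag(−1, 1) · R(−θ) · T(−δ),

and, after reflecting the 180° frame about a current estimate
(θ̃, δ̃), the residual disagreement with the 0° frame at detector row y is
a horizontal shift that is linear in y:

  t_m(y) = 2(δ − δ̃) − 2(θ − θ̃)·y.

`estimate_axis()` iterates two steps — reflective resampling, then row-wise
cross-correlation with a weighted line fit — updating δ̃ by half the
intercept and θ̃ by half the slope until both steps fall below tolerance
(with an adaptive gain that compensates the systematic damping of
rotation measurements; see the vignette). `correct_series()` then applies
the inverse misalignment to the whole tilt series, `fbp_reconstruct()`
produces slices by Ram-Lak filtered back-projection, and `mean_ssim()` /
`mutual_information()` score them against a reference. A mass-centre
baseline (`mc_correct()`, the translational scheme used by classic
phase-contrast reconstruction suites) is included for comparison, and a
deterministic simulator (`shepp_logan_3d()`, `simulate_tilt_series()`,
`inject_misalignment()`) provides ground-truth experiments.

## Worked example

```r
library(tiltcorr)

# simulate a misaligned acquisition: 128^3 phantom, 181 projections,
# axis offset 2 px, flip angle -5 degrees
vol    <- shepp_logan_3d(128)
series <- simulate_tilt_series(vol, angles = seq(0, 180, by = 1))
series <- inject_misalignment(series, axis_params(theta = -5, delta = 2))

# estimate the misalignment from the 0/180 degree pair alone
fit <- estimate_axis(projection_at(series, 0), projection_at(series, 180))
print(fit)
#> Rotation-axis misalignment fit (0/180 degree mirror symmetry)
#>   theta: -4.877 deg   delta: 2 px
#>   5 iterations, converged

# correct, reconstruct the four middle slices, and score them against the
# reconstruction of the unperturbed series
corrected <- correct_series(series, fit$params)
slices    <- reconstruct_slices(corrected)
reference <- reconstruct_slices(simulate_tilt_series(vol, seq(0, 180, by = 1)))
evaluate_slices(slices, reference)
#>   slice mssim   mi
#> 1    63 0.982 2.82
#> 2    64 0.987 3.11
#> 3    65 0.986 3.09
#> 4    66 0.978 2.80
```

The estimate recovers the injected parameters (−4.88° vs −5°, 2.000 px vs
2 px at this half-size scale; ~0.01° and ~0.001 px at 256³), and the
corrected reconstruction is nearly indistinguishable from the reference
(mSSIM ≈ 0.98, against ≈ 0.55 without correction). `summary(fit)` shows
the per-iteration trace; `plot(fit)` displays the final row-shift profile
and the estimate trajectory.

`run_pipeline(pipeline_config())` chains the whole study — simulate,
inject, estimate, correct (none / mass-centre / geometric), reconstruct
and evaluate — and can write slice stacks (multi-page TIFF), the estimate
(JSON), the iteration trace and per-slice metrics (CSV). A thin command
line with `simulate`, `estimate`, `correct`, `reconstruct`, `evaluate` and
`run` subcommands is installed at
`system.file("cli/tiltcorr.R", package = "tiltcorr")`.

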