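---
title: "Marker-free rotation-axis correction for parallel-beam CT"
author: "tiltcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-free rotation-axis correction for parallel-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltcorr)
```

## The problem

In parallel-beam tomography — including propagation-based ("in-line") X-ray
phase-contrast CT, where a coherent beam and a detector placed some distance
behind the sample yield edge-enhanced projections of soft tissue — slice
reconstruction assumes that the rotation axis projects onto the central
column of every projection. Mechanical misalignment of the detector and
rotary stage breaks that assumption in two ways: a lateral offset
$\delta$ (pixels) of the axis from the detector centre line, and an in-plane
flip angle $\theta$ (degrees) between the axis and the detector's vertical.
Left uncorrected, the offset blurs reconstructed slices (the classic
centre-of-rotation "tuning fork" doubling) and the tilt adds edge artifacts
that grow with distance from the central slice. Axial and beam-direction
offsets of the stage are second-order for this geometry and are not
modelled.

`tiltcorr` estimates $(\theta, \delta)$ from just two projections, corrects
the whole tilt series, reconstructs by filtered back-projection (FBP), and
quantifies the result — with a built-in deterministic simulator so every
step can be validated end to end.

## The mirror-symmetry model

For an ideal parallel-beam acquisition the projection at $180^\circ$,
$P_\pi$, is the mirror image of the $0^\circ$ projection $P_0$ about the
rotation axis. With the axis tilted by $\theta$ and offset by $\delta$, the
mirror line is itself tilted and offset, and the map from a point of $P_0$
to its mirror position in $P_\pi$ is the composite reflection

$$
M(\theta,\delta) \;=\;
T(\delta)\,R(\theta)\,
\begin{pmatrix}-1&0\\0&1\end{pmatrix}
\,R(-\theta)\,T(-\delta),
$$

a translate–rotate–reflect–rotate–translate product in homogeneous
coordinates with origin at the image centre ($x$ along detector columns,
$y$ along rows). Its linear block has determinant $-1$ and the whole map is
an involution — reflections about a line square to the identity — which the
test suite verifies on a parameter grid. To first order in $\theta$ (in
radians),

$$
x' \approx -x + 2(\delta - \theta y), \qquad
y' \approx y + 2(\delta - x)\,\theta ,
$$

so a *residual* misalignment manifests as a per-row horizontal shift that
is **linear in the row coordinate**. That is the whole trick: if the
$180^\circ$ frame is reflected about the current axis estimate
$(\tilde\theta, \tilde\delta)$, the remaining disagreement with $P_0$ at
row $y$ is a shift

$$
t_m(y) \;=\; 2(\delta - \tilde\delta) \;-\; 2(\theta - \tilde\theta)\,y .
$$

Estimating the axis therefore reduces to a two-step iteration
(`estimate_axis()`):

1. **Reflective resampling** — apply `correction_transform()` (the same
   reflection, written as translate–reflect–rotate($-2\tilde\theta$)–
   translate) to the background-subtracted $180^\circ$ frame.
2. **Row-wise registration and a line fit** — locate the shift of each
   detector row by zero-normalized cross-correlation
   (`rowwise_shift_profile()`), fit $t_m(y) = a + b\,y$ by weighted least
   squares (`fit_shift_line()`), and update
   $\tilde\delta \mathrel{+}= a/2$,
   $\tilde\theta \mathrel{-}= b/2$ (radians, reported in degrees)
   via `update_estimate()`.

Iteration stops when both parameter steps drop below the tolerances. The
first iteration uses the zero-parameter reflection: the formal
"start from the identity" initialization is read as a zero parameter
estimate, since a plain identity would compare $P_0$ with an unreflected
$P_\pi$ and the row-wise comparison would be meaningless.

### Why the update is gain-adapted

The row-shift measurement is *systematically damped* when the residual
transform contains rotation: a residual rotation $\varepsilon$ shifts row
$y$ by $\varepsilon y$ but also displaces content vertically by
$\varepsilon x$ across the row, mixing neighbouring rows whose profiles
differ. On the Shepp-Logan series the fitted slope recovers only ~30% of
the true residual, so the plain iteration contracts linearly with ratio
about 0.7 — accurate, but needing ~16 iterations. `estimate_axis()`
therefore rescales the flip-angle step by a secant estimate of the damping
factor, computed from successive increments
($\hat c = (d_{k-1}-d_k)/s_{k-1}$, clipped to a safe range and with a step
cap). This is standard acceleration of a linearly damped fixed-point
iteration: the fixed point — where the measured shift profile is flat — is
untouched, and convergence takes 4–6 iterations. `accelerate = FALSE` in
`axis_control()` restores the plain scheme. The offset update needs no
gain: a uniform shift is measured essentially undamped, and $\delta$
typically converges in one step.

### Measurement details

* **Normalization.** The inner-product correlation of the model is
  implemented as *zero-normalized* cross-correlation per row: identical
  argmax on background-subtracted data, but invariant to residual
  illumination offsets, and the peak value doubles as a quality score.
* **Subpixel peak.** Three-point parabolic interpolation around the integer
  argmax (default on). Rows whose maximum sits on the boundary of the lag
  search (`max_shift_frac`, default a quarter of the width per side) are
  discarded as unreliable, as are rows below `min_peak_corr` (default 0.3),
  rows inside the top/bottom margin (`row_margin_frac`, default 0.1 —
  border rows lose support under the reflective resampling), and
  (near-)constant rows.
* **Weights.** The line fit weights rows by their peak correlation clipped
  to $[0,1]$; `weighted = FALSE` gives the plain unweighted fit.
* **Background.** Both projections first have the mean of their left/right
  margin strips subtracted (`subtract_background()`, default 5% of the
  width per side), so air sits at zero.
* **Interpolation.** The estimator resamples with bicubic (Catmull-Rom)
  interpolation by default. Bilinear resampling blurs anisotropically with
  the local fractional offset, which biases the zero crossing of the shift
  measurement (about $0.15^\circ$ at $128^3$ scale, three times less with
  bicubic; both shrink with resolution). Plain `apply_planar_transform()`
  defaults to bilinear, matching common practice for bulk warping.

The per-iteration state — estimates, raw and applied steps, fit
coefficients, residual RMS, mean peak correlation, rows retained — is kept
in the fit's `trace` and shown by `summary()`; `plot()` displays the final
shift profile with its fitted line and the estimate trajectory. The fit
residual RMS is *not* monotone across early iterations (it measures how
well a line fits shear-contaminated shifts, not alignment quality); what
holds, and is tested, is that the final residual does not exceed the first.

## The simulator

`shepp_logan_3d()` samples the widely used ten-ellipsoid "modified"
(high-contrast) 3D Shepp-Logan head phantom — outer shell 1.0, inner shell
$-0.8$, internal features $\pm 0.1/-0.2$ — pointwise on an $n^3$ grid over
$[-1,1]^3$; the ellipsoid table is exposed by `shepp_logan_ellipsoids()`
and the continuous field by `shepp_logan_value()`. `simulate_tilt_series()`
computes parallel-beam line integrals (rotate-and-sum with bilinear
in-plane interpolation, unit steps, axis exactly through the centre); the
$180^\circ$ projection then mirrors the $0^\circ$ one to machine precision,
the symmetry everything else relies on.

`inject_misalignment()` applies the *same* in-plane rotation-then-shift to
every projection, emulating a fixed detector/stage misalignment. Applying
the transform in the projection domain (rather than transforming the
volume and re-projecting) makes injection and `correct_series()` exact
inverses and makes the effective mirror transform between the $0/180$ pair
equal `mirror_transform()` at exactly the injected parameters, so recovery
can be judged against a sharp ground truth. The trade-off is that the
uncorrected reconstructions it produces degrade somewhat more mildly at
the central slices than a volume-domain axis wobble would.

The simulator is deliberately austere: no noise by default (the pipeline
can add Gaussian noise), no Fresnel fringe formation, no cone-beam
geometry, no detector point spread. Passing tests therefore demonstrate
the geometry and the estimator's behaviour under ideal projection data;
robustness to phase-contrast fringes and photon noise on real beamline
data is outside what the synthetic suite can show, though the
background-subtraction, correlation-quality weighting and row filtering
are all aimed at that setting.

## Reconstruction and evaluation

`correct_series()` applies the inverse misalignment (translate $-\delta$,
then rotate $-\theta$ — the exact inverse of the injection order) to every
projection. `build_sinograms()` re-indexes the series losslessly;
`fbp_reconstruct()` filters each sinogram row with the discrete ramp
(Ram-Lak) kernel — built in the spatial domain ($h(0)=1/4$,
$h(k) = -1/(\pi k)^2$ for odd $k$) so the DC term is handled correctly,
applied by FFT with zero padding to at least twice the detector width —
then back-projects with linear detector interpolation, scales by
$\pi/(2\,n_{\text{angles}})$, and masks the inscribed circle. On an
analytic disk sinogram the interior RMSE is below 0.2% of the disk
amplitude; the operator is linear to machine precision. All coordinates
use a centre at $(n-1)/2$ (0-based), consistently across projection,
warping and back-projection.

The mass-centre baseline `mc_correct()` fits the intensity-weighted
per-projection centroid along $x$ to $A\cos\alpha + B\sin\alpha + c$ over
the tilt angles and shifts every projection by $-c$: a purely translational
correction that removes an axis offset exactly but cannot touch the flip
angle — which is precisely the comparison the geometric method is meant to
win for any rotational component.

Image quality is scored against the FBP of the *unperturbed* series (not
the phantom itself, so FBP's own artifacts cancel) on the four central
slices (`middle_slices()`). `mean_ssim()` is the canonical mean structural
similarity index: $11\times 11$ Gaussian window ($\sigma = 1.5$),
$K_1 = 0.01$, $K_2 = 0.03$, both images jointly rescaled to $[0,1]$ by the
reference min/max (so a common affine intensity change cancels), averaged
over the valid window positions; it agrees with scikit-image's
implementation to ten decimals on a fixed fixture. `mutual_information()`
uses an equal-width joint histogram over the combined range (default 256
bins, base-2 logarithm — values in bits), with $0\log 0 = 0$ and constant
images returning zero; `mutual_information(x, x)` equals the histogram
entropy of `x` exactly.

Two evaluation caveats are worth stating. First, with a smooth $256^3$
phantom, four *adjacent* central slices are nearly identical, so all
quality scores are nearly constant across them; protocols that pick four
slices spread along the axis would show marked slice-to-slice variation
instead. Second, scores depend visibly on the SSIM/MI configuration and on
how the misalignment was injected (projection- vs volume-domain), so
absolute values from different implementations are comparable only within
tolerance bands; orderings (geometric > mass-centre > uncorrected) are the
robust comparison, and hold here on every slice for both metrics.

## Problem sizes and defaults

The package's reference experiment — `pipeline_config()` defaults — is the
$256^3$ phantom, 181 projections at $1^\circ$ steps over $0$–$180^\circ$,
injected $\delta = 2$ px and $\theta = -5^\circ$, evaluated on the four
middle slices. The full simulate–estimate–correct–reconstruct–evaluate
chain runs in about a minute on one CPU; estimation alone (which only
needs the $0^\circ/180^\circ$ pair) takes a few seconds including phantom
generation and recovers the parameters to $\sim 0.01^\circ$ /
$\sim 0.001$ px at this scale. Property tests sweep
$\theta \in \{-8,\dots,8\}^\circ \times \delta \in \{-6,\dots,6\}$ px on
the $128^3$ phantom, where recovery is within $0.13^\circ$ and $0.02$ px
throughout. Estimator defaults: `max_iter = 20`, `tol_theta = 0.01` deg,
`tol_delta = 0.05` px; all measurement knobs are in `axis_control()`.

## Known limitations

* The method assumes small flip angles (the constructor rejects
  $|\theta| \ge 45^\circ$; accuracy degrades well before that) and an
  offset below a quarter of the detector width.
* Both $0^\circ$ and $180^\circ$ projections must exist; acquisitions
  spanning less than $180^\circ$ are out of scope.
* Axial ($\delta_y$) and beam-direction ($\delta_z$) stage offsets are
  ignored by design.
* The estimator needs lateral structure in the rows; a sample that is
  homogeneous along $x$ within the correlation window defeats it (rows are
  then dropped and, in the limit, estimation fails with an informative
  error).
* Iterative (ART-type) reconstruction, ring-artifact removal and phase
  retrieval are out of scope; `fbp_reconstruct()` is a plain Ram-Lak FBP.
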