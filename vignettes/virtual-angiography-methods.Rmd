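---
title: "Virtual angiography with virtangio: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual angiography with virtangio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtangio)
```

## The problem

Digital subtraction angiography (DSA) shows an injected contrast bolus
washing through the cerebral vasculature, and is the reference modality
interventionalists use to judge flow in and around aneurysms. A *virtual*
angiogram renders the same bolus passage from a hemodynamic simulation, so
that simulated flow can be compared, vessel by vessel and frame by frame,
with what was actually acquired. For the comparison to be meaningful the
virtual study must be individualized: it has to beat at the patient's heart
rate, start at the same cardiac phase as the acquisition, and inject the
bolus profile that actually arrived at the vessel inlet — none of which are
known a priori, all of which can be estimated from the acquired 2D DSA
series itself.

`virtangio` implements that workflow end to end:

1. **Contrast transport** — massless particles advected through a vessel
   lumen by a time-varying velocity field, with Gaussian smoothing to a
   concentration volume and a gradient-driven diffusion drift.
2. **Parameter extraction** — time-intensity curves (TICs) from a DSA
   sequence; heart rate from intensity-peak spacing; heart-state phase by
   aligning inflow-velocity minima with intensity maxima; the injection
   profile by fitting a capacitor-style charge/discharge curve.
3. **Forward projection** — idealized C-arm cone-beam projection matrices
   built from angulation, SID/SISOD and detector parameters, and ray-cast
   line integrals of the concentration volumes.
4. **Evaluation** — FWHM, time-to-peak, average wash-in/wash-out angles,
   and the shift/scale-aligned relative RMSE between normalized TICs.

The velocity field itself is an *input*: the package consumes gridded CFD
results (one cardiac cycle of vector volumes, wrapped periodically) or uses
its own analytic phantom fields. It contains no Navier–Stokes solver.

## Transport model

Contrast agent is a set of massless, non-interacting particles. Each step
of length $\delta t$ performs:

* **Advection** by the classical fourth-order Runge–Kutta scheme on
  $\dot\rho = f(t, \rho)$ with stages at $t$, $t+\delta t/2$,
  $t+\delta t/2$, $t+\delta t$. The step must satisfy the CFL-style bound
  $\delta t \le h_{\min} / v_{\max}$, which `simulate_transport()`
  enforces at configuration time.
* **Wall bounce-back**: a particle with $\varphi(x) < 0$ (outside the
  lumen; $\varphi$ is the level set, positive inside) is mirrored across
  the zero level set, $x \mapsto x - 2\varphi(x)\,\nabla\varphi/|\nabla
  \varphi|$, up to five times, then clamped to the nearest inside voxel
  center if still outside. No particle is ever lost through a wall, so the
  active count equals the cumulative injected count at every step.
* **Smoothing**: each particle deposits an isotropic Gaussian with
  covariance $\sigma I_3$ (voxel$^2$ units) centered at its exact off-grid
  position; the mixture sampled at the voxel centers is the concentration
  volume used both for rendering and for the diffusion gradient.
* **Boundary extension**: every outside voxel receives the value of its
  nearest inside voxel (exact Euclidean nearest, computed once per
  geometry and cached), which zeroes the concentration gradient across the
  wall so the diffusion drift cannot press particles into the boundary.
* **Diffusion** as a drift velocity $v_{\mathrm{Diff}} = -D\,\nabla C$,
  with the gradient taken by second-order central differences (one-sided
  at grid faces) and interpolated trilinearly at each particle. This is a
  deliberate, literal reading of the model: a strictly Fickian particle
  scheme would use $\nabla C / C$ or Brownian steps, but the coefficient
  $D$ here is an empirical smoothing/mixing parameter (typical values 0.1
  or 1.0, dimensionless), not a physical diffusivity, and users should
  treat it as such.

Injection happens at the start of each step, uniformly over the inlet
disk, with per-step counts produced by largest-remainder apportionment of
the total particle budget along the (normalized) bolus profile —
deterministic and exact in total mass.

### Numerical choices

* The smoothing kernel is truncated per axis at 4 standard deviations and
  not renormalized. A 3-standard-deviation cube truncation retains only
  $\operatorname{erf}(3/\sqrt2)^3 \approx 99.19\%$ of the mass, a 0.8%
  deficit that would be the dominant error in the conservation checks; at
  4 standard deviations the deficit is below 0.02%, at about twice the
  deposit cost.
* The nearest-inside-voxel map is computed by exact brute force in
  compiled code, scanning candidate inside voxels in ascending linear
  index with strict-less updates, so ties resolve deterministically to the
  lowest linear index — the same tie-break a naive `which.min` oracle
  produces. Separable feature transforms are faster asymptotically but do
  not guarantee that tie-break.
* Phantom tubes are *capped* cylinders,
  $\varphi = \min(R - r_{\perp},\, L/2 - |s|)$, kept at least two voxels
  inside the grid. End caps matter: they keep the full smoothing kernel of
  every particle inside the grid, so the concentration integral stays
  within 1% of the particle count even when particles congregate at the
  outlet. The outlet cap reflects like any other wall — the phantom is a
  closed test domain, and late-time pile-up at the outlet is expected and
  visible in long runs.

## Parameter extraction

### Heart rate and heart state

The acquired TIC is a bolus envelope multiplied by a cardiac modulation
(high inlet velocity dilutes contrast, so intensity maxima mark velocity
minima). `detect_peaks()` finds intensity peaks on a moving-average
smoothed curve with a prominence threshold (default 5% of the dynamic
range), a minimum separation (default 0.3 s, capping the detectable rate
at 200 bpm), and parabolic sub-frame refinement. The heart period is the
mean inter-peak interval; the rate is 60/period. Both are returned, since
the mean interval is a period even though the quantity is conventionally
quoted in bpm.

Peak positions on the bolus flanks are biased: a ripple riding a slope of
relative steepness $r = E'/E$ has its maximum displaced by roughly
$r / (d\,\omega^2)$, where $d$ is the modulation depth and $\omega$ the
cardiac angular frequency — easily 50–150 ms on a fresh wash-in flank,
which is far more than the half-frame accuracy heart-state synchronization
needs. `detect_peaks()` therefore subtracts a 1-s moving-average trend
before locating maxima (reducing the bias by a factor $1/d$), and the
composite estimator `extract_cardiac_params()` goes further:

1. fit the capacitor bolus model (whose family contains no oscillation,
   so the fit *is* the pulsatility-free envelope),
2. divide the TIC by the fitted envelope and detect peaks on the
   normalized modulation, without detrending (the moving average's edge
   padding would re-introduce bias near the span ends),
3. estimate period and phase by a weighted lock-in regression
   (least-squares sinusoid with envelope-squared weights), and
4. re-fit the *joint* model
   $I(t) = \mathrm{cap}(p, t)\,(1 + d\cos(2\pi f t - \theta))$
   by Levenberg–Marquardt, re-detecting peaks on the refined-envelope
   ratio.

The first and last peaks of the train, and peaks within 0.2 s of the
envelope's model corners (injection onset and plateau end), are the least
reliable; the period average drops end peaks when at least four remain,
and the phase comes from the joint fit's modulation-maximum time rather
than from any single peak. On synthetic sequences with known truth this
pipeline recovers the rate to ~0.3 bpm and the phase to ~2 ms — an order
of magnitude inside the tolerances the round-trip tests assert (±2 bpm,
±half a frame at 30 fps).

Heart-state synchronization reduces the detected peaks to one cardiac
phase (circular mean modulo the period), extrapolates backward to the
first peak time $t^\* \ge t_0$, and phase-shifts the inflow waveform so
its velocity minimum lands on $t^\*$. When no peaks are detectable (short
or truncated injections), the pipeline proceeds unsynchronized with a
configured fallback rate, with a warning — matching clinical reality,
where some acquisitions simply do not carry usable pulsatility.

### Bolus model

The injection profile is the capacitor charge/discharge curve with five
parameters: onset delay $p_1$, injection duration $p_2$, charging and
discharging time constants $p_3, p_4$, amplitude $p_5$:

$$I(t) = \begin{cases}
0 & t < p_1 \\
p_5\,(1 - e^{-(t-p_1)/p_3}) & p_1 \le t < p_1 + p_2 \\
p_5\,(1 - e^{-p_2/p_3})\,e^{-(t-(p_1+p_2))/p_4} & t \ge p_1 + p_2
\end{cases}$$

The decay branch is anchored at the plateau's end value, which makes the
curve continuous and non-negative — the defining properties of the
capacitor analogy. Fitting uses `minpack.lm` (Levenberg–Marquardt) with
numerical Jacobians, box bounds enforcing the parameter invariants, and
five multi-starts seeded from the 10%-rise time, the FWHM, and the curve
maximum, because the loss surface is multimodal in $p_1$. The fitted curve
resampled at the transport step midpoints and normalized to unit sum is
the injection profile.

## Projection geometry

The C-arm is an ideal pinhole: world origin at the isocenter (+x patient
left, +y anterior, +z head), source at $(0, -\mathrm{SISOD}, 0)$ and
detector at $y = \mathrm{SID} - \mathrm{SISOD}$ for the anteroposterior
(0°, 0°) view. The primary angle (LAO positive) rotates the
source–detector assembly about the head–feet axis and the secondary angle
(CRAN positive) about the left–right axis, composed as
$R_x(\text{secondary})\,R_z(\text{primary})$ — the standard clinical
convention and gantry order (cranial tilt on top of the LAO/RAO sweep).
Intrinsics are $\mathrm{SID}/\text{pixel spacing}$ with the principal
point at the configured isocenter pixel, so the world isocenter projects
onto it exactly; the 3×4 matrix is normalized to a unit ray-direction
third row. Gantry sag, detector distortion, scatter and noise are
deliberately out of scope. Calibrated matrices from a real system can be
substituted for the constructed ones wherever a `projection_matrix` is
accepted.

Rendering casts one ray per detector pixel, samples the concentration
volume equidistantly (default half the smallest voxel spacing) inside the
volume's bounding box, and sums samples times step length — a line
integral of concentration standing in for X-ray attenuation. Output images
are raw line integrals (contrast bright); DSA-style inversion is purely a
display flag, because every downstream metric operates on opacification.

## Evaluation metrics

All TIC metrics operate on the curve min–max normalized to 0–100, and are
therefore invariant to affine intensity rescaling. Level crossings (10%
and 50%) are located by linear interpolation, taking the first upward and
the last downward crossing for multi-modal curves. FWHM is the distance
between the half-maximum crossings; TTP runs from the first 10% crossing
to the maximum; the average wash-in/wash-out angles are
$\arctan(\Delta I / \Delta n)$ with $\Delta I$ on the 0–100 scale and
$\Delta n$ counted in frames at the sequence frame rate (the time base is
configurable and recorded, since the angle convention is otherwise
ambiguous). A curve that never recrosses half maximum gets `NA` FWHM, not
zero.

The rRMSE between a real and a virtual TIC normalizes the real curve to
0–100, then searches integer-frame shifts in a bounded window (default
±1 s) with the closed-form least-squares scale at each shift, and reports
$\sqrt{\tfrac1n \sum ((P_i - a T_{i+s})/\bar P)^2} \times 100$ at the
minimizing $(s, a)$. Exhaustive shift search plus closed-form scale is
deterministic and exactly testable against a brute-force oracle. Arterial
cropping (to exclude venous overlay) is a user decision; normalization is
computed after cropping, and the window is recorded in the report.

`spectral_peak_bpm()` measures the dominant cardiac periodicity of a TIC.
Short records make this surprisingly delicate: over four or five cycles,
the bolus transients leak phase-coherent power into the cardiac band and
displace a plain periodogram peak by several bpm. The estimator therefore
divides out the fitted capacitor envelope, weights samples by the squared
envelope (ratio noise grows where the envelope is small), masks samples
near the envelope's model corners, and scans a weighted least-squares
sinusoid fit over the physiological band (0.6–3.4 Hz), refining the
maximum numerically. Without a usable envelope fit it falls back to a
detrended, Hann-windowed, zero-padded FFT periodogram.

## The synthetic DSA generator

`make_synthetic_dsa()` fabricates an acquisition with known ground truth:
per-pixel intensity inside a vessel mask is
$\mathrm{cap}(p, t - \text{delay}) \times (1 - d\,m(t))$ plus white
Gaussian noise, where $m(t) = -\cos(2\pi (t - \phi)/T)$ is a unit-
amplitude, zero-mean modulation. Intensity maxima fall exactly at
$\phi + kT$ (the phase the extraction must recover), and because $m$ has
zero mean, the cycle-averaged envelope equals the bolus curve, so the
fitted amplitude is unbiased. Defaults model a standard acquisition:
30 fps for 12 s, 84 bpm, bolus $(1, 3, 0.2, 0.5, 10)$, 20% modulation,
noise at 1/20 of the bolus amplitude.

What the generator does *not* emulate: X-ray physics (quantum noise,
scatter, beam hardening), patient or gantry motion, vessel overlap and
venous return, or the flow-dependent waveform distortion a real vascular
tree imprints. Passing round trips therefore demonstrate that the
estimators are correct and well-conditioned under the stated signal
model — not that they are robust to every clinical artifact.

The inflow waveform template is a raised cosine plus a sharpened systolic
peak: $v(u) = v_{\min} + (v_{\max}-v_{\min})\,(\alpha c(u) +
(1-\alpha)c(u)^{\gamma})$ with $c(u) = (1+\cos 2\pi u)/2$, $\alpha = 0.35$
and $\gamma$ solved so the cycle average matches the requested mean. Only
min/mean/max/period are contractual. The cosine base term keeps velocity
varying throughout diastole, as physiological carotid waveforms do; a
template that is flat between systolic peaks imprints a flat-topped
intensity modulation whose fundamental frequency is nearly unobservable in
short records.

## The end-to-end demonstration study

`demo_workflow_config()` assembles a complete desk-scale study:

* geometry: 64³ grid at 0.6 mm, a 3 mm-radius, 30 mm tube along the
  patient axis with a 4.5 mm spherical sac on its wall — the classic
  sidewall-aneurysm phantom;
* inflow: plug profile, 0.28–0.37 m/s with mean 0.31 m/s (a typical
  internal-carotid range), rigid recirculation in the sac;
* measured sequence: the synthetic generator at its standard conditions
  (84 bpm, default bolus, 30 fps, 12 s);
* transport: 10⁴ particles for 5 s at $\delta t = 1.5$ ms — the CFL bound
  for 0.37 m/s on 0.6 mm voxels — with $D = 0.1$, $\sigma = 1$, snapshots
  at 20 fps;
* rendering: anteroposterior (0°, 0°) and lateral (−91°, −0.2°) views,
  96² detector at 0.75 mm pixels, SID 1200 mm / SISOD 800 mm.

The study extracts the heart rate and phase from the synthetic sequence,
synchronizes the waveform, fits and injects the bolus, simulates, renders
both views, and is checked on three properties: the virtual inlet TIC
correlates with the injected bolus (r > 0.95), a distal TIC's spectral
peak sits at the configured heart rate (±2 bpm), and swapping the fitted
bolus for a generic rectangular one of FWHM-matched duration measurably
changes the inlet TIC. The distal probe is placed 8 mm downstream of the
sac — past the aneurysm but clear of the outlet cap, where reflected
particles accumulate late in the run and would contaminate the
measurement. Problem sizes throughout (10⁴ particles, 64³ grids, 5 s
simulated) are chosen as the smallest at which every property is
comfortably measurable; the same code runs a full-scale 10⁶-particle
configuration unchanged, only slower.

## Known limitations

* The diffusion drift is model-faithful but not Fickian; concentration-
  dependent mixing is not captured, and $D$ has no physical units.
* Gridded velocity input assumes one periodic cardiac cycle; transients
  across cycles (e.g., developing flow) are out of scope.
* The idealized projection geometry ignores gantry non-idealities, so
  virtual and real angulations can disagree by small amounts on real
  hardware.
* Contrast settling under gravity, venous overlay, and motion artifacts
  are not modeled; rRMSE comparisons on clinical data should be cropped
  to the arterial phase, as the tooling encourages.
* Phantom outlets reflect rather than absorb. This is the right contract
  for conservation testing, but long simulations accumulate contrast at
  the outlet cap; place measurement ROIs away from it.
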