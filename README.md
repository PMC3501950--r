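# virtangio

Patient-individualized **virtual digital subtraction angiography (DSA)**
in R: simulate contrast-agent transport through a vessel geometry as
discrete particles driven by a time-varying velocity field, extract
patient-specific parameters (heart rate, heart-state phase, bolus
injection profile) from acquired 2D DSA sequences, render virtual DSA
sequences by C-arm cone-beam forward projection, and compare real and
virtual angiograms quantitatively through time-intensity curves (TICs).

The package is aimed at hemodynamics researchers who post-process CFD
velocity fields of cerebral vessels (typically aneurysms) and want
side-by-side, quantitative comparisons with catheter angiography. The
velocity field is an input — gridded per-cycle vector volumes from any
CFD solver, or the built-in analytic phantom fields; no flow solver is
included.

## The model in brief

Contrast agent is a set of *n* massless particles ρᵢ ∈ ℝ³ advected by a
velocity field *f*(t, x):

* **Advection**: classical RK4 on ρ̇ = f(t, ρ) with dt bounded by the CFL
  condition dt ≤ h/vmax; particles crossing the wall are bounced back by
  mirroring across the zero level set of the vessel's signed-distance
  function φ (φ > 0 inside the lumen).
* **Smoothing**: each particle deposits a Gaussian with covariance σ·I₃
  (voxel² units) at its exact position; the mixture sampled on the CFD
  grid is the concentration volume C(x, t).
* **Diffusion**: a drift v_Diff = −D·∇C, with ∇C from central differences
  after extending C over the boundary via an exact nearest-inside-voxel
  (distance-transform) map, so the wall-normal gradient vanishes.
* **Injection**: per-step particle counts are a largest-remainder
  apportionment of the total budget along the injection profile I(t) —
  a five-parameter capacitor charge/discharge curve (onset p₁, duration
  p₂, time constants p₃/p₄, amplitude p₅) fitted to the measured inlet
  TIC by Levenberg–Marquardt.
* **Heart rate / heart state**: the heart period is the mean spacing of
  successive TIC intensity peaks, h = (1/(n−1))·Σ(pᵢ − pᵢ₋₁); the inflow
  waveform is phase-shifted so velocity minima coincide with intensity
  maxima.
* **Projection**: idealized pinhole C-arm, P = K·[R | t] built from the
  LAO/RAO and CRAN/CAUD angles, SID, SISOD and detector pixel spacing;
  images are equidistantly sampled ray-cast line integrals of C.
* **Comparison**: FWHM, time-to-peak, average wash-in/wash-out angles,
  and the relative RMSE √[(1/n)Σ((Pᵢ−Tᵢ)/T̄)²]·100 between normalized
  TICs after an exhaustive integer-frame shift and closed-form scale
  alignment.

## Worked example

The built-in demonstration study builds a 64³ sidewall-aneurysm phantom
(3 mm tube, 4.5 mm sac, 0.6 mm voxels), fabricates a synthetic "measured"
DSA at 84 bpm with a known capacitor bolus, extracts the patient
parameters from it, transports 10⁴ particles for 5 s of pulsatile plug
flow (0.28–0.37 m/s), and renders anteroposterior and lateral views:

```r
library(virtangio)

cfg <- demo_workflow_config(seed = 1)
run <- run_workflow(cfg)
cat(run$log, sep = "\n")
#> heart rate extracted: 84.2 bpm (envelope-normalized)
#> heart state synchronized: shift 0.512 s
#> simulating 3334 steps of 0.0015 s with 10000 particles

# virtual inlet TIC vs the injected bolus shape
ap <- cfg$carm[[1]]
vi <- extract_tic(run$renders[[1]],
                  roi_box_around(ap, cfg$geometry$inlet$center, 4))
cor(vi$intensities, capacitor_eval(run$bolus$params, vi$times))
#> [1] 0.9616

# does the distal TIC still beat at the patient's heart rate?
distal <- cfg$geometry$meta$center + 8 * cfg$geometry$meta$axis
vd <- extract_tic(run$renders[[1]], roi_box_around(ap, distal, 4))
spectral_peak_bpm(vd)
#> [1] 84.23
```

The extracted heart rate (84.2 bpm) matches the 84 bpm ground truth of
the synthetic acquisition; the virtual inlet TIC tracks the fitted
injection bolus (r = 0.96); and the cardiac modulation survives transport
and projection, reappearing in a distal ROI at 84.2 bpm. The run takes
roughly a minute on one core. `run$comparison` (when ROIs are configured)
holds the FWHM / wash-in / wash-out / TTP / rRMSE table for paired ROIs.

A thin command-line wrapper is installed with the package
(`system.file("cli", "virtangio", package = "virtangio")`) with
subcommands `phantom`, `synth-dsa`, `extract-params`, and `run`
(`run --demo` executes the study above and writes all artifacts:
concentration NIfTI series, rendered TIFF stacks, TIC CSVs, and a JSON
run manifest).

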