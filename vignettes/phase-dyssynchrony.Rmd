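---
title: "Phase dyssynchrony analysis of gated myocardial perfusion SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase dyssynchrony analysis of gated myocardial perfusion SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectsync)
```

## The measurement

In ECG-gated myocardial perfusion SPECT, the apparent counts of a myocardial
region rise and fall over the cardiac cycle because the wall is thinner than
about twice the system resolution: through the partial-volume effect the
peak intensity of a structure scales with its thickness, so regional
time-activity curves (TACs) track wall thickening. Fitting the fundamental
cosine

$$v(k) = a_0 + a_1 \cos(2\pi k/N - \phi_1), \qquad k = 0,\dots,N-1,$$

to a TAC of $N$ gated frames yields the contraction **phase** $\phi_1$ — the
cycle angle (degrees) at which the count curve peaks, i.e. end-systole for
that region. Collecting phases over hundreds of myocardial samples gives a
phase distribution whose dispersion quantifies left-ventricular mechanical
dyssynchrony:

* **PSD** — standard deviation of the phase distribution (degrees);
* **95% bandwidth** — width of the histogram region holding 95% of samples
  (degrees);
* **phase entropy** — normalized Shannon entropy of the binned histogram,
  $E = -\sum_i f_i \log f_i / \log n$ with $0\log 0 = 0$, ranging from 0
  (complete order) to 1 (complete disorder), conventionally reported in
  percent.

A second family works on the AHA 17-segment model: each segmental TAC is fit
with the fundamental plus second harmonic, and **TES** (time to end-systole,
degrees) is the cycle angle maximizing the fitted curve. MDTES (max
segmental difference), SDTES (SD) and DTES-LS (mean lateral minus mean
septal TES) are expressed in percent of the cycle (division by 360).

## Pipeline conventions

Several steps are unavoidably underdetermined by common practice; the
package fixes one documented convention each, with a switch where vendors
are known to differ.

* **Sampling.** Per-slice count-weighted centroids (3-slice axial running
  mean) define the sampling centers; 36 angular samples per slice (offset 5°
  so samples straddle, rather than sit on, AHA sector edges); the TAC value
  is the maximum count along the radial ray within a ±20 mm annulus around
  the frame-summed profile peak — the standard maximal-count
  circumferential-profile (polar map) convention. Slices whose total counts
  fall below 10% of the busiest slice are excluded.
* **Phase convention.** Peak-count phase (end-systole), cosine form with
  nonnegative amplitude, in [0, 360). PSD, bandwidth and entropy are
  invariant to any global phase convention shift, so this choice does not
  affect the dyssynchrony indices. Samples whose first-harmonic amplitude
  falls below 2% of their mean counts are excluded from the histogram — the
  explicit analogue of the silent suppression of non-contracting samples in
  clinical software (configurable).
* **Frame timing.** Frame $k$ covers cycle angle $[k, k+1)\cdot 360/N$ and
  the generator evaluates the model at the bin midpoint, while the harmonic
  fit indexes samples at $k\cdot 360/N$; absolute phases therefore carry a
  constant half-frame offset ($360/2N = 11.25°$ at 16 frames) that cancels
  in every dispersion index and every TES difference.
* **PSD** recenters the distribution at its circular mean before taking the
  population SD, so a {350°, 10°} pair reads 10°, not 170°
  (`recenter = FALSE` restores the naive behaviour for emulation studies).
* **Bandwidth** is the shortest circular arc containing ≥95% of samples,
  computed exactly by sweeping sorted positions; the alternative
  symmetric-trim convention is available (`mode = "trim"`). With fewer than
  20 samples a 95% width is ill-defined; the full range is returned with a
  flag.
* **Entropy** is computed on a 1° histogram. The defining formula is used
  with the sign fixed so that the result is nonnegative and equals 1 for
  the uniform histogram.
* **TES alignment.** Before MDTES/SDTES/DTES-LS, segmental TES values are
  rotated so their circular mean is 180°, preventing a 359°/1° pair from
  reading as a 358° spread. DTES-LS uses lateral = {5, 6, 11, 12} and
  septal = {2, 3, 8, 9} (basal + mid anterolateral/inferolateral vs
  anteroseptal/inferoseptal); the membership is an explicit, overridable
  argument because the level convention is not standardized.
* **Base handling.** The basal 20% of used slices are flagged; automatic
  base cut removes flagged slices whose mean TAC amplitude falls below 50%
  of the mid-ventricular mean (never more than 40% of slices), emulating
  the manual basal adjustment and basal circular removal functions of
  clinical packages. Phase-map smoothing (`smooth_phases()`) is off by
  default and wrap-safe when enabled.

## The digital phantom

The generator exists to provide studies with *known* contraction timing,
geometry and noise, under an acquisition envelope chosen to match a
resting normal database: 16 frames per cycle, 64×64 matrices (6.4 mm
pixels, 24 slices of 6.4 mm — matrix-internal values, configurable, since
acquisition protocols rarely publish them), and a noise-free maximum
myocardial count of 123 counts/pixel.

The left ventricle is a half-ellipsoid shell (hemispheric apex, open base,
long axis along the slice axis, cavity long-to-short axis ratio 2) of
uniform tracer concentration. Per segment,

$$w(t) = w_{ED} + \Delta w\,\bigl(1 - \cos(\theta_t - \delta_{seg})\bigr)/2,$$

so wall thickness peaks at cycle angle $180° + \delta_{seg}$; the injected
delays $\delta_{seg}$ are the ground truth that the pipeline must recover.
Each segment's endocardial radius follows the same local waveform
(regional inward motion and regional thickening share one clock, as in a
real dyssynchronous ventricle), scaled so that the global cavity volume
interpolates exactly from EDV to ESV: with pure radial contraction the
volume is proportional to the sector mean of the squared radial scale,
which the model fixes at $1 - EF\cdot \bar s(t)$. The long axis is held
fixed — a deliberate idealization that avoids through-plane motion, which
slice-wise sampling cannot distinguish from timing effects.

Counts are produced by the partial-volume mechanism itself: the uniform
shell is convolved with the system PSF and sampled on the voxel grid, so
thicker walls produce brighter pixels without any imposed brightness
curve. Numerically the convolution is applied *analytically*: the blurred
profile across a locally planar slab is an error-function difference of
the signed distances to the endo- and epicardial surfaces, with
$\sigma_{\mathrm{eff}}^2 = \sigma_{PSF}^2 + h^2/12$ absorbing the voxel
footprint ($h$ = pixel size). This keeps the sampled field band-limited —
rasterizing a hard shell and blurring afterwards leaves aliasing from the
moving boundary that masquerades as several degrees of phase dispersion.
The approximation is exact for flat interfaces; the curvature error is
$O(\sigma^2/R)$ and, importantly, smooth over the cycle. Segment timing
transitions are sharp in angle (the PSF acts through-wall, not
circumferentially); the phantom therefore slightly *under*-mixes adjacent
sectors compared with a full 3-D convolution.

Defaults and their provenance: EDV 75 mL and EF 0.69 (rounded all-subject
normal means of a resting database), end-diastolic wall 10 mm, systolic
thickening 5 mm, PSF FWHM 12 mm (typical reconstructed SPECT resolution),
maximum counts 123. Poisson noise is applied after count scaling and can
be disabled for deterministic tests. Ground-truth AHA segments are painted
with the same used-slice and slice-banding rule the analysis applies
(apical cap ≈ 15% of used slices, then apical/mid/basal thirds), so
injected and recovered segment memberships align by construction.

What the phantom does **not** emulate: projection/reconstruction physics
(attenuation, scatter, FBP streaks, distance-dependent resolution),
perfusion defects beyond per-segment uptake scaling, right-ventricular and
extracardiac activity, long-axis shortening, and gating errors. Passing
recovery tests on this phantom therefore demonstrates that the *analysis*
is correct and well-conditioned at clinical resolution and count levels —
not that any particular clinical population will show particular values.

## The simulated cohort

`make_cohort()` draws per-subject EDV and EF from per-sex normal
distributions (defaults: male 84.4 ± 15.7 mL / 0.665 ± 0.061, female
64.1 ± 12.1 mL / 0.720 ± 0.057, n = 36/33; truncated at ±3 SD, EF within
[0.40, 0.85]) and jitters per-segment delays with SD 8° — the scale that
reproduces the normal-range segmental TES spread of roughly 2% of the
cycle. Two physiological couplings generate the cohort-level structure:

1. **Count statistics vs heart size.** With a fixed injected dose, a larger
   heart accumulates fewer counts per pixel; `counts_scaling = "volume"`
   makes the maximum count inversely proportional to myocardial shell
   volume (normalized to 123 at the cohort mean). Larger (male) hearts are
   therefore noisier, and noisier phases are more dispersed. There is *no*
   intrinsic sex term in contraction timing: the sex difference in the
   dyssynchrony indices is a count-statistics artifact by construction,
   and disabling the scaling provides the corresponding null.
2. **Thickening vs EF.** Within cohorts, systolic thickening is set to
   `wall_mm_ed * ef`, since ejection fraction and systolic wall thickening
   track each other; lower-EF subjects have weaker count modulation, hence
   noisier phases.

Together these produce, on simulated data, the qualitative design of a
normal-database study: male > female PSD/bandwidth/entropy, PSD increasing
with EDV, PSD decreasing with EF — directions the acceptance suite verifies
over 20 seeded cohorts by sign tests. The numeric normal limits of any real
database depend on proprietary edge-detection and filtering chains and are
out of scope.

## Volumes and EF

`estimate_volumes()` is a declared simplification of the threshold family
of clinical algorithms: per frame, slice and angle the endocardial boundary
is the inner radial position where counts first exceed 45% of the profile
maximum (sub-pixel by linear interpolation); cavity volume is the enclosed
area integral summed over slices. It is scale-invariant and, on noise-free
phantoms, recovers EF within ~1–2 points across the 0.4–0.8 range; EDV
carries a systematic negative bias of order 15% (threshold crossing sits
inside the blurred endocardial edge), which is why cohort analyses can
switch to ground-truth volumes (`volumes = "truth"`) when estimator error
must not confound a volume covariate. No attempt is made to reproduce any
vendor's absolute EF/EDV calibration.

## Numerical choices and degenerate inputs

* Harmonic fits use the least-squares design matrix; for uniform sampling
  this equals the DFT coefficients, which the tests exploit as an
  independent oracle (agreement to 1e-9 on random curves). Constant TACs
  return zero amplitude with an explicit undefined-phase flag rather than
  an arbitrary phase.
* TES is located on a 0.1° grid and refined by local quadratic
  interpolation (dense-grid agreement within 0.05°); exact ties return the
  smaller angle with a flag.
* Histogram bins are half-open with the lower edge inclusive; bin width
  must divide 360.
* `normal_limits()` uses the sample SD (n − 1), unrounded — cohort
  statistics; `psd()`/`sdtes` use the population SD — descriptors of a
  fixed sample set. Rounded-then-recomputed limits in published tables can
  differ in the last digit; the package does not emulate that rounding.
* Problem sizes in the test suite: unit tests run on a 32×32/12-slice
  phantom; end-to-end acceptance checks use the full 64×64/24-slice
  geometry, 20 seeded cohorts of 69 subjects for the directional
  replication, 500 null simulations for type-I calibration, and 1000
  random curves for the DFT oracle — sizes chosen to make every check
  statistically meaningful at interactive runtimes.

## Known limitations

* The phantom's idealizations listed above; in particular the absence of
  reconstruction physics means absolute dyssynchrony values are smoother
  than clinical ones at matched counts.
* Slice-wise (2-D) sampling near the apex treats oblique wall crossings as
  in-plane walls; the apical cap segment is the least reliable, as in
  clinical polar-map practice.
* Wilcoxon p-values are exact only for small untied groups (≤10 per
  group); elsewhere the normal approximation with tie correction is used.
* The pipeline analyzes short-axis count volumes; reconstruction from
  projections, DICOM/Interfile ingestion and vendor polar-map formats are
  out of scope.
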