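---
title: "Edge-overshoot artifacts of PSF reconstruction in sub-centimeter PET lesions: the rcpet simulation lab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-overshoot artifacts of PSF reconstruction in sub-centimeter PET lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical PET scanners resolve about 4–5 mm FWHM. For lesions of comparable
size, partial-volume effects depress the measured activity concentration,
and iterative reconstruction with resolution modelling ("PSF
reconstruction") is routinely used to sharpen images and improve
detectability. But resolution-modelled EM is a deconvolution, and
deconvolution of a band-limited signal rings: at sharp activity boundaries
it produces Gibbs-type edge overshoot. For sub-centimeter hot lesions the
overshoot can dominate the lesion core, with consequences that matter
clinically when SUV-type measures steer treatment decisions: recovery
coefficients (RC = measured / true activity concentration) that exceed 1,
that do *not* fall monotonically as the lesion shrinks (peaking near 8 mm),
that converge slowly with iterations, and that are noisier than their
non-PSF counterparts.

`rcpet` reproduces this artifact class end to end in silico: a digital
dual-isotope sphere phantom, a Poisson projection-data simulator with a
finite system resolution, (OS)EM reconstruction with optional image-space
resolution modelling, the standard sphere-VOI recovery metrics, and the
experiment drivers that sweep contrast, iterations, post-filter width and
noise realizations.

## The phantom model

The simulated phantom mirrors a wall-less multi-sphere design: twelve gel
spheres (diameters 10, 10, 6, 6, 12, 4, 10, 3, 8, 4, 4, 6 mm) filled with
¹⁸F (T½ = 109.77 min) at a common concentration, strung along a line and
suspended directly — no cold wall — in a ¹¹C background (T½ = 20.36 min)
that starts at the same concentration. Because the background decays five
times faster, the *true sphere-to-background ratio* of an acquisition frame
grows from 1:1 toward 15:1 purely by differential decay; no refilling or
rescanning is needed. A large ¹⁸F region beside the background serves as
reference: its central 6-mL VOI measures the true sphere concentration, and
a 15-mL VOI inside the background measures the background level. Both are
large enough to be immune to resolution effects.

Concretely (`phantom_default()`):

* sphere string along x, 24 mm center spacing, centers snapped to voxel
  centers (a `center_offset` exists for robustness studies);
* background: axis-aligned box, 300 × 40 × 48 mm (576 mL ≥ the nominal
  250 mL), wide enough that the 15-mL VOI clears both the spheres and the
  box faces by at least 2σ of the system blur;
* reference region: the 6-mL measurement block padded by 10 mm on every
  face, so the VOI mean is untouched by edge blur;
* grid: 2-mm isotropic, phantom plus an 18-mm (4 × FWHM) margin;
* frame schedule: 11 × 10-min frames from t = 0. The frame-*averaged*
  ratio (which is what a frame measures) reaches ≈ 1.14 in frame 1 and
  ≈ 18 in frame 11, so the full 1:1 → 15:1 sweep is covered.
  `phantom_compact()` keeps one sphere per diameter for faster runs.

The "cube-shaped" measurement VOIs are realized as near-cubic voxel blocks
holding exactly `round(volume / voxel_volume)` voxels — 750 voxels
(15 × 10 × 5) for 6 mL and 1875 (25 × 15 × 5) for 15 mL on the 2-mm grid —
because no integer cube matches those volumes exactly and an exact count
makes the measurement deterministic.

Rasterization is volume-weighted: for each voxel crossed by a sphere
surface the fill fraction is midpoint-sampled in the transaxial plane
(4 × 4 sub-positions by default, automatically refined when the sphere is
small relative to the voxel) and integrated *analytically* along z as the
sphere chord clipped to the voxel — purely center-based sub-voxel counting
was tried first and misstates the 3-mm sphere's activity by up to 20% at
default sampling, which would bias its recovery directly. With the hybrid
scheme total sphere activity matches the analytic volume to better than 1%
for every diameter at the default setting. `supersample = 1` falls back to
binary voxel-center rasterization.

## Acquisition model

The scanner is reduced to what the artifact needs: an isotropic Gaussian
detector response (default FWHM 4.5 mm, the NEMA-style resolution of the
emulated clinical systems), slice-wise 2D parallel-beam line integrals
(336 views over 180°, radial bins at the voxel pitch), and independent
Poisson counting. Attenuation, scatter, randoms and TOF are deliberately
absent — the simulator emits already-corrected, mean-preserving data, which
is what a corrected clinical sinogram approximates. The projector is
voxel-driven (each voxel's mass linearly shared between the two radial bins
bracketing its projected center), which makes every view conserve mass
exactly and makes the adjoint the exact matrix transpose — properties the
EM update depends on and the test suite asserts.

Counting statistics: physical phantom studies rarely report per-frame
prompt counts, so the default is chosen once at a realistic clinical
magnitude — 5 × 10⁸ expected
counts for the 1:1 frame, decaying with the phantom activity thereafter
(the ~13:1 frame retains ≈ 6% of that). At this level the late-frame RC
standard deviations are ~0.01–0.05: error bars are visible but the
systematic curves are not drowned. (Much lower totals push the
maximum-based metrics into a noise-dominated regime that *biases* them
upward for the large spheres.)

## Reconstruction

`reconstruct()` is ordered-subset EM with interleaved angular subsets in a
fixed spread-out visiting order, a uniform positive initial image scaled to
the measured counts, and a multiplicative update guarded by
ε = 10⁻¹² × max(expectation) in ratio denominators. With
`psf_modeled = TRUE` the system matrix becomes B = P∘G: a Gaussian kernel G
in image space before projection and its adjoint after backprojection —
the simplest model that reproduces the clinical artifact class. The kernel
defaults to the *matched* width (4.5 mm, equal to the simulated system
response); the overshoot persists even then, which is the point. A Gaussian
post-filter is applied once after the final iteration (vendor conventions
differ; once-at-the-end is deterministic and makes a single reconstruction
with per-iteration snapshots serve a whole iterations × filters sweep).
Clinical subset counts are the defaults: 16 without PSF, 21 with PSF —
hence 336 views, divisible by both.

All Gaussian operators (system blur, modelled kernel, post-filter) share
one numerical contract: a sampled Gaussian, σ = FWHM/2.3548 per axis,
truncated at 6σ+1 voxels, unit-normalized, zero-padded at the grid
boundary. Two numerical notes: (i) the sampled-kernel composition law
(filtering by a then b equals filtering by √(a²+b²)) is exact only up to
sampling error, which is negligible (< 10⁻⁶) once σ exceeds ≈ 1.5 voxels
but grows to percent level for sub-voxel σ; the tests exercise it in its
valid regime. (ii) A discrete-Gaussian (Bessel) kernel would make the
composition exact at any width, but its lattice shape at σ ≈ 1 voxel
weakens the deconvolution ringing enough to suppress the very overshoot
under study, so the field-standard sampled kernel is used.

## Quantification

Per sphere, a spherical VOI with the *physical* diameter is centered on the
known position; voxels count as members when their centers lie strictly
inside (ties, as for the 4-mm sphere whose radius equals the grid pitch,
fall outside; an empty VOI falls back to the single nearest voxel — the
3-mm VOI is one voxel on the 2-mm grid). Three metrics are taken inside the
VOI only:

* `A_max` — maximum voxel value;
* `A_50bg` — mean over the background-corrected 50% isocontour,
  `T = bg + 0.5 (A_max − bg)` (the EARL-style convention; the isocontour is
  restricted to the VOI, not grown beyond it);
* `A_avg` — plain mean over the VOI.

RCs divide these by the true concentration — by default the *measured*
reference-VOI mean of the same frame ("measured-truth", mirroring phantom
practice; `truth = "oracle"` uses the analytic value instead). The
background entering `A_50bg` is the measured 15-mL VOI mean of the same
frame. Being ratios, RCs are independent of decay correction and of the
image's absolute scale; the suite asserts both.

## The experiments

* `run_contrast_sweep()` — frames 1…11 × reconstruction variants; RC vs
  true ratio. At 1:1 all RCs sit near 1 (spill-in balances spill-out);
  without PSF the monotone size ordering emerges as contrast grows; with
  PSF the ordering breaks with an interior maximum at every contrast.
* `run_iteration_sweep()` — one frame near 8:1, iterations 1–6 ×
  post-filters {2, 3, 4, 6} mm from two reconstructions (snapshots +
  post-hoc filtering). Shows the slow PSF convergence and the
  filter-width trade-off; `find_minimal_restoring_filter()` extracts the
  smallest width restoring monotonicity (and, optionally, RC ≤ 1).
* `run_reproducibility()` — N independent noise realizations of a late
  (~13:1) frame; `summarise_reproducibility()` gives the mean ± SD per
  sphere and variant. PSF reconstruction is the less reproducible one for
  most diameters.
* `monotonicity_diagnostics()` — per curve: monotone flag (non-decreasing
  in diameter within a configurable tolerance, default 0.02 RC to absorb
  sampling jitter; ties allowed), argmax diameter (ties to the largest),
  maximum RC, count of RCs above 1.

## Problem sizes and determinism

The test suite runs the compact 6-sphere phantom (one sphere per diameter;
grid ≈ 122 × 39 × 43 at 2 mm) and reduced toy systems for the algebraic
identities; the acceptance script runs the full 12-sphere phantom
(grid ≈ 195 × 39 × 43). One PSF reconstruction at 6 × 21 updates takes
seconds at these sizes. Every stochastic step draws from a private,
explicitly seeded RNG stream (derived per frame × replicate from one base
seed), so identical configurations are bit-identical and the caller's RNG
state is never disturbed.

## What passing does and does not show

The simulator reproduces the *mechanism* (deconvolution ringing at sharp
boundaries under Poisson statistics) and the qualitative-numeric behavior
built on it. It does not model: positron-range dependence on the medium
(only the ¹¹C-background arm exists here — the air/silicone ordering of
real phantoms is a physical-medium effect), TOF weighting, vendor kernel
shapes (possibly anisotropic or spatially variant), attenuation/scatter
correction noise, oblique 3D projection planes, or phantom manufacturing
variability. Absolute RC values are therefore scanner- and kernel-specific
here as in reality; it is the pattern — overshoot above 1, the ~8-mm
interior maximum, delayed convergence, filter suppression, degraded
reproducibility — that transfers.

## Design choices made where the design was open

* Sphere spacing/order along the string is unreported in the physical
  design; 24-mm spacing in diameter order is used and configurable.
* The dual subset counts (16/21) force 336 views (their lcm); a 180-view
  default would not admit either clinical subset count.
* The 11th frame exists because the frame-averaged ratio of a 10 × 10-min
  schedule tops out near 14:1; one more frame covers the full nominal
  sweep.
* Post-filtering between iterations vs once at the end: once at the end.
* `A_50bg` support restricted to the sphere VOI: the alternative
  (region-growing beyond it) is flagged for sensitivity analysis, not
  adopted.
* Replicates default to N = 3 (matching the physical study); the
  dispersion comparison in the tests uses N = 25 for statistical power.
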