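# rcpet — PSF-reconstruction artifacts in sub-centimeter PET lesions, in silico

Quantitative PET reads lesions through recovery coefficients,
RC = measured / true activity concentration. Resolution-modelled ("PSF")
iterative reconstruction sharpens images but, being a deconvolution, rings
at sharp boundaries. For hot lesions smaller than about twice the scanner
resolution this Gibbs-type edge overshoot corrupts quantification in a
characteristic way: RCs can exceed 1, they stop falling monotonically with
lesion size (peaking near 8 mm), they converge slowly with iterations, and
they become less reproducible — a pattern that can masquerade as disease
progression when a shrinking tumour's SUVmax *rises*.

`rcpet` is a self-contained simulation laboratory for this artifact class,
aimed at physicists and method developers who want to study or teach it
without scanner time:

* **Phantom** — a digital wall-less multi-sphere phantom: twelve ¹⁸F gel
  spheres (3–12 mm) strung through a ¹¹C background that starts at 1:1
  concentration; differential decay (T½ 109.77 vs 20.36 min) sweeps the
  true sphere-to-background ratio from 1:1 past 15:1 over eleven 10-min
  frames. A padded ¹⁸F reference region provides the measured truth
  (6-mL cube VOI); a 15-mL cube VOI measures the background.
* **Acquisition** — isotropic Gaussian system response (4.5 mm FWHM
  default), slice-wise parallel-beam projection (336 views), seeded
  Poisson counting at a clinical count magnitude; already-corrected
  (mean-preserving) data by design.
* **Reconstruction** — ordered-subset EM, `x <- x/s · Bᵀ(y / Bx)`, with
  `B = P∘G` when PSF modelling is on (image-space Gaussian kernel, matched
  4.5 mm by default; 21 subsets with PSF, 16 without) and a Gaussian
  post-filter applied after the final iteration.
* **Metrics** — per sphere, a VOI of the physical diameter yields
  `A_max`, the background-corrected 50% isocontour mean
  `A_50bg` (threshold `bg + 0.5(A_max − bg)`), and `A_avg`; RCs divide by
  the measured reference concentration.
* **Experiments** — contrast sweep, iteration × post-filter sweep, noise
  reproducibility, monotonicity diagnostics and the minimal
  artifact-suppressing post-filter, all returning tidy tibbles with
  `autoplot()` methods.

## Worked example

Reconstruct the frame whose true contrast is nearest 8:1 with and without
PSF modelling, sweep iterations and post-filters from the stored snapshots,
and ask the diagnostic questions:

```r
library(rcpet)
library(dplyr)

cfg <- experiment_config(
  phantom     = phantom_compact(),                      # one sphere per diameter
  acquisition = acquisition_config(noiseless = TRUE))   # expectation data

sweep <- run_iteration_sweep(cfg, iterations = 1:6,
                             postfilters = c(2, 3, 4, 6))

monotonicity_diagnostics(sweep) |>
  filter(iterations == 4, postfilter_fwhm == 2) |>
  select(recon, is_monotone, argmax_diameter, max_rc, n_above_1)
#> # A tibble: 2 x 5
#>   recon             is_monotone argmax_diameter max_rc n_above_1
#>   <chr>             <lgl>                 <dbl>  <dbl>     <int>
#> 1 nopsf_4it16ss_2mm TRUE                     12  0.705         0
#> 2 psf_4it21ss_2mm   FALSE                    10  1.11          3

find_minimal_restoring_filter(sweep, iterations = 4)
#> [1] 3
```

Read: without PSF the recovery falls monotonically with diameter and stays
below 1 (the familiar partial-volume pattern; 0.71 for the 12-mm sphere). With PSF and a narrow 2-mm filter the curve breaks — three
diameters overshoot RC > 1 with the maximum (1.11) at an interior size —
and a 3-mm post-filter is the smallest tested width that restores the
monotone ordering. `autoplot(sweep)` draws the RC-vs-iterations panels per
post-filter and variant.

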