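# octskin

Skin surface roughness and optical metrics from 3D optical coherence
tomography (OCT) volumes.

Skin texture — wrinkles — changes with age, UV exposure and treatment, and
quantifying it objectively matters in dermatology, skincare research and
product development. OCT images the skin as a stack of cross-sectional
B-scans and so carries a full 3D topography of the air–skin surface.
`octskin` turns such a volume into the two ISO-style surface texture
parameters

- **arithmetic mean roughness**  `Ra = (1 / (n_x n_y)) Σᵢ Σⱼ |z(xᵢ, yⱼ)|`,
- **depth of roughness**  `Rz = max(z) − min(z)`,

where the heights `z` are referenced to the mean surface of the evaluation
region, plus two depth-resolved optical parameters: the epidermal thickness
(interval between the first peak and the first valley of the surface-aligned
mean depth signal) and the dermal attenuation coefficient μ (from an OLS fit
of `ln(intensity)` vs depth, `I ∝ exp(−2 μ z)`).

The pipeline per volume:

1. **Segmentation** of each B-scan into skin vs background — a
   deterministic adaptive-threshold backend (`segment_classical()`), and a
   small trainable U-Net-style encoder–decoder (`train_neural()`,
   `predict_neural()`), scored with mean intersection-over-union
   (`miou()`);
2. **Boundary extraction** (`extract_boundary()`): topmost skin pixel per
   A-scan, in μm;
3. **Flattening** (`flatten()`): removal of the skin's natural curvature by
   second-order least-squares fitting, so roughness is measured about the
   ISO mean surface rather than the curved anatomy;
4. **Roughness** (`compute_ra()`, `compute_rz()`, `roughness_report()`) and
   **optical metrics** (`mean_depth_profile()`, `epidermal_thickness()`,
   `attenuation_coefficient()`).

A synthetic phantom generator (`phantom_spec()`, `render_volume()`,
`make_plate_phantom()`, `make_cohort()`) renders layered skin and
roughness-standard-plate volumes with speckle and *exact* ground truth, so
every stage is validated against analytic values. `cohort_analysis()`
computes Pearson age–metric correlations (|r| > 0.6 flagged as strong).

## Worked example

Render a roughness standard plate with certified Ra = 6.3 μm (triangular
grooves, global curvature, fully developed speckle), then measure it:

```r
library(octskin)

spec  <- phantom_spec(n_slices = 100, n_depth = 256, n_lateral = 512,
                      curvature_coeff = 2.4e-6, seed = 1)
plate <- make_plate_phantom(6.3, spec)
plate$truth$true_Ra
#> [1] 6.3

res <- run_pipeline(plate$volume)
res$roughness
#> <roughness_report> Ra = 6.210 um, Rz = 39.947 um (100 x 462 grid, backend classical)
```

The recovered Ra of 6.210 μm is within 1.5% of the plate's certified value
despite speckle at per-pixel SNR ≈ 1 and a ~100 μm curvature sag — inside
the few-percent error band expected of a validated roughness instrument.
(Rz is the literal global peak-to-valley and is outlier-sensitive by
construction; quantitative validation is on Ra.) A skin phantom exercises
the optical metrics:

```r
skin <- render_volume(phantom_spec(n_slices = 10, n_depth = 256,
                                   n_lateral = 256, epidermis_thickness = 100,
                                   attenuation_mu = 2, seed = 3))
out <- run_pipeline(skin$volume)
out$optics$epidermal_thickness_um   # 92   (true 100; two 4-um pixels off)
out$optics$attenuation_mu_mm        # 1.99 (true 2)
```

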