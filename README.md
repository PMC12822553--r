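# rimap

Refractive-index mapping below the diffraction limit, in R: combine
defocused single-molecule localization microscopy (SMLM/dSTORM) with atomic
force microscopy (AFM) height maps to measure the refractive index of thin
biological samples — demonstrated on single collagen fibrils — at
sub-diffraction lateral resolution.

## The idea

The shape of a defocused single-molecule image encodes both the emitter's
height `z` above the coverslip and the refractive index `n` of the material
underneath it — and the two are nearly degenerate: assuming too small an
index makes the molecule appear too low. For a surface-labeled object of
AFM-measured height `H_AFM`, that degeneracy becomes a measurement. The
molecules are refit under a grid of assumed indices; the apparent SMLM
crest height `H_SMLM(n)` grows linearly with the assumed index, and its
intersection with `H_AFM` is the sample's refractive index.

The attainable precision is governed by the Fisher information of the
imaging model for Poisson counts,

    FI = sum_xy (1 / I_xy) (dI_xy / dn)^2 ,     dn_SMLM = 1 / sqrt(FI),

combined in quadrature with the index error induced by the AFM height
uncertainty: `dn^2 = dn_SMLM^2 + dn_AFM^2`.

The package implements, as testable modules:

* a vectorial psf for freely rotating dipoles above a coverslip with an
  intermediate layer (Fresnel stack with supercritical angles, defocus,
  Zernike aberrations) — `compute_molecule_image()`;
* the precision budget — `fisher_information_n()`, `delta_n_smlm()`,
  `delta_n_afm()`, `total_delta_n()`, `required_photons()`,
  `crlb_sweep()`;
* Poisson maximum-likelihood localization — `prelocalize()`,
  `fit_molecule()`, `merge_blinks()`, `localize_stack()`;
* the fibril analysis pipeline — drift and reference-plane correction,
  spline axis and cross-section geometry, DBSCAN outlier filtering,
  sliding-window heights, the refractive-index intersection, swelling and
  dry-index inversion, along-axis index maps with variance decomposition,
  and resampling/Monte-Carlo error estimation — `analyze_fibril()` and
  friends;
* AFM map conditioning — `tilt_correct_lines()`, `afm_fibril_profile()`;
* a ground-truth synthetic generator (labeled half-cylinder phantoms,
  blinking stacks with fiducials and drift, AFM maps) —
  `generate_phantom()`, `render_smlm_stack()`, `render_afm_map()`,
  `run_synthetic_experiment()`.

Results are tibbles or small S3 objects with `tidy()`/`glance()` and
`autoplot()` methods.

## Worked example

The precision bound for a hydrated collagen fibril configuration
(N = 123,648 detected photons, SBR = 110, height 138 nm, index 1.437,
defocus 500 nm, NA 1.46, 670 nm emission):

```r
library(rimap)
sys <- optical_system()          # NA 1.46, 670 nm, 160 nm pixels, 500 nm defocus
dn <- delta_n_smlm(sys, layered_sample(1.437, 138),
                   emitter_state(axial_position = 138,
                                 signal_photons = 123648,
                                 background_per_pixel = 123648 / 110))
dn
#> [1] 0.003058501
```

so no unbiased estimator can determine the index better than about
±0.003 from this amount of signal — the scale of the experimentally
reported per-fibril precision. Reaching a target precision of 10^-2 for a
50 nm sample at SBR 100 with a 1 nm AFM error requires on the order of
10^5 photons:

```r
required_photons(1e-2, sys, layered_sample(1.43, 50), sbr = 100,
                 afm = afm_uncertainty(1))
#> [1] 108868
```

A complete synthetic experiment — render a blinking stack and AFM maps of
a labeled fibril phantom (true index 1.43), localize, correct, refit per
assumed index, and intersect with the AFM height:

```r
r <- run_synthetic_experiment(seed = 2, frames = 400)
r$ri
#> <ri_estimate> n = 1.4216 +/- 0.00749  (slope  206.7  nm per RI unit)
tidy(r$swelling)
#> # A tibble: 1 x 5
#>   A_dry  A_wet delta_A n_collagen n_dry
#>   <dbl>  <dbl>   <dbl>      <dbl> <dbl>
#> 1 5613. 15605.    1.78       1.42  1.58
```

The recovered index agrees with the injected 1.43 to 1.1 times its
reported uncertainty; the swelling `delta_A` matches the injected
`(100/60)^2 - 1 = 1.78` and inverts to a dry-collagen index near 1.6
through the area-weighted mixing model.

See the vignette (`vignettes/refractive-index-mapping.Rmd`) for the
models, conventions, parameter meanings, and limitations.

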