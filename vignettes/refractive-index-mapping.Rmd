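---
title: "Mapping the refractive index of thin samples from defocused SMLM and AFM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the refractive index of thin samples from defocused SMLM and AFM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rimap)
```

## The problem

The shape of a single-molecule point spread function (psf) depends not only
on the emitter's position but also on the refractive index of the material
between the emitter and the coverslip. For an emitter a known height above
the glass, the apparent axial position inferred from a defocused psf shifts
systematically with the refractive index assumed in the fitting model: an
assumed index below the true one makes the molecule appear closer to the
glass, and vice versa. On its own this coupling makes axial localization an
ill-conditioned problem — refractive index and height are nearly
interchangeable. Pairing SMLM with an independent height measurement (AFM)
turns the degeneracy into a measurement: the assumed index at which the
SMLM height of a surface-labeled object matches its AFM height *is* the
object's refractive index.

`rimap` implements this measurement for rod-like samples such as single
collagen fibrils: the vectorial image-formation model, the information-
theoretic precision limits, Poisson maximum-likelihood localization, the
fibril cross-section pipeline, and a ground-truth synthetic-data generator
that exercises every stage.

## Image formation

A freely rotating dye above the coverslip is modeled as the incoherent sum
of three orthogonal emission dipoles. Each plane-wave component of the
emission propagates down through a three-layer stack — imaging buffer
(index $n_a = 1.33$), the sample layer (index $n$, thickness $H$), and
glass ($n_g = 1.52$, matched immersion) — with Fresnel transmission for s
and p polarization. Supercritical angles (transverse wavenumbers beyond
$k_0 n_a$) are included through the analytic continuation of the ambient
propagation angle; this near-field coupling carries most of the axial
information at high NA. The layer is treated as laterally infinite: the
curved fibril is modeled locally by the planar layer whose thickness is the
local fibril height, which is exactly the model fitted to the data.

Conventions that two implementations must share to agree numerically:

* **Defocus** enters as the glass-side pupil phase
  $-k_0 n_g \cos\theta_g\, d$; positive $d$ displaces the nominal focal
  plane from the coverslip into the sample. The working point is
  $d \approx 500$ nm.
* **Apodization** is the aplanatic $\sqrt{\cos\theta_g}$ factor.
* **Aberrations** are Noll-indexed Zernike terms, coefficients in radians
  of pupil phase at the pupil edge (unnormalized polynomials,
  $R_n^m(1)=1$). Purely radial terms are handled by the fast radial code
  path; any azimuthal term switches to a Cartesian-pupil FFT path. The two
  paths agree to better than 2% of the peak and serve as mutual
  cross-checks in the test suite.
* **Photon normalization**: the background-free image integrates to the
  photon count $N$ over the computed field (an 18 µm square). The
  defocused supercritical psf has a physically long halo — a percent-level
  tail extends beyond 9 µm — so "all photons" is necessarily a statement
  about a finite field.

For radially symmetric pupils the image reduces to three radial integrals
(orders 0, 1, 2 Bessel transforms of the s/p pupil amplitudes), evaluated
by Gauss–Legendre quadrature over the collection cone and tabulated on a
uniform radial grid. Camera pixels are integrated by midpoint oversampling;
the default `oversampling = 6` makes a further doubling change pixel values
by less than 0.1%. The fitting pipeline uses coarser settings
(`oversampling = 2`) plus a z-tabulated profile cache — a deliberate
speed/accuracy trade documented here because it is the main knob a user
may want to revisit.

## Precision theory

For Poisson pixel counts the Fisher information about the layer index at
known $H$, $N$ and background is
$\mathrm{FI} = \sum_{xy} (1/I_{xy}) (\partial I_{xy}/\partial n)^2$, and
the attainable precision is $\Delta n_\mathrm{SMLM} = 1/\sqrt{\mathrm{FI}}$.
The derivative is a central finite difference (step $10^{-4}$ in $n$, with
a built-in half-step consistency check). Because the information is linear
in photon flux at fixed signal-to-background ratio, a single reference
evaluation scales to any photon budget as $1/\sqrt{N}$.

The AFM height error $\Delta z_\mathrm{AFM}$ propagates into the index by
construction: noise-free images computed at $H \pm \Delta z_\mathrm{AFM}$
are refit for the index at thickness $H$ (bounded scalar minimization over
$[1.30, 1.60]$, tolerance $10^{-6}$), and the two one-sided deviations are
averaged; they agree to a few percent. The two error sources are
independent, so variances add:
$\Delta n^2 = \Delta n_\mathrm{SMLM}^2 + \Delta n_\mathrm{AFM}^2$.
Unidentifiable cases ($H = 0$) and unattainable targets (below the AFM
floor) are reported as distinguished values (`0` with a flag, `Inf`, `NA`
with the floor attached), never exceptions, so parameter sweeps complete.

One protocol subtlety: with the focal plane fixed 500 nm above the
coverslip, an emitter at $H \approx 250{-}400$ nm approaches the focal
plane and the precision-vs-thickness curve turns back up. `crlb_sweep()`
therefore keeps the focal plane a constant 500 nm above the *sample top*
by default (`track_focus = TRUE`) — the protocol an experimenter would
follow across samples of different thickness — which makes
$\Delta n_s(H)$ strictly decreasing over 10–400 nm. Single-configuration
calculators always use the defocus exactly as given.

## Localization

Candidates are detected on a boxcar-smoothed frame (the raw defocused psf
is ring-shaped and yields spurious local maxima), thresholded absolutely
and relative to the frame median, with mutual rejection of candidates
closer than one ROI and a border guard. Each ROI is fit by maximizing the
Poisson log-likelihood over lateral position, height, photons and
background: the photon/background pair is profiled out by damped Newton
steps at fixed shape, and the geometry is optimized by Nelder–Mead (or a
1-D search when the lateral position is held, as in the per-index refits).
Fit quality is the log-likelihood ratio against the saturated model; on
15 × 15 px ROIs, well-modeled fits concentrate near the pixel count and
the conventional gate `llr < 600` passes over 98% of them in simulation.
Repeated blinks of one fluorophore are linked over dark gaps and
summarized by their per-axis standard error of the mean.

## The fibril pipeline

1. **Drift** is removed using fiducial beads: per-fiducial centered
   trajectories are averaged per frame, interpolated, anchored at the
   first frame, and subtracted.
2. **Reference plane and defocus**: glass-bound dyes adjacent to the
   fibril are refit while scanning the defocus (secant iteration) until
   their mean height is zero; the residual plane through their positions
   corrects the coverslip tilt. Reference fits allow negative heights —
   clamping at the coverslip would bias the mean upward and drag the
   fitted defocus with it. The standard error of the glass heights,
   $\sigma_\mathrm{ref}$, is retained: it shifts every SMLM height
   coherently and therefore enters the final error budget as a
   common-mode term rather than averaging out across the index grid.
3. **Axis and cross-section**: a planar cubic B-spline (order 4; degree
   configurable) is fit through the fibril's central axis and every
   localization is projected to arclength/lateral/height coordinates
   $(s, X, Z)$ by nearest-point projection onto a 10 nm presampling of
   the curve. The spline is fit through 250 nm binned medians by default,
   which keeps label clumps on the fibril flanks from steering the curve.
   With only a few hundred localizations the SMLM axis is still the
   dominant geometric error source; when a registered AFM map is
   available its ridge provides a far denser axis estimate, and
   `analyze_fibril()` accepts such a pre-fit axis.
4. **Outliers** are removed by DBSCAN in the $(X, Z)$ plane (defaults
   `eps = 30` nm, `min_samples = 10`; the main cluster is kept).
5. **Height**: localizations ordered by $X$ are binned into sliding
   windows of fixed count, the per-window median height is smoothed by a
   3-window moving average, and the crest height is the profile maximum
   plus the debris offset (median AFM height of coverslip debris, which
   offsets the SMLM reference plane).
6. **Index intersection**: the whole fibril is refit once per assumed
   index on the grid (default 1.38–1.48 in 0.02 steps), the crest height
   grows linearly with the assumed index, and the intersection of that
   line with the AFM height is the fibril's refractive index.
7. **Swelling**: cross-sectional areas from dry and wet AFM maps give
   $\Delta A = A_\mathrm{wet}/A_\mathrm{dry} - 1$, and the hydrated index
   inverts exactly through the area-weighted mixing model
   $n_\mathrm{collagen} = (n_\mathrm{dry} + \Delta A\, n_\mathrm{water}) /
   (1 + \Delta A)$.
8. **Mapping and variance decomposition**: sliding windows of fixed
   localization count along the arclength (default 100 localizations, 90%
   overlap) repeat the height-and-intersection estimate against the local
   AFM height. Along-axis variance splits into sample and experimental
   parts, $\sigma^2_{n,\mathrm{collagen}} = \sigma^2_n -
   \sigma^2_{n,\mathrm{exp}}$ (floored at zero), as a function of window
   size.

### Error estimation

Height errors come from half-sample resampling: half the localizations
are drawn without replacement, the height recomputed, 1000 times, and the
standard deviation divided by $\sqrt{2}$. This estimator is calibrated for
noise-dominated height errors; when the error is dominated by how sparsely
the curved crest is sampled, the half-sample scaling is only approximate
(we measure ~2% agreement with a brute-force Monte Carlo oracle in the
noise-dominated regime and tens of percent in a strongly geometry-
dominated one). Index errors come from 10,000 Gaussian draws of all
heights (plus the common-mode reference term) pushed through the line
intersection.

### Matched windows for the two modalities

The same sliding-window rule is applied to the AFM map, but "the same
window" is interpreted as the same *effective lateral extent*, not the
same point count: a 40-point window spans ~50 nm on a sparse localization
set and ~12 nm on a dense AFM grid, and the crest-median bias of the
estimator depends on that extent. Two corrections follow. First, the AFM
window count is scaled by the point-density ratio. Second, the SMLM
observed-X window additionally aggregates true positions blurred by the
lateral localization noise (a window of observed width W collects true
offsets with variance W^2/12 + sigma_lat^2, with sigma_lat from the
lateral Fisher information at the median photon count), so the AFM window
is widened to the same effective width, sqrt(W^2 + 12 sigma_lat^2).
Matching the effective kernels of the two estimators keeps the
intersection unbiased at the few-hundred-localization scale of the
synthetic studies; with the much larger localization counts of a full
experimental acquisition both corrections become negligible.
Cross-sectional *areas*, in contrast, are an AFM-only quantity and are
integrated with a fixed moderate window in both hydration states.

## The synthetic-data generator

`fibril_phantom()` / `generate_phantom()` place labels by a Poisson point
process on the upper surface of a half-cylinder (the fibril; uniform per
unit area) and sparsely on the surrounding glass (defaults 400 and
1.5 µm⁻²). Blinking is a two-state Markov chain with geometric on-times;
photons per frame are log-normal around 10³–3·10³, the dSTORM regime.
Frames include two bright fiducial beads, linear-plus-random-walk drift,
uniform Poisson background, and Poisson shot noise; AFM maps sample the
same surface at 39 nm pixels with Gaussian height noise and per-line
tilts. Rendering uses the same planar-layer psf as fitting — a deliberate
idealization so that recovery tests isolate pipeline correctness from
model misspecification. What the generator does *not* emulate: antibody
linker geometry (exposed only as a scalar normal offset, default 0),
cylindrical-lens refraction by the curved fibril, EM-gain excess noise
(counts are plain Poisson), photobleaching, and sample motion other than
rigid drift. Passing the end-to-end tests therefore demonstrates that the
analysis chain is correct and well-calibrated under its own forward model,
not that the optical model captures every property of real fibrils.

The packaged study `run_synthetic_experiment()` uses a 5 µm straight
fibril of hydrated radius 100 nm (dry 60 nm, so the injected area swelling
is $\Delta A = (100/60)^2 - 1 \approx 1.78$, within the reported range for
rehydrated fibrils), true index 1.43, 400–450 frames of 64 × 64 px at
160 nm pixels, ~3·10³ photons per burst, background 10 — a few hundred
localizations per fibril. These sizes were chosen so a full 20-seed
recovery study runs in minutes on one CPU; they are an order of magnitude
below a real 80,000-frame acquisition, which is why the per-fibril
uncertainty here (~6·10⁻³) is about twice the published experimental
precision.

## Numerical choices and degenerate inputs

* Pupil quadrature: 512 Gauss–Legendre nodes; radial grid to 9 µm in
  7.5 nm steps; linear interpolation on the uniform grid in the fit hot
  path.
* Finite differences: $10^{-4}$ in $n$ (half-step check), 2 nm in $z$.
* Refit z-tables: 4 nm z-grid, linear interpolation; fits clamp to the
  table range and report the clamped value.
* Ties in nearest-point projection resolve toward smaller arclength;
  points beyond the axis ends are clamped and flagged.
* $H = 0$ makes the index unidentifiable (flagged zero information);
  all-noise DBSCAN input, degenerate axis clouds, non-monotone area
  grids, and negative counts are errors with actionable messages.
* All stochastic steps take explicit seeds; resampling defaults (1000
  half-samples, 10,000 draws) are configuration, not code.

## Known limitations

* The planar-layer approximation ignores refraction by the curved fibril
  surface; both the real experiment and this implementation share it.
* AFM tip convolution is not deconvolved; heights are used as the
  instrument reports them.
* EM-gain excess noise is ignored (Poisson statistics assumed).
* The half-sample height-error estimator underestimates in
  geometry-dominated sampling regimes (see above).
* SMLM/AFM registration is assumed exact; the pipeline consumes
  pre-registered inputs.
* Multi-emitter ROIs are rejected, not fit; overlapping fibrils are out
  of scope.
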