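---
title: "Morphometry and rotational symmetry of pore-like membrane complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and rotational symmetry of pore-like membrane complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreSym)
```

# The measurement problem

Internal membranes of the planctomycete *Gemmata obscuriglobus* carry
pore-like complexes whose en-face appearance in negatively stained and
frozen-hydrated electron micrographs is a central electron-dense plug
(about 9.5 nm), a thin brighter inner ring (about 17.5 nm) and a thicker
dark outer ring (about 33.5 nm) built from discrete subunits with 8-fold
rotational symmetry, at areal densities of roughly 87 per square micron on
sheets from lysed cells and roughly 200 per square micron on a purified
pore-bearing membrane fraction. Two smaller ring classes (about 14.5 nm
with a 5 nm dense centre, and about 6 nm) co-occur. poreSym implements the
numerical procedures needed to characterize such structures — ring
morphometry, density estimation, Markham rotational reinforcement, and
immunogold distance association — together with a synthetic-micrograph
generator that provides ground truth at exactly these published values, so
each procedure's recovery error is measurable.

# The synthetic pore and sheet model

A pore class is parameterized by `PoreModel`. The rendered, noise-free
intensity at polar offset $(r, \theta)$ from the pore centre is

$$ I(r,\theta) = b
   + c_p \cdot \tfrac12\,\mathrm{erfc}\!\left(\frac{r - d_p/2}{\sqrt2\,w_p}\right)
   + c_i \exp\!\left(-\frac{(r - d_i/2)^2}{2 w_i^2}\right)
   + c_o \left[1 + A\cos n(\theta-\theta_0)\right]
         \exp\!\left(-\frac{(r - d_o/2)^2}{2 w_o^2}\right), $$

followed by a Gaussian PSF blur and i.i.d. Gaussian noise. Conventions that
matter:

* **Contrast polarity.** Intensity is brightness; electron-dense material is
  dark. Default signs follow the negative-stain appearance: plug dark
  ($c_p = -0.5$), inner ring bright ($c_i = +0.3$), outer ring dark
  ($c_o = -0.4$), on a membrane background of 0.5 against an exterior of
  0.35 (arbitrary units).
* **Diameter convention.** Ring diameters refer to the annulus ridge
  (intensity extremum) line; the plug diameter is the full width at half
  contrast of the central disk. The erfc edge places the half-contrast point
  exactly at $d_p/2$ before blurring, so generator and estimator share one
  convention and recovery is well defined. The published tracing rule is
  ambiguous on this point; a shared ridge convention is the choice made
  here.
* **Subunits.** The outer ring is modulated by $A\cos n\theta$ with default
  $n = 8$ and modulation depth $A = 0.3$ — strong enough that the 8
  subunits are visible by eye at SNR 3, weak enough that the ring remains a
  continuous annulus, matching the published appearance.
* **Tilt.** Membrane tilt is rendered as in-plane affine compression by
  $\cos(\text{tilt})$ along a tilt axis — pure foreshortening, no 3D
  projection. The published analysis treated tilt as ellipticity below 10
  degrees, where this approximation is appropriate.
* **PSF and noise.** A single Gaussian PSF ($\sigma$ = 1.0 nm by default)
  stands in for the microscope envelope; no contrast transfer function is
  simulated, because morphometry and symmetry operate at scales (4–35 nm)
  where a Gaussian envelope suffices at the magnifications involved. The
  signal-to-noise convention throughout is
  $\mathrm{SNR} = |c_o|/\sigma_{\text{noise}}$.
* **Ring widths.** Gaussian radial sigmas of 2.2 nm (outer), 1.4 nm (inner)
  and a 1.2 nm plug edge width reproduce the relative thicknesses visible
  in the published panels (thin inner, thick outer ring) while keeping the
  three features separable at 0.69 nm/pixel.

Sheets (`renderSheet`) place `round(density x area)` pore centres by
sequential hard-core rejection sampling with `max_attempts = 100 x` the
target count — simple and adequate below packing fraction 0.55, which the
scene validity check enforces. Centres keep an edge margin (default: one
outer radius) inside the membrane region so rendered rings are complete;
this is a realism choice, and densities are unaffected because the target
count is fixed before placement. Each pore receives a uniformly random
azimuthal phase. The basket depth of the 3D pore model (about 25 nm) is
stored as metadata only and never rendered: the analysis is strictly 2D en
face.

The medium (14.5 nm) class is modelled as a single ring with a 5 nm dense
centre and no inner ring (inner contrast 0; a placeholder inner diameter
keeps the ordering invariant). Whether this class is a distinct pore type
or a reverse ("basket-side") view of large pores is an open biological
question; the generator treats classes as independent and does not model
reverse views. The small 6 nm class gets a 2.5 nm centre — its published
description fixes only the overall width.

## What the generator does not emulate

Stain granularity and correlated background texture, membrane curvature and
folds, partially assembled or overlapping pores, CTF oscillations,
freeze-fracture shadowing, and 3D basket side views. Tests passing on this
generator therefore certify the *algorithms* (recovery under the stated
geometry, noise and tilt), not performance on every real-image pathology.

# Morphometry

`refineCenter` locates the symmetry centre as the shift maximizing the
correlation between the patch and its 180-degree rotation (FFT
cross-correlation; the peak displacement equals twice the centre offset),
with 3-point parabolic sub-pixel refinement and the search limited to a
quarter of the patch radius. A flat patch is an error.

`radialProfile` bins mean intensity in concentric annuli (default bin: one
pixel, 0.69 nm); empty bins are an error rather than silently interpolated.
`measureRings` then takes the baseline as the median of the outermost 15%
of bins, requires each feature to clear a prominence threshold of
`max(3 x sigma_bin, 2% of the profile range)` (with `sigma_bin` estimated
robustly from first differences), and reports:

* plug: twice the first half-contrast crossing radius;
* inner/outer rings: twice the parabola-refined radius of the strongest
  local extremum of the stated polarity, searched outward in order.

Missing features are flagged (`plug_missing`, `inner_missing`,
`outer_missing`), never guessed — the medium-class model, which has no
inner ring, is the standing test of this contract. Uncertainties combine
half a bin width with the parabola vertex standard error in quadrature.
Published diameter tolerances are reported as mean ± s.d. in pipeline
summaries; whether the original ± values were s.d. or range is not stated
in the source material, and s.d. is the assumption documented here.

Tilted pores: when the fitted axis ratio falls below 0.97, `measurePore`
applies `deellipse` before measuring. For near-circular rings the tilt
angle is ill-conditioned ($d\,\mathrm{acos}/d\,\mathrm{ratio} \to \infty$
as ratio $\to 1$), so `estimateTilt` smooths the patch (sigma 1 px) before
taking the contrast-weighted second moments of the ridge band; estimates
above 10 degrees carry a `highTilt` flag, since larger tilts were outside
the analysed regime.

# Rotational symmetry

`markhamSuperposition` implements the classical rotate-and-superimpose
operation: the patch is rotated by $k \cdot 360/n$ degrees ($k = 0..n-1$,
bilinear interpolation about the refined centre) and averaged, so true
n-fold features reinforce while noise averages out. Increments are stored
exactly as $360/n$ and display as 45.0 degrees for 8-fold and 51.4 degrees
for 7-fold. Superposition and scoring run on raw patches only; input whose
provenance records a bandpass filter triggers a warning, mirroring the
methodological rule that reinforcement must not be computed on filtered
structures.

The cited Friedman modification of Markham rotation is not specified in the
source; the quantitative statistic here is this package's own
operationalization, with every ingredient documented:

1. **Azimuthal component.** Correlations are computed on the patch minus
   its rotational (radial-bin) average, within a radial band from half the
   plug radius to 1.1 x the outer-ring radius. The axisymmetric component
   is identical under every rotation and carries no information about $n$;
   removing it is what makes the correlation a symmetry statistic. (The
   band bounds are radii; measured plug and outer radii supply them by
   default.)
2. **Smoothing and dither.** The residual is smoothed (sigma 1 px) and the
   reference copy rotated by a fixed dither angle (14.142 degrees) before
   comparison. Both exist because the pixel grid is special: rotations by
   multiples of 90 degrees compose exactly on the grid while other angles
   pass through bilinear interpolation, and the grid-locked pixelization
   residue of a circular ring is itself perfectly 4-fold symmetric. The
   dither gives reference and candidate exactly one resampling each; the
   smoothing suppresses the grid-locked residue.
3. **Score.** `score(n)` is the mean Pearson correlation over the $n-1$
   commensurate rotations. The control is the same single-rotation
   correlation at $m = 99$ random angles, excluding 1.5-degree
   neighbourhoods of all commensurate angles; it is summarized by its mean
   (the no-symmetry baseline) and the standard error of that mean.
4. **Selection.** The selected order is the largest $n$ whose score is
   within $\varepsilon$ of the maximum score and exceeds the control mean
   by at least three times `max(control s.e., parametric null s.e.)` and by
   an absolute margin of 0.05. The parametric null s.e. is the Fisher
   correlation floor $1/\sqrt{n_\mathrm{eff}-3}$ (band pixels per
   smoothing-correlation area), divided by $\sqrt{n-1}$; it prevents a
   pure-noise patch, whose control s.e. is tiny, from clearing the bar by
   chance. The absolute margin rejects trivially small but statistically
   significant self-similarity. A patch whose azimuthal component carries
   less than 1% of the band variance is treated as circularly symmetric and
   yields "none" — this guard, not the correlation test, is what handles
   the noiseless circular pore, whose only azimuthal structure is the
   4-fold pixelization residue.

**Why the largest-n tie-break and this $\varepsilon$.** A perfect 8-fold
image reinforces equally at $n = 2, 4, 8$ (every divisor maps subunits onto
subunits), so divisor scores tie at the maximum and the largest tied order
is the answer. $\varepsilon$ must cover the spread of that tie. Measured at
the package's default study condition (SNR 3, 50 seeds), the divisor gap
`max(score(2), score(4)) - score(8)` has mean 0.006, s.d. 0.034 and maximum
0.095 — the residue of the grid-exactness asymmetry plus the sampling noise
of `score(2)`, which is a single correlation — while non-divisor larger
orders score at least 0.39 below the maximum. $\varepsilon = 0.12$ covers
the tie spread with headroom and cannot admit a wrong larger order, whose
scores are nowhere near the tie set.

`angularPowerSpectrum` provides the independent cross-check: the azimuthal
residual resampled on 360 angle bins, Fourier power at integer harmonics,
dominant harmonic reported next to the Markham selection. It also reports
the fraction of band variance carried by the angular profile; below about
1% the dominant harmonic only reflects pixelization and is not meaningful.

# Detection and density

Detection is matched filtering: normalized cross-correlation of the locally
standardized image against zero-mean Gaussian annulus templates over a
radius grid (default 12–22 nm in 2 nm steps, template width equal to the
generator's outer-ring sigma — the outer ring being the most consistent
feature across preparation methods), followed by 3x3 local-maximum
selection above a score threshold of 0.3 within the membrane mask and
greedy non-maximum suppression (higher score wins; exact ties broken by
lower row then column). Local standardization makes detection exactly
invariant to affine intensity changes. Detections nearer the mask boundary
than their ridge radius are flagged `edge` but retained; the density
estimator uses all detections, since no published edge rule exists.
Membrane masks come from Otsu thresholding after Gaussian pre-smoothing
(sigma 3 px — without it, exterior pixel noise percolates through the
morphological closing), closing, hole filling (pores are enclosed spots)
and largest-component selection. Density is count over mask area with a
Poisson 95% interval.

# Immunogold association

The association rule is a distance threshold: a particle is associated when
its distance to the nearest pore does not exceed 20 nm, inclusive. Distance
is measured to the outer-ring *edge* (`max(0, |particle - centre| - outer
radius)`) by default, which keeps the rule size-independent across pore
classes; centre distance is available via `mode = "center"`, since the
original measurement convention is unstated. Membrane-trace references
(mask or polyline) are supported for whole-cell counts. The published counts
(397 associated / 45 not on purified membranes; 549 / 60 in cells) cannot be
recomputed without the original micrographs and enter the test suite only
as arithmetic (fraction 397/442 = 0.898) and boundary-semantics checks.

`permutationEnrichment` adds a formal null the source lacks: B seeded
uniform placements in the membrane region,
$p = (1 + \#\{\hat f_b \ge \hat f_{\text{obs}}\})/(B+1)$, minimum
attainable $1/(B+1)$. The p-values are discrete (fractions of $n$
particles on a grid of $B+1$ values) and include the $+1$ correction, so
under the null they are valid but mildly conservative rather than exactly
uniform; the test suite asserts exactly that.

# Numerical choices and degenerate inputs

* 16-bit TIFF output quantizes intensities (scale stored in a JSON
  sidecar); MRC mode 2 stores float32 and is the lossless interchange
  format. Reading never rescales silently, and a missing pixel size is an
  error, not a default.
* `extractPatch` sides are `2 ceil(r/ps) + 1` (always odd); windows
  crossing the border are errors — no padding is invented.
* The display bandpass is a Fourier difference of Gaussians whose transfer
  crosses half amplitude exactly at the cutoff feature sizes (defaults 40
  and 3 px); the mean is restored after filtering. It only approximates
  other implementations of the same cutoffs, which do not document their
  kernels.
* Degenerate inputs error early with explanatory messages: flat patches
  (centre refinement), uniform images (masking), empty radius grids,
  inverted band cutoffs, infeasible packings (with achieved vs requested
  counts), empty radial bins.
* All randomness flows through explicit seeds; scenes, pipelines and
  reports are bit-reproducible (the run log holds the timestamps so
  `report.json` can stay deterministic).

# Problem sizes

The shipped tests and the acceptance script use patch sizes of 73–77 px
(26 nm radius at 0.69 nm/px), 50 pores per morphometry experiment,
100 seeds for the symmetry-concordance property, sheets of 1.2–2 um at the
two published densities, and permutation tests at B = 199–999. These sizes
were chosen so each experiment's Monte-Carlo error is comfortably inside
the tolerance it is compared against.

# Known limitations

The tilt model is first-order foreshortening; beyond ~10 degrees (flagged)
the correction degrades. The tilt estimator is ill-conditioned near
circularity, so small spurious tilts are corrected on noisy pores — the
corresponding stretch is bounded by the 0.97 axis-ratio trigger and biases
small-ring diameters upward slightly (well inside published tolerances).
The detector assumes dark outer rings of roughly known width; strongly
defocused or phase-reversed imaging conditions would need a different
template polarity. The permutation null is uniform placement within the
membrane; clustered antibody deposition would require a different null
model and is out of scope, as are Ripley-type clustering statistics and 3D
section-thickness corrections.
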