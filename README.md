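# poreSym

Quantitative 2D image analysis of nuclear-pore-like complexes on membrane
sheets imaged by transmission electron microscopy, built around the membrane
pores of the planctomycete *Gemmata obscuriglobus*. These pores show the
structural vocabulary of the eukaryotic nuclear pore complex — an outer ring
(~33.5 nm), an inner ring (~17.5 nm), a central electron-dense plug
(~9.5 nm) and 8-fold rotational symmetry — at roughly a third of its size.
Characterizing them from micrographs requires a small set of reusable
numerical procedures, which this package implements as a tested pipeline:

- **Synthetic micrograph generation** (`renderPorePatch`, `renderSheet`,
  `placeGold`): parametric ring/plug pore models rendered on membrane sheets
  with hard-core (minimum-separation) pore placement, tilt foreshortening,
  Gaussian PSF and noise — with complete ground truth, so every downstream
  stage is verifiable without access to original micrographs.
- **Image I/O** (`readMicrograph`, `writeMicrograph`, `extractPatch`,
  `bandpassFilter`): 16-bit TIFF and MRC mode-2 images with physical pixel
  sizes in nm; the bandpass filter is for display only.
- **Pore detection and density** (`makeMembraneMask`, `detectPores`,
  `estimateDensity`): normalized cross-correlation against zero-mean annulus
  templates over a radius grid, non-maximum suppression, and areal density
  in pores/um^2 with a Poisson interval.
- **Ring morphometry** (`refineCenter`, `radialProfile`, `measureRings`,
  `measurePore`): sub-pixel centre refinement by 180-degree self-correlation,
  radial intensity profiles, and plug / inner-ring / outer-ring diameters
  with uncertainties and missing-feature flags.
- **Rotational symmetry** (`estimateTilt`, `deellipse`,
  `markhamSuperposition`, `reinforcementScore`, `angularPowerSpectrum`,
  `assessSymmetry`): the Markham rotational-reinforcement analysis — the
  image rotated in silico by increments of 360/n (45.0 degrees for 8-fold,
  51.4 for 7-fold) and superimposed — quantified as the mean rotational
  self-correlation of the azimuthal image component against a seeded
  random-rotation control, with ellipticity (tilt) correction and an
  independent angular-power-spectrum cross-check. Symmetry scoring runs on
  raw images only, never on bandpass-filtered ones.
- **Immunogold association** (`classifyAssociation`,
  `permutationEnrichment`): particles count as structure-associated when
  their distance to the nearest pore's outer-ring edge does not exceed a
  threshold (20 nm by default, inclusive), with a permutation test against
  uniform placement in the membrane.
- **Pipeline** (`runConfig`, `runPipeline`): orchestrates
  generate → detect → measure → symmetry → gold with presets, derived seeds
  and a deterministic `report.json`. A thin command-line wrapper lives at
  `inst/scripts/pore-pipeline.R`.

## Worked example

Render one noisy pore with the default large-pore model (outer/inner/plug
diameters 33.5/17.5/9.5 nm, 8 subunits, 0.69 nm/pixel, SNR 5), measure its
rings, and scan its rotational symmetry:

```r
library(poreSym)

mdl <- PoreModel()                      # the large pore class
p <- renderPorePatch(mdl, patchRadius = 26, noiseSigma = 0.08, seed = 7)
measurePore(p)$measurement
#> RingMeasurement:
#>   plug  : 9.55 +/- 0.98 nm
#>   inner : 17.96 +/- 1.65 nm
#>   outer : 33.82 +/- 1.13 nm

assessSymmetry(p, seed = 1)
#> SymmetryScan:
#>   n =  2 (180.0 deg): score +0.7279
#>   ...
#>   n =  7 ( 51.4 deg): score -0.1375
#>   n =  8 ( 45.0 deg): score +0.7413
#>   ...
#>   control: 0.0931 +/- 0.5368 (se 0.0539, m = 99)
#>   selected order: 8 | spectrum harmonic: 8
```

The measured diameters recover the generator's ground truth within the
stated uncertainties, and the symmetry scan selects order 8: the
reinforcement score at 45.0-degree rotations (0.74) exceeds both the 7-fold
score at 51.4 degrees (-0.14) and the random-rotation control; the scores at
n = 2 and n = 4 tie with n = 8 because divisors of the true order also map
subunits onto subunits, and the largest tied order is selected. The angular
power spectrum independently reports harmonic 8.

Sheet-level analysis runs the same way through the pipeline:

```r
cfg <- runConfig("sheet-lysed-87", seed = 1)   # 87 pores/um^2 preset
report <- runPipeline(cfg, "out/")
report$detect$density$density                  # recovered pores per um^2
```

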