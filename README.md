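# fiberAlign

Quantifying the direction and extent of structural protein alignment in
engineered tissue constructs, from three complementary measurements:

* **Polarized Raman spectroscopy (PRS)** — label-free and hydration
  compatible.  Band intensities (above all the amide I C=O stretch near
  1665 cm⁻¹) depend on the angle between the laser polarization and the
  protein fiber axis.  Spectra are preprocessed (iterative 11th-order
  polynomial baseline removal, Savitzky–Golay 3/11 smoothing, SNV
  normalization, 1400–1800 cm⁻¹ cropping), projected onto a *master PC1
  loading* derived from highly aligned reference tissue, and the score is
  fit across polarization angles φ to

      PC1 = PC1₀ + A·sin(π(φ − φc)/90°)

  The amplitude *A* measures the extent of alignment; the alignment angle
  is β_PRS = (φc + 45°) mod 180°.
* **Immunofluorescence fiber images** — CT-FIRE-style per-fiber angle
  tables are summarized by the orientation-tensor mean fiber axis, the
  alignment index **S = 2⟨cos²θ⟩ − 1** (θ measured from the mean axis;
  0 = isotropic, 1 = perfectly aligned) and axial circular statistics.
* **A continuum contraction model** — a plane-stress, compressible
  neo-Hookean finite-element model of the cell-laden central strip of the
  dog-bone construct (E = 700 Pa, ν = 0.4),

      ψ = E/(4(1+ν))·(Ī₁ − 3) + E/(6(1−2ν))·(J_el − 1)²,

  loaded by a stress-free shrinkage strain εs through the multiplicative
  split F = F_e·F_s, F_s = (1 − εs)·I.  εs is fitted to the measured area
  shrinkage; the local deformation gradient then yields an ellipse-based
  alignment factor α = b/a, a model alignment angle β_model, and — via 150
  embedded fibers per 100 µm element — an *equivalent* S that bridges the
  continuum and discrete measures (closed form S = (α−1)/(α+1) under pure
  stretch).

The cross-modality comparison normalizes each branch by its in-sample
maximum (γ = A/A_max, α/α_max, S/S_max) and compares angles on the axial
circle.  Seeded synthetic generators emulate the statistical structure of
the raw spectra and fiber tables, so the entire pipeline is testable
without instrument data.

## Worked example

Fiber-image branch, using the shipped synthetic example table (150 fibers
emulating a corner-edge ROI with mean 129.1° and SD 25°):

```r
library(fiberAlign)
f <- readFiberTable(system.file("extdata", "synthetic_fibers_CE.csv",
                                package = "fiberAlign"))
f
#> FiberSet: 150 fibers in a 100 um ROI
#>   S = 0.686, mean axis = 128.8 deg (axial SD 24.9 deg)
```

S ≈ 0.69 matches the wrapped-normal closed form e^(−2σ²) = 0.683 at
σ = 25°, and the recovered axis is within 0.3° of the generating mean.

PRS branch, end to end on synthetic acquisitions (a 110-spectrum reference
scan, then a 2 ROI × 11 point × 12 replicate session at one location with
modulation phase φc = 75°):

```r
cfg <- preprocessConfig()
ref <- genReferenceSet(spectrumModel(noiseSd = 1, phaseDeg = 90),
                       n = 110, seed = 1)
ld  <- deriveLoading(preprocessSpectra(ref, cfg))
ld
#> LoadingFunction on 401 wavenumbers [1400.0, 1800.0] cm-1; PC1 98.2% var

set <- genAcquisitionSet(spectrumModel(noiseSd = 1, phaseDeg = 75),
                         location = "CE", seed = 2)
sc  <- projectPC1(preprocessSpectra(set, cfg), ld)
summarizeAlignment(sc)
#>   location n_points A_mean  A_sd ci_lo ci_hi phase_deg beta_prs_deg gamma
#> 1       CE       22   6.55 0.051  6.53  6.57      74.9          120     1
```

The 22 per-point sine fits recover the generating phase (74.9° vs 75°) and
the alignment angle β_PRS = 120°.

Contraction model at the production resolution (100 µm elements; the
strain sweep takes about a minute on one core):

```r
mesh <- buildMesh(tissueGeometry())          # 4 x 10 mm, 100 um elements
fit  <- fitShrinkageStrain(0.60, mesh, tissueMaterial(),
                           grid = seq(0, 0.7, by = 0.05))
fit$epsS
#> [1] 0.6
alignmentMap(mesh, fit$field)$regions
#>   location    x    y alpha beta_model_deg S_equiv gamma_model
#> 1       CE 3.95 0.15 7.759         145.51  0.7717      1.0000
#> 2       ME 3.95 5.05 3.501          89.99  0.5556      0.4512
#> 3       MC 2.05 5.05 3.505          90.00  0.5561      0.4518
```

A shrinkage strain of 0.6 matches the 60 % measured area shrinkage; the
corner-edge element is strongly aligned (α ≈ 7.8, β ≈ 145°, equivalent
S ≈ 0.77) while the mid-span elements align with the inter-anchor axis
(α ≈ 3.5, β = 90°, S ≈ 0.56).  `runPipeline()` drives all three branches
from a YAML configuration and writes the comparison tables
(`comparison_gamma.csv`, `comparison_angles.csv`, `comparison_S.csv`) plus
a VTK displacement field.

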