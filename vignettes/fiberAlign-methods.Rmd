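---
title: "Measuring protein fiber alignment in engineered tissue constructs: methods and design notes"
author: "fiberAlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fiberAlign methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberAlign)
```

## The measurement problem

Cell-laden collagen gels cast in a dog-bone mold contract over days of
culture: myoblasts pull on the matrix, the free central strip necks between
the two anchored wings, and the collagen fibers reorganize.  Three very
different instruments can report on the resulting alignment:

* **Polarized Raman spectroscopy (PRS)** measures how band intensities —
  above all the amide I C=O stretch near 1665 cm⁻¹ — vary with the angle
  between the laser polarization and the fiber axis.  It is label-free,
  works on hydrated samples, and averages through the sample depth.
* **Immunofluorescence imaging** plus curvelet-based fiber extraction
  yields discrete per-fiber angles in a 100 µm × 100 µm ROI.
* **A continuum contraction model** predicts the local deformation
  everywhere in the construct from a single fitted load parameter.

`fiberAlign` implements all three branches and the conversions that make
their outputs comparable.

## PRS branch

### Preprocessing

Raw polarization-resolved spectra pass through a fixed chain:

1. **Baseline removal** — iterative modified polynomial fitting of order 11
   (I-ModPoly style: the working spectrum is clipped at one residual
   standard deviation above the current baseline before each refit).  The
   iteration is deterministic, exact on polynomial backgrounds up to the
   configured order, and recovers an isolated Gaussian band (σ = 8 cm⁻¹)
   to well within 5 % of its height.  Tolerance 10⁻⁶ of the intensity
   range, at most 300 iterations.
2. **Savitzky–Golay smoothing** — third-order polynomial, 11-point frame
   (`signal::sgolayfilt`), which passes cubics through unchanged.
3. **SNV normalization** — each spectrum scaled to mean 0, sample
   (n − 1) SD 1, removing per-shot intensity drift.
4. **Cropping** to the 1400–1800 cm⁻¹ analysis window.  Wavenumbers below
   1300 cm⁻¹ are dominated by substrate background and are never analyzed.

The order is enforced: cropping comes last so smoothing edge transients
fall outside the analysis window, and SNV precedes replicate averaging so
that averaging acts on normalized spectra (a per-shot drift should not
weight the mean).  Whether SNV acts before or after averaging is not
uniquely determined by practice; both are supported
(`preprocessConfig(averageReplicates = )`), with SNV-then-average the
default for the drift-robustness reason above.

### Scoring and the sinusoidal fit

A *master loading function* is derived once from a highly aligned
reference tissue set (`deriveLoading`): the first principal component of
the mean-centered reference spectra, sign-fixed so the coefficient nearest
1665 cm⁻¹ is non-negative.  Test spectra are **never** re-decomposed; they
are projected through the fixed affine map

\[ \mathrm{PC1}(s) = \langle s - \bar{s}_\mathrm{ref},\, w \rangle , \]

which is the only reproducible reading of scoring new samples against a
reference loading, and makes scores linear in the spectrum.

Across polarization angles φ the score of an aligned region oscillates
with period 180°:

\[ \mathrm{PC1}(\varphi) = \mathrm{PC1}_0 + A \sin\!\big(\pi(\varphi - \varphi_c)/90^\circ\big). \]

Although this model is nonlinear in φ_c, it is exactly linear in
\((\mathrm{PC1}_0, a, b)\) with \(a = A\cos(\pi\varphi_c/90)\),
\(b = -A\sin(\pi\varphi_c/90)\), so `fitSine` solves the global least
squares problem in closed form from the period-180° Fourier component —
no iteration, no multi-start, no convergence failures.  The branch
ambiguity \((A, \varphi_c) \sim (-A, \varphi_c + 90^\circ)\) is resolved by
the constraint \(A \ge 0\) with \(\varphi_c \in [0, 180^\circ)\).  The
amplitude *A* is the extent-of-alignment metric; the alignment angle is
\(\beta_\mathrm{PRS} = (\varphi_c + 45^\circ) \bmod 180^\circ\), the
polarization angle of maximum score.  When \(A < 2\,\mathrm{RMSE}\) the
fit is flagged `aligned = FALSE`: the phase of a vanishing sinusoid is
unidentifiable and `alignmentAngle` refuses to report it.

Per-location summaries fit one sinusoid per measurement point (the default,
matching how 22 points per location are individually fitted and then
summarized) and report mean, SD and the Student-t interval
\( \bar A \pm t_{0.975,\,n-1}\,\mathrm{SD}/\sqrt{n} \); a pooled mode fits
all points jointly.  The alignment aspect ratio \(\gamma = A / A_{\max}\)
normalizes by the in-sample maximum so PRS can be compared with the other
modalities.

## Discrete-fiber branch

Fiber angles live on the *axial* circle — θ and θ + 180° are the same
fiber — so every statistic doubles the angles first.  The mean fiber axis
is the principal axis of the orientation tensor ⟨u uᵀ⟩, equivalently the
axis maximizing ⟨cos 2θ⟩ (the "fitted ellipse" major axis).  The alignment
index

\[ S = 2\langle \cos^2\theta \rangle - 1 = \langle \cos 2\theta \rangle \]

is measured about that axis; with the maximizing axis it equals the
resultant length of the doubled angles, hence \(S \in [0, 1]\) with 0 for
isotropy and 1 for perfect alignment.  Fibers are *counted*, not
length-weighted (a length-weighted mode exists but is off by default).
The angular SD is the axial circular SD (double, circular SD, halve),
which is the only convention stable across the 0°/180° wrap; the
arithmetic SD about the axis is also reported for comparison.

For the wrapped normal with angular SD σ the closed form
\(E[\cos 2\theta] = e^{-2\sigma^2}\) (σ in radians) makes the synthetic
generator an analytic oracle: σ = 25° gives S ≈ 0.683.  This is why the
generator draws wrapped-normal rather than von Mises angles.

## Continuum contraction branch

### Geometry and boundary conditions

The cell-laden central strip is 4 mm wide and spans the 10 mm gap between
the two functionalized PDMS wings (the wings anchor the gel; the reported
wing spacing fixes the span).  Only the central region is meshed: the two
short 4-mm interfaces are fully fixed, the long lateral edges are free, so
the strip necks into the familiar hourglass.  The inter-anchor axis is at
90° in the angle convention used everywhere in the package.  We verified
the alternative reading — clamping the two *long* edges across a 4 mm
span — and it cannot produce the observed deformation: shear lag between
two close clamped edges locks the interior, capping area shrinkage near
20 % no matter the load, with an almost isotropic center.  With the
adopted orientation the model reproduces the measured ~60 % area shrinkage
at a shrinkage strain of 0.6.

### Constitutive model and load

The gel is compressible neo-Hookean,

\[ \psi = \frac{E}{4(1+\nu)}(\bar I_1 - 3) + \frac{E}{6(1-2\nu)}(J_{el}-1)^2, \]

with E = 700 Pa and ν = 0.4 (measured values for collagen gels), \(\bar
I_1\) the isochoric first invariant and \(J_{el}\) the elastic volume
ratio.  Cell traction is modeled as a stress-free isotropic shrinkage of
the cell-laden material: the deformation gradient splits multiplicatively,
\(F = F_e F_s\) with \(F_s = (1-\varepsilon_s) I\), and the strain energy
is evaluated on \(F_e\) only (energy per unit reference volume carries the
factor \(J_s = (1-\varepsilon_s)^3\)).  This is the direct counterpart of
imposing an equivalent thermal contraction in a commercial code, without
the thermal machinery.  ε_s is stored as a positive magnitude; 0.6 means
the stress-free state of contracted material is scaled by 0.4.

Plane stress applies because the 1 mm thickness is an order of magnitude
below the in-plane dimensions: the out-of-plane elastic stretch is solved
pointwise by a scalar Newton iteration (tolerance 10⁻¹⁰) so the transverse
stress vanishes at every quadrature point.

### Discretization and solver

Structured 4-node quadrilaterals (100 µm squares by default, matching the
element size at which the deformation field is averaged and reported) with
2 × 2 Gauss quadrature; at ν = 0.4 under plane stress there is no
incompressibility locking, so full integration is the simplest robust
choice.  The solver is total-Lagrangian Newton with the load ramped in
increments and automatic step halving on divergence (at most 5 halvings),
relative residual tolerance 10⁻⁸.  The residual is the analytic gradient
of the discrete energy (verified by central finite differences to 10⁻⁵);
the tangent is assembled by central differences of element residuals,
which preserves Newton's fast local convergence at a fraction of the
implementation complexity of the exact plane-stress-condensed tangent.
The implementation is specialized to axis-aligned structured meshes of
congruent square elements (one set of shape-function gradients serves all
elements), which is what makes a pure-R assembly fast; material frame
indifference is verified at the constitutive level on affine deformations.

`fitShrinkageStrain` sweeps ε_s over a grid (step 0.05 up to 0.7 by
default), warm-starting each solve from the previous grid point so the
sweep is one continuation run, and picks the grid value whose simulated
area shrinkage is closest to the measured target (ties to the smaller
strain).  The area is the shoelace polygon area of the deformed boundary.

### From deformation to alignment

At any material point, `polarDecompose` splits F = R U by the
eigendecomposition of FᵀF.  A circle of radius r = 0.05 mm deforms into an
ellipse with semi-axes r·λ_max, r·λ_min (principal stretches of U); the
**local alignment factor** is α = λ_max/λ_min ≥ 1 and the **model
alignment angle** β_model is the orientation of the spatial major axis,
the leading principal direction of F Fᵀ (equivalently R applied to U's
major eigenvector).  β_model is invariant to the seed radius and to
uniform scaling of F, and rotates with superposed rotations; α is the same
quantity whichever construction is used (asserted to 10⁻¹⁰ in the tests).

To bridge to the discrete-fiber index, 150 fibers (the typical count
extracted from a 100 µm × 100 µm image ROI) are seeded at uniform angles,
mapped through F as material tangents, and fed to `alignmentIndex`.  For
pure stretch with axis ratio α and uniform fibers the equivalent index has
the closed form \(S = (\alpha-1)/(\alpha+1)\); at n = 150 the
discretization deviation stays below 0.02.  This reconciles the (α, S)
pairs the three branches report: α = 7.8 ↦ S ≈ 0.77 and α = 3.5 ↦ S ≈
0.56.

### Region sampling

The corner-edge (CE), middle-edge (ME) and middle-center (MC) regions are
sampled at reference coordinates exposed in `alignmentMap(samplePoints=)`.
The defaults place CE on the free lateral edge one element away from a
fixed corner, ME on the same free edge at mid-span, and MC at the domain
center; α, β and the equivalent S are averaged over the sampled element's
2 × 2 quadrature points (angles averaged axially).  Two caveats are
deliberate and documented rather than hidden:

* The deformation is singular at the fixed–free corner, so the CE value
  depends on the element size: the region definition is *tied to the
  100 µm element*, exactly as the reported field is averaged over 100 µm
  elements.  ME/MC and domain-averaged values converge under refinement
  (< 0.1 % between 200 µm and 100 µm meshes); a fixed physical window
  touching the corner converges at only ~2 %.
* Of the four symmetry-equivalent corners, the default CE corner is the
  one whose spatial major axis falls near 145°; its mirror images report
  the axial mirror 180° − β.  ME and MC are computed separately and their
  agreement is asserted in the tests, not assumed.

## Synthetic data: what it emulates, what it does not

The generators exist so every stage is testable without instrument data:

* `genPolarizedSpectra` / `genAcquisitionSet` — Gaussian bands at 1445,
  1465, 1605, 1656 and 1675 cm⁻¹ on a smooth polynomial baseline with
  i.i.d. Gaussian noise; the amide I bands are modulated as
  \(h(\varphi) = h_0(1 + m \sin(\pi(\varphi-\varphi_c)/90))\).  The
  acquisition layout (2 ROIs × 11 points × 12 replicates, replicates
  cycling through the six polarization angles) mirrors a real session:
  264 spectra at 22 points per location.
* `genReferenceSet` — a dense polarization scan of a strongly modulated
  "reference muscle" model, so PC1 of the preprocessed set is the amide
  modulation axis.
* `genFiberAngles` — axial wrapped-normal angles with the closed-form S
  oracle above.

All generators are pure functions of (parameters, seed).  They do *not*
emulate shot noise, cosmic rays, wavenumber miscalibration, water/Matrigel
interference, depth averaging, or non-affine fiber kinematics — so passing
tests demonstrate that the *analysis chain* recovers known structure, not
that the instrument model is realistic.  Absolute amplitude values depend
on band heights and are not comparable to any particular instrument's
scale; only relative amplitudes (γ) and phases are meaningful end-to-end.

## Numerical choices and degenerate inputs

* SNV refuses zero-variance spectra; `deriveLoading` refuses identical
  reference sets (< 2 distinct spectra leave PCA undefined).
* `projectPC1` refuses grid mismatches instead of silently interpolating;
  resampling is an explicit, logged step.
* Isotropic fiber sets (vanishing doubled-angle resultant) return an
  undefined-axis flag; S is still reported (it is 0 in the limit).
* Polar decomposition and the ellipse construction require det F > 0;
  isotropic F returns α = 1 with an undefined angle rather than an
  arbitrary one.
* Angle comparisons across modalities always use the axial distance
  (`axialDiff`), so 175° vs 5° is a 10° disagreement, never 170°.
* Tie-breaks: equal-|error| shrinkage fits resolve to the smaller strain;
  multiple elements attaining γ = 1 would all be reported.

## Problem sizes

The shipped analyses use the production mesh (40 × 100 = 4000 elements at
100 µm; a ~55 s continuation sweep over 15 strain values on one core) and,
in tests, coarser meshes (200–500 µm) wherever the property under test is
resolution-independent.  Stochastic checks use n = 10⁵ fiber draws for
moment accuracy and 22-point synthetic PRS sessions matching the real
layout.

## Known limitations

* The continuum model applies uniform contraction in a homogeneous strip:
  no time evolution, no cell-density field, no fiber-network (non-affine)
  mechanics, no contact with the mold, no 3-D thickness effects beyond
  plane stress.
* PRS amplitudes are depth-averaged and scale-dependent; cross-modality
  comparisons should use γ and angles, not raw A.
* The FE assembly is restricted to the structured square-element meshes
  `buildMesh` produces; it is not a general unstructured solver.
* The corner-edge metric is tied to the 100 µm element size by
  construction (see Region sampling).
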