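---
title: "Quantifying granule densities in cryo-STEM bright-field tomograms"
author: "cstetQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying granule densities in cryo-STEM bright-field tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cstetQuant)
```

## The measurement model

In scanning transmission electron microscopy of vitrified cells, the
bright-field (BF) detector collects electrons transmitted within a small
acceptance cone (cutoff semi-angle $\theta_c \approx 5$ mrad at 200 keV).
Material in the beam scatters electrons out of that cone, so denser or
heavier material appears *darker*. In the thin-sample, low-contrast regime
the reconstructed voxel intensity is modeled as linear in the local
scattering power:

$$ I(\mathbf{r}) = x - g\,S(\mathbf{r}), \qquad
   S = \sum_e n_e \,\sigma_e(\theta > \theta_c), $$

where $x$ is an additive background contributed by electrons that were
never scattered out of the acceptance cone, $g$ is an unknown instrument
gain, $n_e$ is the number density of element $e$ (atoms/nm^3^) and
$\sigma_e$ its partial elastic cross-section for scattering beyond the
cutoff. Neither $x$ nor $g$ is known for a given reconstruction, but both
cancel in ratios of background-subtracted intensities:

$$ \frac{I_A - x}{I_B - x} \;=\; \frac{S_A}{S_B}. $$

Because cells contain objects of known composition — ribosomes, and
cytosolic fluid that is essentially water — this one equation determines
$x$ from measured intensity levels, after which *any* intensity maps
linearly onto an absolute density scale anchored at the background
(density zero) and at the extrapolated intensity of a reference solid
(crystalline tricalcium phosphate, TCP, for calcium-phosphate granules).

## Reference compositions

Three reference materials are packaged (`referenceProfile()`):

* **Vitreous ice** ("water"): O and H at the densities implied by bulk
  low-density amorphous ice, 0.93 g/cm^3^ (configurable). Only oxygen
  contributes signal, since hydrogen scatters negligibly beyond the
  cutoff.
* **Ribosome**: per-element atom counts of a complete solvated particle
  over a 7000 nm^3^ envelope volume; the 42% of that envelope that is
  solvent is treated as bulk vitreous ice (`solvatedComposition()`).
* **Ribosomal RNA**: the RNA component alone, converted to densities
  through its partial specific volume, 0.569 cm^3^/g. The RNA scatters
  more strongly than the protein-plus-solvent average, and its peak is
  what a "peak ribosome" threshold selects.
* **TCP**, Ca~3~(PO~4~)~2~ at 3.14 g/cm^3^, from formula stoichiometry.

Each profile can be built two ways: `pathway = "computed"` derives the
densities from the packaged counts and parameters; `pathway = "printed"`
(default) returns the quoted tabulated densities, which are the canonical
calibration inputs. The two agree within 1% for every element except the
rRNA magnesium entry, whose quoted value (0.24 atoms/nm^3^) is not
derivable from the stated count (239 atoms) and partial specific volume —
those give 0.109 atoms/nm^3^ — and appears to be a typographical error in
the source tabulation. Magnesium contributes about 0.2% of the rRNA
signal, so no downstream quantity changes at quoted precision; the
packaged file stores the quoted value and the test suite asserts the
recomputed one for that single cell.

## Scattering signals and quoting conventions

`signalPerVolume()` contracts a density profile with the packaged
cross-section table ($\sigma$ in nm^2^ per atom beyond 5 mrad at
200 keV), yielding the expected signal per nm^3^ (`bfSignalTable()`
collects all four materials). Two numerical conventions matter and are
applied *only* at the reporting layer:

* Signals are quoted at 3 decimals, and material/water ratios are formed
  from the quoted signals, then quoted at 2 decimals. The unrounded
  TCP/water quotient is about 0.3% larger than the quoted chain; the
  reference evaluation propagated the quoted values, and
  `granuleDensityReport()` reproduces that arithmetic so that its output
  matches the published grid cell-for-cell. The unrounded signals are
  always returned alongside.
* The estimated background $x$ is quoted at 3 significant figures before
  the TCP level is extrapolated in reports (`quoteX = TRUE`); the exact
  solution is kept by default in programmatic use
  (`intensityCalibration()`, `calibrationFromReference()`).

A screened-atom (Lenz/screened-Rutherford) model
(`lenzPartialCrossSection()`) is provided for sensitivity analysis: a
closed-form integral of
$d\sigma/d\Omega = (2Ze^2/4\pi\epsilon_0 pv)^2/(\theta^2+\theta_0^2)^2$
with screening angle $\theta_0 = \lambda/(2\pi a_0 Z^{-1/3})$ and
relativistic $pv$. The model behind the packaged per-atom values is not
identified, and the Lenz values come out far below them (orders of
magnitude, not a rounding difference), so the packaged table is the sole
calibration pathway; the Lenz op is tested only for internal correctness
against numerical quadrature and for its monotonicity properties. Because
the calibration uses only *ratios* of signals, a common multiplicative
model error cancels; what matters is the relative weighting across
elements.

```{r lenz-comparison, eval = FALSE}
# sensitivity: Lenz-model ratios vs packaged-table ratios
lz <- lenzCrossSectionTable()
c(packaged = predictedRatio(signalPerVolume(referenceProfile("TCP")),
                            signalPerVolume(referenceProfile("water"))),
  lenz = predictedRatio(signalPerVolume(referenceProfile("TCP"), lz),
                        signalPerVolume(referenceProfile("water"), lz)))
```

## Calibration

`estimateBackground(ref, water, R)` solves $(I_{ref}-x)/(I_w-x) = R$
exactly: $x = (R I_w - I_{ref})/(R-1)$, which for BF polarity
($I_{ref} < I_w$, $R > 1$) always lies above the water level. Two
pairings are supported, mirroring the two internal standards:

* **primary** (`rna_peak`): the peak-ribosome intensity paired with the
  rRNA/water ratio — the darkest ribosome voxels are RNA-dominated;
* **parenthetical** (`ribosome_inclusive`): the whole-ribosome threshold
  paired with the ribosome/water ratio.

The TCP level then extrapolates as $I_{TCP} = x - R_{TCP/w}(x - I_w)$,
and `densityFraction()` maps any intensity to
$(x - I)/(x - I_{TCP})$ = fraction of crystalline TCP, with mass density
= fraction × 3.14 g/cm^3^ and molar density dividing by the Ca~3~(PO~4~)~2~
formula weight computed from the packaged atomic weights (≈310.17 g/mol).
Intensities above the background would imply negative density; they are
flagged with a warning, never clipped, since they indicate a calibration
or measurement problem the user must see. `equivalentConcentration()`
converts a granule density plus a granule volume fraction into
liquid-equivalent molarities (3 Ca^2+^ and 2 PO~4~^3−^ per formula unit).

Degenerate inputs are rejected at construction: the five thresholds must
satisfy peak < inclusive < water within each object class, predicted
ratios must exceed 1, and the calibration object's validity enforces the
BF polarity ordering $I_{TCP} < I_w < x$.

## Morphometry

Granules are segmented by a single intensity threshold (BF: voxels at or
below the level), followed by 3D connected-component labeling. Default
connectivity is 26 — granules are compact blobs and 26-connectivity
matches visual segmentation practice — with 6 and 18 available. Per
component the package reports voxel count, volume, equivalent spherical
diameter $d = (6V/\pi)^{1/3}$ and centroid; components below 10 nm
equivalent diameter (default) are counted separately as noise specks,
a cut chosen below the smallest granules of interest (~20 nm) and above
the single-voxel noise scale at typical 1–4 nm sampling. Volume fractions
are computed over axis-aligned, half-open voxel boxes
(`volumeFraction()`), the estimator used for "granules occupy X% of the
mitochondrial volume".

The Fourier band-pass (`bandpassFilter()`) retains wavelengths between
`lowCut` and `highCut` pixels (reference setting 1–100 px) and is applied
per (y, x) slice by default, since reconstruction shading is a per-slice
artifact; a 3D variant is available. Any band with a finite upper
wavelength excludes DC, so filtered volumes are zero-mean; thresholds
must be re-measured after filtering, not carried over.

## The phantom generator

`generatePhantom()` emulates the features of a BF reconstruction that the
analysis relies on, with every parameter known:

* an ellipsoidal mitochondrion (default semi-axes 300 × 350 × 450 nm)
  whose matrix scatters slightly more than cytosol (0.18 vs 0.159 nm^-1^),
  as matrices appear darker than cytosol in BF;
* spherical granules with lognormal diameters (median 50 nm,
  sdlog 0.35) truncated to the observed 20–100 nm range, placed
  largest-first by rejection sampling with no overlap and an 8 nm minimum
  gap, until a target fill fraction (default 20%) of the ellipsoid is
  reached; each granule scatters at `fractionOfTcp` (default 0.40) times
  the TCP signal;
* 25 nm ribosome-like puncta in the cytosol at the predicted ribosome
  signal;
* intensity $I = x - gS$ with $x = 24.3$ and $g$ set so cytosol sits at
  16 (the representative tomogram's scale), Gaussian PSF (default
  $\sigma$ = 4 nm, one voxel) and additive Gaussian noise (default sd
  0.5 intensity units).

All randomness flows from the single spec seed through a private RNG
stream; generation is bit-reproducible and leaves the caller's RNG
untouched. Packing is declared infeasible (an explicit error, after a
bounded number of placement attempts per granule) if the realized fill
falls more than 10% relative below the target; individual granules that
would overshoot the target by more than 10% are skipped so the realized
fill brackets the target.

What the phantom deliberately does **not** model: exponential (multiple-
scattering) attenuation — the intensity is exactly linear in signal, so
recovery tests validate the calibration arithmetic, not the linearity
assumption itself; detector/dose physics (Poisson counting, probe shape);
missing-wedge artifacts in the directly generated volumes (the toy
projector/WBP/SIRT path exists to demonstrate those separately and is not
part of the quantitative chain); and any non-spherical granule shape or
intra-granule heterogeneity. Passing recovery tests therefore show that
the pipeline inverts its own forward model at realistic noise, blur and
crowding — not that real tomograms satisfy that model.

`measureReferenceLevels()` reads the calibration levels off the ground
truth: water as the mean over cytosol voxels clear of all objects and the
grid border, the ribosome peak as the mean over ribosome center voxels,
the granule peak over granule interiors eroded by twice the PSF plus one
voxel (so blur does not bias the plateau), and the inclusive level as the
matrix/granule half-contrast — the level at which a blurred sphere's
half-height surface sits at its true boundary, which is what makes
segmentation-based sizes and fills unbiased to first order.

## Tomography toy model

`projectTiltSeries()` computes parallel-beam line integrals about the y
axis with unit-voxel sampling and zero-padded bilinear interpolation
(border samples collect their in-bounds interpolation share, which makes
the zero-tilt projection an exact column sum). `reconstructVolume()`
offers ramp-filtered backprojection (WBP; band-limited Ram-Lak kernel in
real space, avoiding the DC bias of a plain $|f|$ multiplier) and SIRT
with row/column-sum normalization, whose reprojection residual is
non-increasing. A ±60° series shows the classic missing-wedge elongation
along the beam axis. Reconstruction is intentionally decoupled from the
calibration tests so their correctness is not hostage to reconstruction
artifacts.

## Problem sizes and test design

The validation suite runs the full recovery at the study scale: a 256^3^
phantom at 4 nm voxels (a ~1 µm^3^ field), fill 0.20, granule density
0.40 of TCP, PSF 4 nm, noise 0.5, seed fixed a priori. Recovered density
must land within ±0.05 and the segmented fill within ±0.02 of the
ground-truth mask fill in the same ROI (an inscribed box, so the
comparison isolates segmentation accuracy from the spatial sampling
fluctuation of granule placement); the realized global fill must honor
the 20% target within 10% relative. Size-distribution recovery uses a
50-granule phantom and requires the mean recovered equivalent diameter
within 10% of the generator's. Counts measured on real tomograms in the
source study (numbers of mitochondria, tomograms, cells) are not
reproducible from a desk and are out of scope; the synthetic recovery
suite stands in for them.

## Known limitations

* The intensity model carries a single additive background; per-voxel
  thickness or illumination variation is not corrected beyond the
  band-pass filter.
* The quoting conventions above mean programmatic (unrounded) results
  differ from report cells in the third decimal; use the report layer
  when comparing to the published grid.
* The Lenz cross-section op is a sensitivity tool only.
* MRC I/O supports modes 0/1/2, little-endian, single-volume files.
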