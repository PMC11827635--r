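---
title: "Models and methods behind actinlattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind actinlattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinlattice)
```

actinlattice quantifies how ligand complexes decorate actin filaments, at
two very different scales: per-subunit helical lattice geometry measured
from 3D models and density maps, and micron-scale binding measured from
two-channel fluorescence images. This vignette explains the models the
package implements, the parameters that matter, the numerical choices
made where the underlying procedures are underdetermined, and what the
synthetic-data generators do and do not emulate.

## Helical lattice geometry

F-actin is a two-strand helical polymer. Consecutive subunits along the
one-start (genetic) helix are related by a screw operation of about
-167 degrees (left-handed) and 27 Angstrom; subunits two indices apart —
neighbours along one strand — are related by the equivalent strand-level
step of about +26 degrees / 55 Angstrom (the wrap of 2 x -167 into
(-180, 180]). `build_filament()` generates models from this
parameterisation (protomer index 0 at the pointed end, strand = index
parity, barbed end toward +z); `measure_lattice()` and
`strand_profile()` invert it.

**Twist and rise definitions.** Rise is the distance between neighbouring
subunit centroids projected on the local filament axis. Twist is the
signed rotation about that axis carrying one subunit's azimuth onto the
next; angles are wrapped to (-180, 180] and kept in degrees throughout.
Two routes are implemented and agree to 1e-12 on noise-free generated
lattices:

* `method = "azimuthal"` (default): twist from centroid azimuths about
  the local axis, with the transverse circle centre fitted per window
  (Kasa algebraic fit, exact for exact circles).
* `method = "orientation"`: twist from the relative subunit orientation
  quaternions projected on the local axis (a swing-twist decomposition).

**Local axis.** The axis is never given by the data, so it is estimated
from a sliding window of centroids (default 7). For points on a helix
with constant rise, the second differences of consecutive centroids are
purely transverse, so cross products of consecutive second differences
recover the axis direction *exactly*, for any per-step twist sequence;
the principal-direction fallback covers degenerate (untwisted,
collinear) windows, where it is itself exact. This is why noise-free
round trips in the test suite hold to 1e-6 and better rather than to a
few tenths of a degree, which is what a windowed principal-component
axis would give. Models shorter than the window fall back to a global
axis with a warning.

**Curved filaments.** Uniplanar curvature is associated with asymmetric
twist between the two strands (twist-bend coupling). `bend_filament()`
generates such states: centroids are mapped onto a circular arc
(curvature `kappa`, radius `1/kappa`) with arc length preserved, frames
parallel-transported, and a commanded strand twist asymmetry `a` applied
as +a/2 per strand-level step on strand 0 and -a/2 on strand 1, so the
measured strand means differ by exactly `a`. With the canonical
left-handed lattice a negative `a` under-twists strand 0, which the
generators treat as the convex-side, decorated strand. Curvature 0 with
asymmetry 0 returns the input unchanged, bit for bit.

Before measurement, profiles of curved models are straightened: the
backbone arc is estimated from wobble-cancelling smoothed centroids
(weights 1,2,2,2,1 / 8 nearly annihilate the fast ~167 degree-per-step
wobble), fitted by quadratics in the two transverse coordinates, and the
bend mapping inverted. The straightening only engages when the fitted
arc's sagitta exceeds 12 times the fit residual — genuine arcs at bend
radii of 1000-4000 Angstrom score 20-180 on this ratio, while helical
wobble that escapes the smoothing filter scores below 8 — so straight
lattices, where direct measurement is exact, are never distorted by a
spurious arc.

**Known limitation.** On *curved* lattices whose strand asymmetry chirps
the one-start wobble, the azimuthal route retains a residual of a few
tenths of a degree after straightening (arc-fit leakage); the
orientation route recovers commanded asymmetries to better than 0.05
degrees at bend radii >= 1000 Angstrom and is what
`frame_series_occupancy()` uses for curved-frame geometry. On straight
lattices both routes are exact, and the azimuthal route remains the
default because it needs only centroids.

**Tiling and trimming.** Following the standard measurement protocol,
`tile_filament()` superposes copies end-over-end on a shared overlap
(least-squares Kabsch superposition over the overlap centroids; three
copies of a 15-mer with a 4-subunit overlap give the 37-subunit extended
model), and `trim_central()` retains a central block of steps (default
10) to avoid edge effects. For even leftover counts the retained window
shifts toward the pointed end; this tie rule is documented and tested.
The generator's helical radius (centroid distance from the axis,
default 25 Angstrom) does not affect twist or rise measurements on
generated models; it is configurable.

## Density-map occupancy

`render_density()` is a deterministic forward model standing in for
reconstructed frame volumes: each subunit contributes an isotropic
Gaussian blob (amplitude 1, sigma 5 Angstrom by default) and each
decorated site a blob of amplitude equal to its occupancy, anchored 25
Angstrom radially outward from the subunit centroid along the subunit's
body-frame x axis (which the generators keep pointing radially, also on
bent models). A blob of amplitude A integrates to
A (2 pi sigma^2)^(3/2), which the tests use as a closed-form oracle.

`split_density()` partitions foreground density by nearest-reference
(Voronoi) assignment within a cutoff radius (default 15 Angstrom) among
subunit centroids and site anchors; the output grids partition the
foreground exactly, voxel for voxel. `site_intensities()` integrates
each site subvolume, and `normalize_sites()` divides by the maximal
site, which serves as the occupancy proxy: a fully occupied bound
complex is taken to have the same rendered intensity as an actin
subunit. This calibration is adopted as an assumption, as in the
analysis the package reimplements.

Two normalisation scopes exist for frame series: the default
(`"per-series"`) divides all frames by the series-wide maximal site so
frames are mutually comparable — required for a trajectory read-out —
and `"per-frame"` is available. Site anchors come from generator ground
truth, so model-to-map fitting error is zero by construction; with the
default geometry (anchors 5 sigma from centroids, cutoff 3 sigma) the
proxy recovers generator occupancies to about 0.01, the residual being
actin-tail contamination, which largely cancels under normalisation.

The ten-frame default series couples curvature (0 to 1/2000 per
Angstrom), strand asymmetry (0 to -2 degrees) and convex-strand
decoration (baseline 0.1 ramping by 0.9) linearly along the series,
emulating the ordered structure of a variability trajectory; the bare
strand stays at baseline. The association between local strand twist and
occupancy is reported as both Spearman and Pearson coefficients, since a
scatter read-out does not fix the rank-vs-linear choice; with uniform
occupancy both are reported as not applicable.

## Cooperative lattice binding

The bridging of adjacent actin-binding domains by a coiled-coil is
modelled as nearest-neighbour cooperativity on a 1D lattice of
`n_sites` (default 200) with free ends. Association at a site with `b`
bound neighbours proceeds at `k_on * C * omega^b` and dissociation at
`k_off * omega^(-b)`. Omega therefore acts twice, and the equilibrium
statistical weight of a bound nearest-neighbour pair is `omega^2`; the
exact oracle `equilibrium_coverage_exact()` applies that weight
internally so simulator and oracle agree when called with the same
omega. The symmetric split (omega^(b/2) on each rate) was deliberately
not used: the asymmetric placement is the conventional way to write a
bridging-stabilised off-rate, and the tested quantity — equilibrium
coverage — depends only on the product.

The oracle computes the exact Boltzmann average either by brute-force
enumeration (n <= 20) or by a transfer-matrix recursion with running
normalisation (any n, no overflow); the two agree to 1e-12 and the
omega = 1 case collapses to the Langmuir isotherm exactly. The Gillespie
simulator is validated against the oracle within three batch-means
standard errors across an (omega, concentration) grid; because interior
dissociation slows as omega^-2, patch relaxation reaches tens of
seconds at omega = 5 and the validation runs use 1000 s of simulated
time so batch lengths dominate the relaxation time.

`fit_hill()` fits f(C) = f_max C^h / (Kd^h + C^h) by bounded
Levenberg-Marquardt with multistart (Kd from concentration quartiles,
h in 0.7-4). f_max is fitted rather than pinned to 1 because measured
fraction-bound commonly saturates below 1; `fix_fmax = TRUE` pins it.
Noise-free curves are recovered to machine precision; the
parameter-recovery protocol (8 log-spaced concentrations 0.1-4 uM
bracketing Kd = 0.94 uM, 3 replicates, 5% CV multiplicative noise,
fixed seed) recovers Kd within 10% and h within 15%. These are
parameter-recovery checks on synthetic curves: the underlying
experimental dataset is not deposited, so the reported Kd and h act as
generating parameters, not as refit targets.

The default binding kinetics (`k_off/k_on = 8.4 uM`, `omega = 3`) were
chosen once so that the exact equilibrium curve, Hill-fitted over the
default concentration grid, shows the reported apparent behaviour
(Kd ~0.92 uM, h ~2.7). `patch_statistics()` audits the event log:
association events are classified as nucleations, left/right-end
elongations or gap fills, patch identities are tracked through merges
and splits, and the fraction of patches that grew at both ends — the
signature of bidirectional patch elongation — is reported.

## Image quantification

**Rolling-ball background subtraction** is implemented as grayscale
opening with a non-flat ball structuring element (height profile
sqrt(r^2 - d^2)); the default radius is 100 pixels. Output is clipped at
zero; flat images and constant offsets are removed exactly, and a
feature of diameter D on a flat background is attenuated by at most
r - sqrt(r^2 - (D/2)^2), under 1% of amplitude for D << r. Radii above
24 pixels are processed on a block-minimum shrunken image and
re-enlarged bilinearly, mirroring common large-radius practice; the
exact path is cross-checked in the tests against a naive morphological
oracle.

**Yen thresholding** is implemented from the criterion definition over a
256-bin histogram on the min-max intensity range (the binning is a
documented choice; the method's source does not state one) and verified
in the tests against an exhaustive criterion scan; it also matches the
scikit-image reference implementation to 1e-7 on shared inputs. One
behavioural property matters for pipeline design: with strongly
unbalanced classes (foreground a few percent to ~20% of pixels) the
criterion places its threshold just above — or inside — the background
mode rather than mid-gap. That is the method, not an artefact, and it
shapes the synthetic TIRF optics below.

**Fraction bound** is the area of the conjunction of the filament and
ligand masks divided by the filament mask area
(`quantify_tirf_pair()` chains rolling-ball on the ligand channel,
per-channel Yen, conjunction; background subtraction defaults to the
ligand channel only, matching the quantification it reimplements, with
`"both"` and `"none"` available).

**Line scans and FWHM.** `line_profile()` samples both channels along a
line with bilinear interpolation, averaged across a perpendicular width.
`fwhm()` takes the profile minimum as baseline (robust to offsets; a
percentile baseline is available), half-maximum midway between baseline
and the global maximum, and locates the two flanking crossings by linear
interpolation; plateaus or multiple maxima use the global maximum with a
warning. Gaussian bands give 2 sqrt(2 ln 2) sigma within 2% at
realistic sampling, and the two-channel ratio
(`fwhm_ratio()`) reads 1 for equal bands and sigma_a/sigma_b for
unequal ones, with a configurable broadening flag (default 1.5). The
exact peak-finding conventions of the original line-scan protocol are
not restated in its source, so these baseline and interpolation rules
are explicit package decisions.

## What the synthetic data emulate — and what they do not

Every generator output ships with a ground-truth record sufficient to
score the downstream operation without re-deriving truth, and identical
config + seed gives bit-identical outputs.

* **Frame series**: ordered curvature/decoration coupling with per-step
  lattice truth. Not emulated: reconstruction noise, resolution
  anisotropy, fitting error of atomic models into maps (anchors are
  truth), or the latent-space analysis that produces real frame series.
* **Volume library**: for each complex orientation (default azimuths 0,
  120, 240 degrees) and curvature, one bare + one fully decorated +
  `n_partial` randomly decorated filaments, the counting structure of a
  segmentation-training library. The published library's total (312) is
  reproducible by configuration, not hard-coded, because the per-cell
  counts behind that total are not stated. Blobs stand in for the
  coarse complex model; blob realism is outside testable scope.
* **TIRF pairs**: filaments as lines (one lattice site per 5 pixels,
  3 pixels thick) under binned-camera optics — 0.2 um pixels, an
  effectively sub-pixel PSF (sigma 0.05 um, as after deconvolution),
  Poisson shot noise (gain 10) over a flat background. These optics
  were chosen once so that the half-amplitude truth masks and the
  Yen-based pipeline measure the same quantity: given Yen's
  threshold-placement behaviour above, any blurred-edge plateau or
  background-noise tail near the threshold splits randomly between the
  two independently noisy channels and biases the mask conjunction by
  0.02-0.15 regardless of sampling density. With resolved features and
  zero-background shot noise the pipeline reproduces truth fractions to
  ~0.004 and recovers the reference Hill parameters within 15%. What
  passing these tests shows is that the pipeline is implemented
  correctly; it does not show that fraction-bound is unbiased on real,
  diffraction-limited, read-noise-limited images — on such data the
  Yen threshold sits in the PSF tails and the absolute fraction depends
  on the optics, which is one reason saturation curves fit f_max
  rather than pinning it to 1.
* **Junction images**: straight bands with per-channel Gaussian
  cross-sections plus Gaussian noise — sufficient for the FWHM-ratio
  statistic, with none of the cell-shape, tricellular-vertex or
  staining-variability structure of real junctions.

## Problem sizes and runtime choices

The default study sizes — 37-subunit models, ten 4-Angstrom-voxel
frames, 200-site lattices, eight concentrations with three filaments
per image, a 4 x 4 simulator-validation grid at 1000 simulated seconds
— were chosen as the smallest sizes at which every statistic above is
measured well inside its stated tolerance; the full test suite and the
acceptance script each run in a few minutes on one CPU.
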