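# actinlattice

Quantitative analyses for ligand-decorated actin filaments: helical
lattice geometry, density-map occupancy, cooperative binding, and
two-channel fluorescence quantification.

## What this package is for

Adhesion complexes such as the cadherin–catenin–vinculin assembly bind
F-actin cooperatively — a coiled-coil bridge links adjacent
actin-binding domains along one strand — and that binding is coupled to
filament shape: curved filaments carry asymmetric twist between their
two strands (twist-bend coupling), and the under-twisted strand is the
decorated one. Testing such claims requires a chain of measurements
that span structural and light-microscopy data:

* **Lattice geometry** — per-subunit twist and rise of a two-strand
  helical lattice (one-start step ≈ −167° / 27 Å; strand-level step
  ≈ 26° / 55 Å), measured per strand on straight and curved filament
  models, with end-over-end tiling (3 × 15-mer → 37-mer) and central-10
  trimming to avoid edge effects.
* **Occupancy** — splitting a density map between filament and bound
  complexes, integrating each site's subvolume, and normalising to the
  maximal site as an occupancy proxy, tracked per strand across an
  ordered frame series and correlated with local twist.
* **Cooperative binding** — a 1D nearest-neighbour lattice model
  (association `k_on·C·ω^b`, dissociation `k_off·ω^(−b)` for `b` bound
  neighbours), an exact transfer-matrix equilibrium oracle, an
  event-driven Gillespie simulator with patch-elongation audits, and
  Hill fits `f(C) = f_max·C^h/(K_d^h + C^h)` of saturation curves.
* **Image quantification** — fraction of the filament mask bound by
  ligand (rolling-ball background subtraction → Yen thresholding →
  mask conjunction) and junction line-scan FWHM ratios.

Every analysis stage has a seeded synthetic-data generator with ground
truth, so the whole chain is testable without any experimental
download. The package is aimed at structural biologists and
cytoskeleton labs who want these measurements as tested, reusable
functions rather than one-off scripts.

## Worked example

Build the canonical 37-subunit model by tiling, measure its lattice,
then bend it with a commanded −2° strand twist asymmetry and recover
that asymmetry:

```r
library(actinlattice)

f15 <- build_filament(helical_symmetry(-167, 27), 15)
f37 <- tile_filament(f15, n_copies = 3, overlap_subunits = 4, "pointed")
summarize_profile(trim_central(measure_lattice(f37), 10))
#>   strand  n twist_mean     twist_sd rise_mean rise_sd
#> 1      0  5       -167 2.863408e-13        27       0
#> 2      1  5       -167 1.556721e-13        27       0
#> 3    all 10       -167 9.217967e-13        27       0

bent <- bend_filament(f37, curvature = 1/2000, c(1, 0, 0),
                      strand_twist_asymmetry_deg = -2)
e <- strand_profile(bent, method = "orientation")$entries
mean(e$twist_deg[e$strand == 0]) - mean(e$twist_deg[e$strand == 1])
#> [1] -2.001059
```

Fit a saturation curve with the Hill equation (three replicates, 5%
multiplicative noise, generated at K_d = 0.94 μM, h = 2.7):

```r
set.seed(8)
C <- exp(seq(log(0.1), log(4), length.out = 8))
noisy <- do.call(rbind, lapply(1:3, function(r)
  data.frame(concentration = C,
             fraction_bound = hill_curve(C, 0.94, 2.7) *
               (1 + rnorm(8, sd = 0.05)))))
fit_hill(noisy)
#> <hill_fit> Kd = 0.9128 uM, h = 2.71, f_max = 0.972 (|r| = 0.0692)
```

The recovered K_d (0.91 μM) and h (2.71) sit within the recovery
tolerances (10% and 15%) of the generating values.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full
study on synthetic data and write tables under `results/`:

| script | what it computes |
|---|---|
| `01_lattice_geometry.R` | tiled 37-mer twist/rise, central-10 summary, twist-bend asymmetry vs curvature |
| `02_frame_series_occupancy.R` | per-strand occupancy trajectory over a 10-frame curved series, twist-vs-intensity table |
| `03_cooperative_binding.R` | simulator-vs-oracle grid, Hill h vs ω, patch-elongation audit, K_d/h recovery |
| `04_tirf_fraction_bound.R` | end-to-end TIRF fraction-bound curve and Hill fit |
| `05_junction_linescan.R` | junction FWHM ratios for equal and broadened bands |

Run any of them from the repository root, e.g.
`Rscript analysis/02_frame_series_occupancy.R`. The occupancy driver
prints, among other things:

```
decorated-strand mean normalised intensity per frame:
  0.105  0.204  0.303  0.401  0.500  0.598  0.697  0.797  0.895  0.994
occupancy proxy vs truth: max |error| 0.0118 over 370 sites
final frame twist vs intensity: Spearman -0.701, Pearson -0.999
```

— the decorated strand's occupancy proxy climbs with curvature while
the bare strand stays at baseline, and occupancy associates negatively
with strand twist (the under-twisted strand carries the signal).

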