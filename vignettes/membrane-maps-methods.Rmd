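---
title: "Methods: leaflet-resolved bilayer maps under hexagonal periodic boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaflet-resolved bilayer maps under hexagonal periodic boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranemaps)
```

## Scope and model

`membranemaps` analyses molecular-dynamics trajectories of phospholipid
bilayers interacting with a polymer nanoparticle. Simulations of membrane
patches are often run in a hexagonal prism unit cell (equal in-plane
lattice vectors at 120°), which maximises the lateral distance between a
centred inclusion and its periodic images at fixed cell area; most stock
membrane-analysis tooling assumes rectangular cells, which is the gap this
package fills. Every operation here — distances, tessellations, raster
maps — is periodic under a general triclinic cell in the reduced
lower-triangular MD convention (first lattice vector along x, second in
the xy plane).

The computed observables are the standard ones of membrane biophysics:

* **Leaflet assignment.** Lipids are grouped by connected components of a
  graph on phosphorus atoms with edges below a distance cutoff
  (minimum-image metric). On a curved membrane the two leaflets remain
  locally ~4 nm apart while intra-leaflet neighbours sit ~0.8 nm apart, so
  components separate the leaflets even when their z-ranges overlap and a
  midplane threshold would fail.
* **Area per lipid (APL).** Per leaflet, phosphorus xy positions are
  replicated with their 8 in-plane periodic images and each original site
  receives its Voronoi cell area, computed by iterative half-plane
  clipping (each cell is the intersection of bisector half-planes,
  visited nearest-first with an early exit). Because the periodic Voronoi
  cells tile the unit cell, per-leaflet areas sum *exactly* to the cell
  cross-section area — this conservation is asserted at 1e-9 relative in
  the tests and is the principal internal consistency check.
* **Thickness d_P.** Defined as the distance between phosphorus levels of
  the two leaflets: each leaflet's phosphorus z is rasterised
  (nearest-site fill) onto a fractional grid over the in-plane cell, the
  lower grid is subtracted from the upper, and frames are averaged.
* **Order parameter.** The deuterium order parameter
  S~CD~ = ⟨(3 cos²θ − 1)/2⟩ over C–H bond angles θ to the membrane
  normal, reported as a magnitude per acyl carbon. The laboratory z axis
  is used as the normal (the membrane is globally flat on average); local
  normals are intentionally out of scope for this release.
* **Density profiles.** Mass histograms along z in g/cm³, referenced to
  the mean-phosphorus midplane, with the conservation identity
  ∫ρ dz × A = group mass holding exactly by construction.
* **Coil metrics.** Mass-weighted radius of gyration, per-chain
  end-to-end distance, and the nanoparticle centre-of-mass height above
  the midplane. Molecules are made whole before any mass-weighted moment:
  wrapping corrupts centres of mass, so positions are unwrapped by
  chaining minimum-image steps along the bond order, then molecules are
  placed by the minimum-image shift of their centroids (adequate for
  compact assemblies; not for percolating aggregates).
* **Release classification.** Each probe molecule's distance to the
  nanoparticle COM over time is reduced to one number — its sample
  standard deviation — and the probes are clustered with k-means (Lloyd,
  k = 3, 10 restarts, best inertia). Labels follow ascending centroid:
  *immobile* (lowest dispersion, trapped in the particle), *released*
  (bounded wandering in the bilayer), *escaped* (large excursions). The
  mapping rule is ours: the source material describes the categories but
  not the assignment; ascending dispersion matches "distance remained
  almost constant" for trapped molecules.

## Raster conventions

Maps use an *n* × *n* grid over fractional in-plane coordinates (default
512), so all pixels have equal area in any triclinic cell. The fill rule
is nearest-site: a pixel takes the value of the lipid whose phosphorus is
periodically nearest. This makes a single-frame APL map exactly the
piecewise-constant Voronoi image, leaves no holes, and needs no
interpolation parameters. Whether the reference implementation
interpolated instead is unknowable from its description; the difference
is confined to cell boundaries and vanishes in the scalar summaries,
which either average per-lipid areas directly (APL) or are
pixel-weighted means whose fill-rule sensitivity is O(jitter/grid).

Consequence worth knowing: the plain pixel mean of an APL map converges
to the *area-weighted* mean Σaᵢ²/Σaᵢ of per-lipid areas, not the
unweighted mean — larger cells cover more pixels. Scalar APL summaries
therefore always come from the per-lipid areas, never from map pixels.

Windows follow the source conventions: maps average a 10 ns window at the
end of the trajectory, scalar summaries the last 50 ns. "Last *w* ns" is
defined strictly: frames with t > t_max − w, so with a 1 ns stride the
last 50 ns is exactly 50 frames.

## The synthetic world

No reference trajectories are deposited, so every stage is validated
against generated systems with planted, analytically known ground truth.
Defaults mirror the reference system: hexagonal cell, planted APL
0.64 nm², phosphorus-to-phosphorus thickness 3.93 nm, a nanoparticle of
14 chains × 40 styrene units (≈4.2 kDa per chain, bulk density
1.05 g/cm³), 32 probe molecules split 6 immobile / 18 released /
8 escaped.

* **Bilayer.** Phosphorus beads on a fractional lattice: an m₁ × m₂ grid
  of fractional coordinates has congruent Voronoi cells in *any* cell, so
  the planted APL is exact by symmetry, not approximately. This requires
  n = m₁ × m₂ with balanced factors; the default is 180 lipids/leaflet
  (12 × 15), the closest balanced count to the reference 178 + 178.
  Lipids are minimal — P bead plus two acyl chains of carbons with two
  explicit hydrogens each at a controlled angle to the normal — because
  the computed observables depend only on P positions and C–H vectors.
  Noise is rigid per-lipid isotropic Gaussian jitter (default σ =
  0.05 nm, a typical P-atom thermal displacement between frames), the
  simplest model whose effect on every average is known in closed form.
* **Curvature.** Both leaflets displaced outward by a Gaussian
  h·exp(−r²/2σ²), so central thickness is base + 2h; h = 1.965 nm doubles
  the 3.93 nm bilayer, emulating the lipid-covered inclusion regime. Note
  an outward bump *thickens*; overlapping leaflet z-ranges (the hard case
  for leaflet assignment) require an undulation, which the test suite
  constructs separately.
* **Nanoparticle.** Collapsed confined random walks packed in a sphere
  sized from bulk polystyrene density; styrene repeat units carry full
  C₈H₈ atom masses plus two capping hydrogens per chain, so chain mass is
  exact (40 units → 4.168 kDa, printed as 4.2).
* **Release series.** Immobile: constant + N(0, σ₁). Released: AR(1)
  around a bilayer-resident distance with stationary sd σ₂. Escaped:
  drift-dominated departure whose linear ramp pins the series sd near σ₃,
  plus a smaller random walk for excursions. The drift-dominated choice
  is deliberate: a pure random walk has so much path-to-path dispersion
  variance that the planted 6/18/8 labels would *not* be the optimal SSE
  partition — k-means would merge immobile with released and split
  escaped. "Well-separated dispersion" is part of the stated world, and
  separation must hold for the feature (the per-series sd), not just its
  expectation. Defaults σ = (0.05, 0.5, 2.0) nm.

What a green test does **not** establish: the generators are kinematic.
There is no force field, no thermostat, no correlated lipid motion, no
lipid flip-flop, no nanoparticle deformation, and probe "release" is a
stochastic script, not a free-energy barrier crossing. Green tests
certify that the *analysis* recovers what was planted at the stated
noise, nothing about membrane physics.

## Numerical choices

* Minimum image: fractional nearest-integer wrap followed by a ±1 shift
  search — exact for reduced-convention cells (all preinstalled and
  generated cells satisfy it); validated against exhaustive 125-image
  enumeration on random reduced triclinic cells.
* Voronoi degeneracy: coincident sites are perturbed once by 1e-9 nm
  (deterministic ε, far below any physical coordinate precision) and the
  tessellation recomputed; persisting duplicates raise an error rather
  than silently double-counting area.
* Half-plane clipping visits neighbours nearest-first and stops when the
  next bisector is provably outside the current cell (distance > twice
  the farthest vertex), giving near-linear behaviour per site.
* k-means: `stats::kmeans`, Lloyd algorithm, 100 iteration cap, restarts
  under a fixed recorded seed; with fewer distinct feature values than k
  the call errors and suggests reducing k.
* Leaflet graph pathologies: one connected component errors with advice
  to lower the cutoff; more than two components merge smallest-first into
  the nearest centroid with a warning, and per-frame label changes
  (flip-flop candidates) are counted in the pipeline log.
* All I/O is plain text. The JSON trajectory dialect (versioned, 0-based
  indices on disk) round-trips coordinates at full double precision; GRO
  round-trips at its native 10⁻³ nm.

## Open choices resolved

* Frame stride and leaflet-reassignment cadence are configuration values
  (`mode = "every"` or `"first"`); the reference's choice is unstated.
* S~CD~ uses explicit hydrogens only; reconstructing hydrogens for
  united-atom inputs is out of scope.
* Escaped-state detection uses the dispersion feature alone (the quoted
  method), not a solvent-contact criterion.

## Limitations

Half-thickness (leaflet-resolved) maps, curvature tensors, undulation
spectra, lipid diffusion and release-rate fitting are out of scope.
Binary trajectory formats (XTC/TRR) are unsupported in this R
implementation because no reader exists in the dependency footprint;
convert to the JSON dialect first. The raster fill rule is exact for
piecewise-constant quantities but is not an interpolator; do not use map
pixels for scalar statistics when the per-lipid records are available.
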