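# membranemaps

Trajectory analysis for lipid-bilayer / polymer-nanoparticle simulations
with first-class support for **hexagonal (and general triclinic) periodic
cells** — the case most membrane tooling does not handle. Intended for
computational biophysicists analysing membrane patches around an embedded
nanoparticle (e.g. a polystyrene nanoplastic in a POPC bilayer) and for
anyone needing periodic-correct per-lipid areas and thickness maps.

## What it computes

For a trajectory (structure: GRO/PDB; frames: a plain-text JSON dialect):

* **Leaflet assignment** by connected components of the phosphorus
  distance graph under the minimum-image metric — robust on curved
  membranes where a z-threshold fails.
* **Area per lipid (APL)**: periodic Voronoi tessellation of each
  leaflet's phosphorus positions (8-image ghost replication + half-plane
  clipping). Per-leaflet areas sum exactly to the cell cross-section.
* **Thickness maps** d_P: per-leaflet nearest-site rasters of phosphorus
  z over a fractional grid (default 512 × 512), top minus bottom,
  time-averaged; plus scalar summaries mean ± sd over a window
  (convention: last 50 ns).
* **Deuterium order parameters** |S_CD| = |⟨(3 cos²θ − 1)/2⟩| per acyl
  carbon, θ the C–H angle to the membrane normal.
* **Mass-density profiles** along the normal (g/cm³, midplane-referenced).
* **Polymer metrics**: mass-weighted radius of gyration R_g, per-chain
  end-to-end distance d_ee, nanoparticle COM height above the midplane
  (molecules made whole across the boundary first).
* **Release classification**: per-probe distance-to-nanoparticle series
  reduced to its sample standard deviation, then 1-D k-means (k = 3,
  Lloyd, 10 restarts); labels by ascending centroid:
  immobile < released < escaped.
* A **synthetic-data module** generating bilayer + nanoparticle + probe
  trajectories with planted, analytically known ground truth (APL,
  thickness, bump height, C–H angles, mobility classes), so the whole
  pipeline is testable without reference trajectories.

## Worked example

```r
library(membranemaps)

# a 128-lipid hexagonal bilayer with planted APL 0.64 nm^2 and
# thickness 3.93 nm, jittered by 0.05 nm, 20 frames
bil <- make_flat_bilayer(n_per_leaflet = 64, jitter = 0.05,
                         n_frames = 20, seed = 42)
asg <- assign_leaflets_trajectory(bil$frames, bil$selection)

ar <- voronoi_apl(bil$frames[[20]], asg$labels[20, ], bil$selection)
head(ar, 3)
#>   lipid leaflet      area
#> 1     1   upper 0.6267659
#> 2     2   upper 0.6444853
#> 3     3   upper 0.6590688

dp <- mean_thickness(bil$frames, asg, bil$selection,
                     window = c(10 + 1e-6, 19), grid = 64)
round(dp, 4)
#>   mean     sd
#> 3.9300 0.0712

# planted 6/18/8 immobile/released/escaped probe mixture, recovered 32/32
rs  <- make_release_series(seed = 42)
cls <- classify_release(release_feature(rs$series), seed = 42)
cls
#> <release_classification> 32 molecules; centroids: 0.0516, 0.512, 2
#>
#> immobile released  escaped
#>        6       18        8
mean(as.character(cls$label) == rs$truth$classes)
#> [1] 1
```

The per-lipid areas scatter around the planted 0.64 nm² (their mean is
exactly `cell area / n` by conservation); the thickness summary recovers
the planted 3.93 nm; the release classifier recovers every planted label.

## Pipeline & CLI

```r
cfg <- pipeline_config(generator = list(kind = "descent",
                                        args = list(n_frames = 60)))
run_pipeline(cfg, "out/")   # maps, summary.csv, profiles, release.csv,
                            # manifest.json (seed, config hash, checksums)
```

or from the shell (after install):

```sh
Rscript inst/cli/membranemaps all --config cfg.json --out out/
```

Outputs are plain text and byte-reproducible for a fixed config + seed.

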