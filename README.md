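# brainfish

Quantification of single-molecule FISH (smFISH) in intact *Drosophila*
brains. Each mRNA appears as a diffraction-limited fluorescent spot in a
multi-channel 3D confocal stack; **brainfish** turns such stacks into
statistically controlled per-compartment transcript counts, and carries the
companion analyses of the same experiments: transcription-focus
characterization, bleach- and background-corrected fluorescent-protein
intensities, and skeleton/mesh-based dendritic morphometry from connectome
data. A ground-truthed synthetic scene generator makes every stage testable
without microscopy data.

Intended users: labs quantifying transcript abundance in genetically labeled
neurons (mushroom body output neurons being the motivating case), and anyone
who needs a spot caller with an explicit false-discovery-rate guarantee.

## The statistics at the core

**Detection.** At every interior voxel a generalized likelihood ratio test
compares, over the local ROI under Poisson noise,

- H0: constant background *b*, against
- H1: *b* + *a* · PSF, amplitude *a* ≥ 0,

where the PSF is a pixel-integrated 3D Gaussian with σ<sub>xy</sub> = 1.39 px
and σ<sub>z</sub> = 3.48 z-slices. The boundary constraint *a* ≥ 0 makes the
null distribution of T = 2(LL₁ − LL₀) the mixture ½χ²₀ + ½χ²₁, so
p = ½ P(χ²₁ ≥ T). Candidate molecule positions (local maxima of the
statistic field) are selected by the Benjamini–Hochberg step-up at
α = 0.05 across the full scanned-voxel family, then collapsed to one
detection per molecule.

**Refinement.** Each detection is re-fit on its 2D cross-section by Poisson
maximum likelihood (pixel-integrated Gaussian + background): subpixel x, y,
signal photons, background, and width σ<sub>xy</sub>, with
FWHM = 2√(2 ln 2) σ<sub>xy</sub>. Fits wider than 5 px are discarded.
Localization precision is verified against the Cramér–Rao bound of the same
likelihood.

**Masks.** Drawn compartment outlines become masks M1; dendrite masks M2
threshold the difference-of-Gaussians-enhanced membrane label:
M2 = (A∘M1) > mean(A∘M1) + std(A∘M1), with the sample (N−1) standard
deviation. Spots are counted per compartment by mask membership.

**Protein & morphometry.** YFP intensity: exponential depth-bleach
correction, 60 px rolling-ball background subtraction, central 11-slice
crop, adu/voxel inside the mask. Morphometry: compartment meshes (optionally
volume-scaled 1.35×), skeletons clipped to the mesh, capsule voxelization on
an 8 nm grid, postsynapse counts by point-in-mesh.

## Worked example

```r
library(brainfish)

# a ground-truthed scene: 40 spots (peak 300 photons/voxel over background
# 20) plus a dendrite-like membrane label
amp <- 300 / psf_center_fraction()
spots <- place_spots(40, c(20, 128, 128), photons = amp, margin = c(8, 7), seed = 22)
sc <- render_scene(scene_spec(
  shape = c(20, 128, 128), spots = spots, background = 20,
  dendrite = list(level = 150, width = 4, y0 = 64, amp = 10, period = 128),
  seed = 23
))

cfg <- run_config(
  sc$stack,
  smfish_channel = "smFISH", label_channel = "neuron",
  mask = list(name = "dendrite",
              vertices = rbind(c(20, 10), c(20, 118), c(108, 118), c(108, 10))),
  sample_id = "demo", seed = 23
)
run <- run_smfish_count(cfg)
run$counts
#> # A tibble: 1 × 5
#>   sample compartment n_detected n_kept n_colocalized
#>   <chr>  <chr>            <int>  <int>         <int>
#> 1 demo   dendrite            37     37             0
```

`n_detected` is the number of FDR-controlled detections in the stack (37 of
the 40 planted spots; the misses are pairs planted closer together than the
duplicate-suppression radius), `n_kept` the fits surviving the 5 px width
filter, and `n_colocalized` how many land on the dendrite mask M2 — here 0,
matching the ground truth: the spots were placed at random, and none fell on
the thin ribbon. `tidy(run)`, `glance(run)` and `autoplot()` on the spot
tables give the broom-style views; `run_report()` collates runs into one
tidy table. A thin command-line wrapper with `simulate` / `detect` /
`count` / `report` subcommands is at `inst/scripts/brainfish-cli.R`.

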