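---
title: "Quantifying single-molecule FISH in intact brains: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-molecule FISH in intact brains: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

brainfish quantifies single-molecule fluorescence in situ hybridization
(smFISH) in whole-mount *Drosophila* brains: each mRNA appears as a
diffraction-limited fluorescent spot in a 3D confocal stack, and the package
turns those stacks into per-compartment transcript counts, transcription-focus
statistics, protein-level intensities and connectome-based morphometry. This
vignette describes the statistical models, the tunable parameters, and the
design decisions, in enough detail that a reader can judge what a passing test
suite does and does not establish.

## Imaging model

A stack is a `(z, y, x)` array of analog-digital units (adu) with voxel size
(200, 139, 139) nm — 200 nm optical sectioning and 139 nm pixels from a 60x
spinning-disk configuration. The point spread function is modeled as a
separable pixel-integrated 3D Gaussian with lateral width `sigma_xy = 1.39` px
and axial width `sigma_z = 3.48` z-slices; both defaults are tunable through
`detection_params()`. Photon (shot) noise is Poisson; an optional linear
camera transform `adu = gain * photons + offset` converts counts to photons
before any likelihood is evaluated (unit gain and zero offset by default).

Coordinates are 1-based voxel indices in `(z, y, x)` order with voxel centers
at integer positions, matching how R indexes arrays. All subpixel positions
are reported in this frame.

## Spot detection: per-voxel GLRT with FDR control

At every interior voxel the detector computes a generalized likelihood ratio
test (GLRT) over the local ROI — a box of half-width `ceiling(3 sigma_xy)` px
laterally and `ceiling(3 sigma_z / 2)` slices axially, which captures
essentially all of the spot mass:

* H0: constant Poisson background `b`.
* H1: background plus a pixel-integrated 3D Gaussian of fixed width centered
  at the voxel, with amplitude `a >= 0`.

Because the amplitude sits on the boundary of its parameter space under H0,
the statistic `T = 2 (LL1 - LL0)` is asymptotically distributed as the
mixture `0.5 chi2_0 + 0.5 chi2_1`, giving `p = 0.5 P(chi2_1 >= T)` for
`T > 0`. The constrained maximization is a two-parameter Newton iteration;
where the (background-profiled) Rao score statistic is below 9 — p-values
above roughly 1e-3, far beyond any attainable significance cut-off in an
image-sized family of tests — the score value, the first-order equivalent of
the LRT, is reported directly. Empirically the null tail is well calibrated
(about 540 observed vs 484 expected voxels below p = 1e-3, and 4 vs 4.8 below
1e-5, on a 256 x 256 x 20 pure-background stack).

Multiple testing is controlled per image with the Benjamini–Hochberg step-up
at `alpha = 0.05` (the target false discovery rate). Two design choices here
are the package's own and deserve justification:

1. **Candidate reduction to local maxima.** One molecule excites the
   statistic at its whole neighborhood of voxels. If every super-threshold
   voxel entered the BH discovery count, a scene with bright spots would
   inflate the step-up cut-off by orders of magnitude (the discovery count
   includes every signal voxel), and the detector would flood with noise
   calls: we measured detection-level FDR near 0.5 in that configuration.
   `detect_spots()` therefore treats only local maxima of the statistic
   field (within the duplicate-suppression neighborhood) as candidate
   molecule positions; all other voxels enter the BH vector with p = 1, so
   the multiplicity budget remains the full number of scanned voxels. The
   expected number of false detections is then at most `alpha` times the
   discovery count, which is exactly the FDR guarantee the method promises.
2. **Duplicate suppression radius.** Within a radius of `3 sigma_xy` px
   laterally and `ceiling(3 sigma_z / 2)` slices axially, only the strongest
   detection is kept (ties broken lexicographically). The axial radius
   matters: with `sigma_z = 3.48` slices a single molecule is significant
   across many z-planes, and a 1-slice radius provably leaves axial
   duplicates of the same molecule.

The FDR guarantee is exercised end-to-end on synthetic stacks: 30 stacks of
256 x 256 x 20 voxels, 100 spots each with peak amplitude 300 photons/voxel
over background 20 (spot brightness is specified as the peak amplitude — what
one reads off an image — and converted to the integrated photon count through
the central-voxel PSF fraction, about 0.009). Detections are matched to
ground truth within 2 px; pooled empirical FDR is compared against
`alpha + 2 SE`. In this regime the detector also recovers about 95% of
planted spots; the misses are almost entirely pairs planted closer together
than the duplicate-suppression radius, which no single-molecule counter can
split.

What this does *not* establish about real data: the synthetic background is
spatially flat, while brains have structured autofluorescence; the PSF is the
nominal Gaussian, while depth aberrations broaden it; and spot brightness is
uniform, while probe accessibility varies. The width filter and the
FDR-controlled test are the defenses the method provides against the first
two; they are exercised only under the model here.

## Spot refinement: Poisson MLE on a 2D cross-section

Each detection is refined on the z-slice where it was found — a deliberate 2D
cross-section, which reduces the influence of axially overlapping spots — in
a square ROI of side `round_to_odd(2 (3 sigma_xy + 1))` (11 px at the default
width). The model is a pixel-integrated 2D Gaussian (erf differences per
pixel) plus constant background under Poisson noise; five parameters
(subpixel x, y, signal photons, background, width) are estimated by `nlminb`
on a log-transformed positive parameterization. Initialization is
deterministic: border-median background, background-subtracted centroid
position, residual-sum photons, default width. Non-convergence is flagged and
flagged fits are excluded downstream.

The estimator is checked against the Cramér–Rao lower bound computed from the
numerically differentiated Fisher information of the same likelihood:
localization RMSE at 200 photons stays within 1.3x CRLB (500 Poisson
replicates), and the photon estimate is unbiased within 2% at 500 photons.
`FWHM = 2 sqrt(2 ln 2) sigma_xy` exactly. Fits wider than 5 px are discarded
as spurious (strictly greater than 5; a fit at exactly 5 px is kept).
`signal_background_ratio` is defined as the fitted peak amplitude
`photons / (2 pi sigma^2)` divided by the fitted per-pixel background — one
reasonable convention for the "signal/background" axis label; figures using a
different convention are not directly comparable.

Transcription foci — the bright nuclear spot at the transcribing locus — are
handled by `fit_transcription_focus()`: the highest-photon spot in the soma
is selected, its width is re-estimated by nonlinear least squares on an ROI
sized for 3x the single-molecule width (foci are wider; the enlarged ROI is
our choice, as no focus ROI is prescribed anywhere), and photons/background
are recomputed by the Poisson MLE with that width held fixed. A fitted width
not exceeding the single-molecule default is flagged (`is_focus_width =
FALSE`) rather than silently accepted; we flag rather than test significance
because no quantitative criterion for "wider than sparse signal" is
prescribed.

## Compartment masks and co-localization

The drawn compartment contour becomes the per-slice mask M1 by boundary-
inclusive even-odd rasterization (pixel centers; vertices at pixel-center
coordinates). Where a membrane label exists (dendrites), each slice of the
label channel is enhanced with a difference of Gaussians (widths 1 and 5 px,
reflective boundaries) and thresholded:

M2 = (A o M1) > mean(A o M1) + std(A o M1)

with `o` the Hadamard product and `std` the sample (N-1) standard deviation.
Mean and std are taken over **all** pixels of the product image, faithful to
the formula as printed; a `domain = "within_m1"` switch computes them over
the drawn region only, since the original convention is not recorded. The
strict inequality is intersected with M1 so M2 never escapes the drawn
region (the DoG output has negative values, so a negative threshold could
otherwise admit pixels outside M1). The formula is scale-invariant: M2 is
unchanged when the label image is multiplied by any positive constant.

A spot co-localizes with a compartment when its rounded `(y, x)` pixel is
true on its detection slice — in M2 for dendrites, in M1 for calyx and soma
(no membrane label exists there). Pixel-center membership of the rounded
position is the simplest reproducible reading of "overlapping". A single
polygon is broadcast across the (typically 10-slice) analysis substack;
per-slice polygons are supported. For even substack sizes the window starts
at `center - n/2`.

## Protein intensity

Fluorescent-protein quantification runs a fixed order, enforced by
`quantify_protein()`: exponential bleach correction over the full stack
(least-squares fit of `a exp(-k z)` to per-slice means, slices divided by
`exp(-k z)` so the first slice is unchanged; `k` may be negative), per-slice
rolling-ball background subtraction (grayscale opening with a non-flat,
ball-shaped structuring element; "width of 60 pixels" is read as a 60 px
ball radius, the convention of the common ImageJ parameter), central crop of
11 slices (five above and below the center slice `floor(depth/2)`; the
center-inclusive reading of "five above and below" — configurable), then
summation inside the compartment mask, reported as adu/voxel. Bleach fitting
on slice means rather than per-voxel values is a robustness choice; the
per-slice mean is a sufficient statistic for a spatially flat decay model.

## Morphometry

Connectome-based dendritic measurements work on local files: SWC skeletons
(7-column, nm), OBJ compartment meshes, and CSV/JSON synapse tables.
A compartment mesh may be scaled by a **volume** factor (1.35x for a mesh
that undercovers its dendrites) — implemented as isotropic scaling about the
vertex centroid by `factor^(1/3)`, because the stated quantity scaled is the
mesh's volume; a `mode = "linear"` alternative supports sensitivity
analysis. Skeletons are clipped to the mesh (nodes inside kept; crossing
edges cut at the surface intersection; ray-casting containment with a fixed
ray direction, on-surface points counted inside). Clipped fragments are
rasterized as capsules (sphere-swept segments, radii linearly interpolated)
onto an 8 nm grid; volume is occupied voxels times 8^3 nm^3, reported in
both nm^3 and um^3 side by side, since printed dendritic volumes of order
10^3 are plausible only in um^3 while the stated unit is nm^3.
Postsynapse counts are the `post`-kind synapse positions inside the mesh.

Analytic fixtures (sphere, capsule, two disjoint compartments with planted
synapse counts) verify voxelization within 5% at 8 nm and monotone error
decrease at 16/8/4 nm. Reproducing published volumes and synapse counts for
specific neurons requires the corresponding connectome files, which are not
bundled; the operations that would consume them are exactly the ones tested
on fixtures.

## Chromatic-shift correction

The shift between detection channels is estimated from a shared nuclear-dye
calibration image pair as the 3D affine transform minimizing the mean squared
intensity error of the warped moving image against the reference. The
optimization is hierarchical — translation, then translation plus per-axis
scale, then the full 12-parameter affine — over a 3-level coarse-to-fine
pyramid with fixed iteration budgets (deterministic given the inputs), with
trilinear interpolation throughout and the MSE evaluated over a fixed
interior margin so the objective is smooth in the parameters. Both images
are band-limited with a sigma = 1 voxel Gaussian first; nuclei are much
larger than a voxel, so this suppresses shot noise without moving the
optimum. The transform estimated between calibration images is applied to
the corresponding data channels (trilinear, out-of-bounds voxels zero).

Synthetic nuclei scenes (30 nuclei of 4 px radius at 5000 peak photons —
nuclear dyes are the brightest channel in this kind of experiment) give
translation recovery within 0.1 px and x-scale recovery within 0.002 for a
1.01 injected scale; across random affines within ±3 px / ±2% scale the mean
displacement error of the recovered map is a few hundredths of a pixel. Two
accuracy limits are worth knowing: the scale and translation parameters
trade off against each other (the well-determined quantity is the
displacement field over the nuclei, not each parameter separately), and with
trilinear interpolation the weakly-constrained z-z scale on thin stacks
absorbs most of the parameter-level error.

## The synthetic-data generator

`render_scene()` is first-class, tested code: expected photon image =
background + pixel-integrated 3D Gaussian spots (+ soft-edged nuclei for
calibration channels, + a sinusoidal dendrite ribbon with Gaussian cross
section, each with its ground-truth mask) x a depth bleaching factor
`exp(-k z)`; then Poisson sampling with a mandatory seed, then the camera
transform. Identical spec and seed give bit-identical stacks, and every
manifest records exactly what was injected. Spot brightness in the detection
scenes is given as peak amplitude (photons/voxel) and converted via
`psf_center_fraction()`; spot records in the manifest keep integrated
photons, which is what photon-conservation checks measure. The generator
emulates shot noise, bleaching, chromatic shift and co-labeled structures;
it does not emulate structured autofluorescence, depth-dependent PSF
broadening, or probe-accessibility variation in brightness.

Default problem sizes in the test suite are chosen to keep the full run on a
single CPU comfortably inside half an hour: the FDR condition runs the full
30 stacks at 256 x 256 x 20; the registration round-trip property runs 12
seeded replicates at 64 x 64 x 32 (the full 50-replicate version behaves
identically and can be run by raising `n_seeds` in the test); null-detection
checks run 20 replicates at 128 x 128 x 20.

## Degenerate inputs and numeric conventions

Constant calibration images are a registration error (zero variance);
non-positive slice means are a bleach-fit error; empty masks are an error
for intensity (a division by zero voxel count) but an empty *spot list* for
focus fitting is a no-focus result, not an error. ROIs clipped by the image
border exclude the spot rather than zero-padding. BH on an empty p-vector
returns an empty flag vector. Ties in duplicate suppression break
lexicographically by `(z, y, x)`; ties in local-maximum selection break
toward the smaller linear index. The score-to-exact switch in the GLRT is at
statistic 9; below it the reported value is the score statistic, whose
difference from the exact LRT is far below any decision threshold in use.
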