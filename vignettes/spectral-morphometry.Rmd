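---
title: "Spectral morphometry of intrinsic-emission liver images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(specmorph)
```

## The problem

Multi-photon microscopy of unstained liver tissue records intrinsic emission
— autofluorescence from NADH, flavins, retinol and related fluorophores,
plus second-harmonic generation (SHG) from fibrillar collagen — as a
per-pixel emission spectrum (here 25 channels, 400–650 nm at 10 nm
bandwidth, 512 × 512 px). These spectra are mixtures of highly overlapping
fluorophore sources, so classical spectral unmixing is impractical: no
clean reference spectra exist for the endogenous species. `specmorph`
implements the alternative: *marker-controlled segmentation*. Instead of
separating sources, representative quantized spectra ("internal markers")
are learned from the images themselves and every pixel is assigned to its
nearest marker. The resulting label maps support mathematical-morphology
readouts of disease progression and a bag-of-features (BoF) image
classifier.

Four spectral object classes drive the analysis:

* **HP** — hepatic parenchyma: broad emission rising between 500 and
  650 nm (NADH/flavin autofluorescence).
* **SHG** — collagen fibrils: a sharp narrow peak at 525 nm, exactly half
  the 1050 nm excitation wavelength.
* **WD** — "white dot" vitamin-A (stellate-cell-associated) sites: broad
  emission across 400–650 nm.
* **RC** — bright red-cell-like objects appearing in fibrotic livers: the
  HP spectral shape at roughly three-fold amplitude.

## Pipeline

1. **Band reduction** (`band_reduce`): the cube is collapsed to three band
   images — shorter 400–500 nm, SHG 520–530 nm, longer 550–650 nm. A
   channel spans the half-open interval `[start + i·bw, start + (i+1)·bw)`
   and a band keeps the channels fully contained in it, which makes the
   three bands select exactly 10 / 1 / 10 channels. Bands are averaged, not
   summed, so band images stay on the 8-bit scale (the two differ only by a
   constant factor).
2. **Keypoint detection** (`detect_keypoints`): FAST-9 segment-test corners
   on each band image independently. The detector threshold defaults to 20
   (8-bit units); the arc length is 9, with non-maximum suppression on the
   summed absolute intensity excess. These are workflow choices — the
   method is robust to them because keypoints only seed the spectra pool.
3. **Spectra pooling** (`collect_spectra`, `pool_spectra`): at every
   keypoint the per-channel mean over a radius-2 discrete disk (13 px) is
   taken from the *original* cube. Pools from all bands and images are
   concatenated; duplicates are retained (harmless to k-means).
4. **Marker quantization** (`build_markers`): k-means (Euclidean, k-means++
   initialisation, best of 10 restarts, fixed seed) on the raw,
   un-normalised pooled spectra. No normalisation is applied deliberately:
   HP and RC share a spectral shape and differ chiefly by amplitude, so
   amplitude is informative. k = 4–20 is supported; k = 10 is the
   reference setting.
5. **Annotation** (`annotate_markers`): rule-based reading of each
   centroid's band structure — SHG if the SHG-band mean exceeds 2× the
   larger other-band mean; among the rest, WD if the shorter-band mean is
   at least 0.5× the longer-band mean; the remainder are split into HP/RC
   at the midpoint of their longer-band amplitudes, but only when those
   amplitudes span at least a factor 2. Two guards extend the basic rules:
   centroids with all band means below the low-signal threshold become
   `other`, and the HP/RC split is suppressed when no genuinely
   high-amplitude cluster exists. Without the second guard the midpoint
   rule invents RC markers in control images whose parenchyma merely varies
   in brightness. All thresholds are exposed as arguments.
6. **Segmentation** (`segment_image`): every pixel whose mean intensity
   over all channels exceeds 4 (the low-signal cut, on the 8-bit scale) is
   assigned to the nearest marker centroid; ties go to the lowest marker
   index; everything else is background. "Averaged over spectral bands" is
   read as the mean over all 25 channels, applied uniformly per pixel; the
   threshold is configurable.
7. **Morphometry** (`label_objects`, `morphometry_report`): per-class
   connected components (default 8-connectivity so diagonally touching
   fibril pixels stay one object; 4-connectivity available), a 2 px minimum
   object size to suppress single-pixel noise, object counts per unit
   signal area, mean areas, and mean centroid-to-centroid nearest-neighbour
   distances. Group differences are tested with the two-sample
   Kolmogorov–Smirnov test at alpha = 0.05. Two distinct denominators are
   implemented explicitly: per-class count/area ratios use the *total
   signal area*; the SHG area ratio of a maximum-intensity projection uses
   the *total image area*.
8. **BoF classification** (`cross_validate`): the segmentation map is cut
   into a `2^l × 2^l` grid of patches (l = 2–5 on 512 px images gives
   patch sides 128/64/32/16). Each patch becomes a marker histogram over
   its non-background pixels; all-background patches carry no evidence and
   are dropped. Training-fold patch features are quantized into a codebook
   of c visual words (c = 10–100); each image becomes an L1-normalised term
   vector of nearest-word counts (1-nearest-neighbour assignment, ties to
   the lowest index), classified by a linear SVM (one-vs-rest; default
   cost 100 — the cost must match the feature scale, and unit-L1 term
   vectors with entries of order 1/c need a cost of that magnitude to
   reproduce what cost 1 does on the equivalent raw count histograms).
   Folds are stratified with a fixed seed and the codebook is rebuilt
   inside every training fold, so no information leaks into the held-out
   fold. Accuracy is reported as the fold-averaged total accuracy plus
   fold-averaged per-class recalls (the pooled confusion matrix is also
   returned).

### Emission-filter simulation

`simulate_filter_channels` collapses a cube to the three channels a
bandpass-filter detector would record (417/60, 525/50, 617/73 nm;
fractional channel-overlap weighting, passbands clipped to the cube range,
dichroic edges beyond the passbands ignored). Rebuilding markers and
segmenting in this 3-channel space quantifies what the spectral detector
buys: the 50 nm-wide 525 filter dilutes the narrow SHG peak five-fold, so
fibrils overlying parenchyma become nearly indistinguishable from
parenchyma and the SHG overlap with the band-extraction reference map
collapses, while the full-spectrum segmentation keeps it above 98%.

## The phantom generator

No microscope data ship with the package; `generate_phantom` renders
synthetic liver fields with known ground truth, and all quantitative
claims in the test suite are claims about these phantoms:

* **Parenchyma**: an irregular hepatocyte mosaic (~16 px cells, per-cell
  brightness 0.75–1.25, darker intercellular borders) modulated by a
  smooth ±12% illumination field, carved by dark sinusoid channels
  (smooth random walks, ~5 px wide).
* **SHG fibrils**: low-curvature curves seeded on the sinusoid network,
  per-fibril brightness 0.6–1.0, drawn until a target pixel fraction is
  reached. Two morphologies occur: fine fibrils (~3 px) whose emission
  *adds* to the underlying parenchyma fluorescence — the mixed-pixel case
  that makes filter-based detection hard — and thicker septum-like bundles
  (~5 px) of dense scar that displace hepatocytes and carry no underlay.
* **WD sites**: 2–4 px-diameter dots (areas 4–12 px) lining the sinusoid
  channels, where stellate cells sit in the tissue.
* **RC objects**: bright disks at hepatocyte scale (mean area 300 px in
  the 2-week class, 700 px in the 4-week class), non-overlapping, with
  ~5 px granular internal texture so that — as with real cells — feature
  detectors sample their interiors and not only their rims.
* **Noise**: additive truncated Gaussian (sd 3 by default), chosen over
  Poisson for simplicity; intensities clipped to [0, 255].

Emission templates are smooth piecewise-linear curves with peak amplitudes
HP 60, RC 180, WD 80, SHG 200 on the 8-bit scale, preserving the ordering
relations observed in real spectra (RC brighter than HP with the same
shape; SHG single-channel; WD broad).

Class composition defaults (at 512 px, scaled by area for other sizes):
control 48 WD, no RC, 1% SHG; 2-week fibrosis 96 WD, 12 RC × 300 px, 5%
SHG; 4-week fibrosis identical except 30 RC × 700 px. The 2- and 4-week
classes therefore differ *only* in their red-cell-object load, which is
exactly the signature the morphometry and the classifier are supposed to
read out. Published images do not come with object-density tables, so the
absolute counts are package choices; only the orderings (more WD and RC in
disease, larger and more RC with progression, equal WD/SHG composition
across the two fibrosis grades) are treated as fixed constraints.

**What the phantoms do not emulate**: optical point-spread blur,
depth-dependent attenuation, Poisson photon statistics, partial-volume
mixing at object boundaries (objects are stamped with crisp edges), real
vascular topology, and any within-class biological variability beyond
object counts and brightness jitter. Passing tests therefore demonstrate
that the implementation is faithful and that the method behaves as
described under controlled conditions — not that the same accuracy would
be reached on real tissue.

## Numerical and design choices

* **12→8 bit**: `floor(v · 255/4095)` — monotone, exact at both ends; a
  bit-shift would map 4095 to 254.
* **k-means**: k-means++ seeding with explicit restarts and Lloyd
  iterations; assignment ties break to the lowest centroid index.
  Degenerate pools (fewer distinct spectra than clusters) raise an error
  rather than silently duplicating centroids.
* **Maximum-intensity projection** is computed per channel before any band
  reduction (the alternative — projecting band images — is not equivalent;
  the per-channel order is the one that preserves spectral maxima).
* **Overlap metric**: the symmetric intersection-over-union; a one-sided
  variant (`mode = "a_in"`) is provided because the underlying phrase
  "ratio of overlapping pixels to the total signal area" admits both
  readings.
* **Otsu binarization** (via EBImage) for the SHG band map and the MIP
  area ratio; a constant band yields an empty map with a warning rather
  than an arbitrary split.
* **Connected components** are computed over an igraph pixel-adjacency
  graph, which makes the 4- vs 8-connectivity choice explicit and testable
  against a flood-fill oracle.
* **Marker fidelity**: the package checks that each keypoint-pool centroid
  has a pixel-clustering counterpart with cosine similarity above 0.95.
  The check is directional because the two pools weight the classes very
  differently — signal pixels are ~95% parenchyma, so at k = 10 the pixel
  pool spends surplus centroids on parenchyma brightness shades while the
  keypoint pool refines object classes; a bijective matching would compare
  those surplus shades against each other and measure pool composition,
  not fidelity.
* **Codebook per fold**: the reference protocol does not say whether the
  codebook was global or per-fold; per-fold is implemented to avoid
  train/test leakage.
* **kNN code assignment**: "nearest code" is implemented as hard
  1-nearest-neighbour vector quantization; soft multi-neighbour assignment
  is out of scope.

## Problem sizes

The test suite exercises the full pipeline on 128–256 px phantoms with up
to 40 images per class; the acceptance script
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
runs the same computations at the full 512 px acquisition size with 10
phantoms for the segmentation-overlap comparison and 40 images per class
for the two classification experiments. These sizes are the package's
reference experiment definitions.

## Known limitations

* Marker annotation is heuristic; on data whose spectra violate the band
  structure assumed here (e.g. different fluorophore panels) the rules
  need re-parameterising.
* The BoF representation discards all spatial arrangement beyond the patch
  grid; spatial-pyramid or texture descriptors are deliberately out of
  scope.
* Filter-space segmentation quality depends strongly on how much fibril
  signal overlies parenchyma; on phantoms the degradation is stronger than
  the ~10-point drop reported for real tissue because phantom fibrils are
  thin and half their length crosses parenchyma.
* Watershed, soft assignment, and spectral unmixing are non-goals.
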