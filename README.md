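# specmorph

Marker-controlled segmentation and bag-of-features classification of
multi-photon intrinsic-emission spectral microscopy images, aimed at
label-free assessment of liver fibrosis.

## The problem

Unstained liver tissue imaged by multi-photon microscopy through a spectral
detector yields, at every pixel, a 25-channel emission spectrum
(400–650 nm, 10 nm bandwidth). That spectrum mixes autofluorescence from
NADH, flavins and retinol with second-harmonic generation (SHG) from
fibrillar collagen — overlapping sources with no usable reference spectra,
which rules out classical unmixing. `specmorph` takes the segmentation
route instead: representative quantized spectra (*internal markers*) are
learned from the images and every pixel is assigned to its nearest marker:

1. reduce each cube to three band images (shorter 400–500 nm, SHG
   520–530 nm, longer 550–650 nm);
2. detect FAST-9 corners on each band image and pool radius-2 disk-averaged
   spectra at those keypoints;
3. quantize the pool with k-means (k-means++ init, 10 restarts) into *k*
   markers, annotated as hepatic parenchyma (HP), collagen SHG, vitamin-A
   white dots (WD) or bright red-cell-like objects (RC);
4. assign each pixel with channel-mean intensity > 4 to its nearest marker
   (background otherwise) — the segmentation
   `labels(x) = argmin_j ||s(x) − c_j||`;
5. quantify the label maps: per-class object counts and areas, counts per
   unit signal area, nearest-neighbour distances, SHG area ratios of
   maximum-intensity projections, Kolmogorov–Smirnov group tests;
6. classify images with a bag-of-features pipeline: `2^l × 2^l` grid
   patches → marker histograms → k-means codebook of *c* visual words →
   L1-normalised term vectors → linear SVM, under stratified 4-fold
   cross-validation with per-fold codebooks.

Because no microscopy data ship with the package, a synthetic phantom
generator (`generate_phantom`) renders liver-like spectral images — mosaic
parenchyma cut by dark sinusoids, curvilinear SHG fibrils, sinusoid-lining
WD dots, cell-scale RC disks — with known ground-truth labels for three
classes: `control`, `fibrosis_2wk`, `fibrosis_4wk`.

## Worked example

```r
library(specmorph)

# a 2-week-fibrosis phantom with ground truth
ph  <- generate_phantom(phantom_spec("fibrosis_2wk", image_size = 256, seed = 5))

# markers from FAST-keypoint spectra, quantized and annotated
ms  <- annotate_markers(build_markers(pool_spectra(list(ph$image)), k = 10, seed = 1))
ms$annotations
#>  [1] "SHG" "RC"  "WD"  "WD"  "SHG" "HP"  "HP"  "RC"  "SHG" "WD"

seg <- segment_image(ph$image, ms)
seg
#> <segmentation_map> 256 x 256, k = 10, 2.9% background

# how well does marker segmentation recover the SHG band map?
overlap_ratio(band_shg_map(ph$image), seg, "SHG")
#> [1] 0.9968652

print(morphometry_report(seg), digits = 3)
#>   class n_objects count_ratio mean_area mean_nnd
#> 1    HP        12    1.89e-04      4944     28.8
#> 2   SHG        10    1.57e-04       318     40.5
#> 3    WD        24    3.77e-04         8     13.5
#> 4    RC         5    7.86e-05       182     33.5
```

The segmentation assigns every high-signal pixel to one of the ten
markers; the report counts the simply-connected objects of each annotated
class, their density per unit signal area, mean areas (px) and mean
nearest-neighbour distances (px). The overlap value says that 99.7%
(intersection over union) of the pixels
called SHG by direct 520–530 nm band thresholding are also called SHG by
the full marker-controlled segmentation. Collapsing the same cube to three
simulated emission-filter channels (`simulate_filter_channels`) and
repeating the procedure drops that agreement far below 90% — the
motivation for spectral detection.

Classification of a phantom dataset:

```r
ds   <- generate_dataset(list(control = phantom_spec("control"),
                              fibrosis_2wk = phantom_spec("fibrosis_2wk")),
                         n_per_class = 40, base_seed = 100, materialize = FALSE)
# segment each image with shared markers, then
cv <- cross_validate(segs, ds$manifest$class_label,
                     bof_config(l = 5, c = 50, folds = 4, seed = 1))
cv$total_accuracy      # fold-averaged total accuracy
cv$per_class           # fold-averaged per-class recalls
```

## Command line

A thin CLI over the package functions lives at `inst/cli/specmorph.R`:

```sh
Rscript inst/cli/specmorph.R phantom --class fibrosis_2wk --n 10 --seed 42 --out phantoms/
Rscript inst/cli/specmorph.R markers --images phantoms/ --k 10 --seed 1 --out markers.json
Rscript inst/cli/specmorph.R segment --image phantoms/cube_001.tif --markers markers.json --out seg.tif
Rscript inst/cli/specmorph.R morph   --seg seg.tif --out report.csv
```

See `vignettes/spectral-morphometry.Rmd` for the full method description,
parameter rationale, and the phantom generator's design and limitations.
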