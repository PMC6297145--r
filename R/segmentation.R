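#' Low-signal mask
#'
#' High-signal pixels are those whose intensity averaged over all spectral
#' channels exceeds `min_mean` (default 4 on the 8-bit scale); everything
#' else is treated as background in segmentation and morphometry. The total
#' signal area of an image is the number of high-signal pixels.
#'
#' @param img a [spectral_image] or [multiband_image].
#' @param min_mean threshold on the per-pixel channel mean.
#' @return Logical H x W matrix, `TRUE` where signal.
#' @export
signal_mask <- function(img, min_mean = 4) {
  a <- image_array(img)
  rowMeans(a, dims = 2) > min_mean
}

#' Marker-controlled segmentation
#'
#' Assigns the spectrum of every high-signal pixel to the nearest marker
#' centroid (Euclidean distance; ties go to the lowest marker index).
#' Low-signal pixels receive the background label 0. The partition is
#' exhaustive: background plus per-marker counts sum to H x W.
#'
#' @param img a [spectral_image] or [multiband_image]; channel count must
#'   equal the markers' channel count.
#' @param ms a [marker_set] (annotated or not).
#' @param min_mean low-signal threshold passed to [signal_mask()].
#' @return An object of class `segmentation_map`: `labels` (H x W integers
#'   in 0..k), `k`, and `annotations` copied from the marker set.
#' @export
segment_image <- function(img, ms, min_mean = 4) {
  a <- image_array(img)
  if (dim(a)[3] != ncol(ms$centroids))
    stop(sprintf("image has %d channels but markers have %d",
                 dim(a)[3], ncol(ms$centroids)))
  h <- dim(a)[1]; w <- dim(a)[2]
  X <- matrix(a, h * w, dim(a)[3])
  lab <- nearest_centroid(X, ms$centroids)
  lab[!signal_mask(img, min_mean)] <- 0L
  structure(list(labels = matrix(as.integer(lab), h, w), k = ms$k,
                 annotations = ms$annotations),
            class = "segmentation_map")
}

# nearest row of `centers` for each row of X; ties -> lowest index
nearest_centroid <- function(X, centers) {
  d2 <- -2 * X %*% t(centers)
  d2 <- sweep(d2, 2, rowSums(centers^2), "+")
  max.col(-d2, ties.method = "first")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d x %d, k = %d, %.1f%% background\n",
              nrow(x$labels), ncol(x$labels), x$k,
              100 * mean(x$labels == 0)))
  invisible(x)
}

#' Emission filter bank of the three-detector configuration
#'
#' Bandpass intervals, given as centre/width pairs 417/60, 525/50 and
#' 617/73 nm: `[387, 447]`, `[500, 550]` and `[580.5, 653.5]` nm. Intervals
#' are clipped to the cube's wavelength range when applied.
#'
#' @return An object of class `filter_bank` (named list of intervals, in
#'   shorter / SHG / longer order).
#' @export
default_filter_bank <- function() {
  structure(list(shorter = c(387, 447), SHG = c(500, 550),
                 longer = c(580.5, 653.5)),
            class = "filter_bank")
}

#' Simulate three-channel emission-filter acquisition
#'
#' Collapses a spectral cube to the three channels a filter-based detector
#' would record: each output channel is the fractional-overlap-weighted mean
#' of the spectral channels intersecting the filter passband.
#'
#' @param img a [spectral_image].
#' @param fb a [default_filter_bank()]-style filter bank.
#' @return An object of class `multiband_image` (`data`: H x W x 3,
#'   `band_names`: shorter/SHG/longer) that can be fed back into the
#'   marker-construction and segmentation pipeline.
#' @export
simulate_filter_channels <- function(img, fb = default_filter_bank()) {
  stopifnot(inherits(img, "spectral_image"))
  d <- dim(img$data)
  lo <- img$wavelength_start + (seq_len(d[3]) - 1) * img$bandwidth
  hi <- lo + img$bandwidth
  rng <- c(min(lo), max(hi))
  planes <- lapply(fb, function(pb) {
    pb <- c(max(pb[1], rng[1]), min(pb[2], rng[2]))
    if (pb[2] <= pb[1]) stop("filter passband lies outside the cube's range")
    wts <- pmax(0, pmin(hi, pb[2]) - pmax(lo, pb[1])) / img$bandwidth
    if (sum(wts) == 0) stop("filter passband selects no spectral channel")
    X <- matrix(img$data, d[1] * d[2], d[3])
    matrix(X %*% wts / sum(wts), d[1], d[2])
  })
  structure(list(data = array(unlist(planes), dim = c(d[1], d[2], 3)),
                 band_names = names(fb)),
            class = "multiband_image")
}

# pixels of a segmentation map (or a plain logical mask) belonging to a class
class_mask <- function(x, label_class) {
  if (is.logical(x)) return(x)
  if (is.matrix(x) && !inherits(x, "segmentation_map")) return(x > 0)
  stopifnot(inherits(x, "segmentation_map"))
  if (is.null(x$annotations)) stop("segmentation map carries no annotations")
  sel <- which(x$annotations == label_class)
  if (length(sel) == 0) return(x$labels < 0)      # all FALSE
  matrix(x$labels %in% sel, nrow(x$labels), ncol(x$labels))
}

#' Segmentation agreement for one marker class
#'
#' Compares the pixel sets carrying a given class annotation in two
#' segmentations (or binary maps). The default metric is the symmetric
#' intersection-over-union; `mode = "a_in"` gives the one-sided variant
#' `|A intersect B| / |A|`.
#'
#' @param a,b [segmentation_map]s or logical matrices of equal shape.
#' @param label_class marker annotation to compare (default `"SHG"`).
#' @param mode `"iou"` (default) or `"a_in"`.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) when both maps are
#'   empty for the class.
#' @export
overlap_ratio <- function(a, b, label_class = "SHG", mode = c("iou", "a_in")) {
  mode <- match.arg(mode)
  ma <- class_mask(a, label_class); mb <- class_mask(b, label_class)
  if (!identical(dim(ma), dim(mb))) stop("maps differ in shape")
  inter <- sum(ma & mb)
  denom <- if (mode == "iou") sum(ma | mb) else sum(ma)
  if (denom == 0) {
    warning("no pixels of class '", label_class, "' in the compared maps")
    return(NA_real_)
  }
  inter / denom
}

#' Reference SHG map by spectral-band extraction
#'
#' Binarizes the SHG band (520-530 nm) plane of a spectral cube with Otsu's
#' threshold, restricted to high-signal pixels. This is the band-extraction
#' reference against which marker-controlled segmentations are scored.
#'
#' @param img a [spectral_image].
#' @param bands [band_set] providing the `SHG` band.
#' @param min_mean low-signal threshold.
#' @return Logical H x W matrix.
#' @export
band_shg_map <- function(img, bands = default_band_set(), min_mean = 4) {
  r <- band_reduce(img, bands)
  plane <- r[, , "SHG"]
  if (max(plane) <= min(plane)) {
    warning("constant SHG band; returning an empty map")
    return(plane > Inf)
  }
  thr <- otsu_threshold(plane)
  (plane > thr) & signal_mask(img, min_mean)
}

# Otsu threshold on an 8-bit-scale matrix, returned on the input scale
otsu_threshold <- function(plane) {
  EBImage::otsu(EBImage::Image(plane / 255), range = c(0, 1), levels = 256) * 255
}

#' Write a segmentation map as a label TIFF plus JSON legend
#'
#' @param seg a [segmentation_map].
#' @param path output TIFF path; the legend goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  tiff::writeTIFF(seg$labels / 255, path, bits.per.sample = 8,
                  compression = "none")
  legend <- list(k = seg$k, annotations = seg$annotations,
                 colors = c(HP = "yellow", SHG = "green", WD = "white",
                            RC = "red", other = "gray"))
  jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  lab <- round(tiff::readTIFF(path, as.is = TRUE))
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(labels = matrix(as.integer(lab), nrow(lab), ncol(lab)),
                 k = j$k, annotations = j$annotations),
            class = "segmentation_map")
}
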