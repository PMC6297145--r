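# 16-pixel Bresenham circle of radius 3, in circular order (dy, dx)
fast_circle <- cbind(
  dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3),
  dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1))

# rows of an N x 16 logical matrix with a circular run of >= arc TRUEs
circ_run_at_least <- function(m, arc) {
  run <- numeric(nrow(m)); hit <- logical(nrow(m))
  for (j in c(seq_len(16), seq_len(arc - 1))) {
    run <- (run + 1) * m[, j]
    hit <- hit | run >= arc
  }
  hit
}

#' FAST-9 corner detection on a single-band image
#'
#' Segment-test corners: a pixel is a corner when at least `arc` contiguous
#' pixels on its 16-pixel Bresenham circle are all brighter than the centre
#' by more than `threshold`, or all darker. Non-maximum suppression keeps
#' local maxima of the summed absolute intensity excess over the circle.
#' Detected points are at least 3 px from the image border.
#'
#' @param band_image numeric matrix (8-bit single-band image).
#' @param threshold segment-test intensity threshold (default 20).
#' @param arc required contiguous arc length (default 9, "FAST-9").
#' @param nms apply 3 x 3 non-maximum suppression (default `TRUE`).
#' @return Integer matrix with columns `y`, `x` (1-based row/col indices)
#'   and an attribute `score`.
#' @export
detect_keypoints <- function(band_image, threshold = 20, arc = 9, nms = TRUE) {
  h <- nrow(band_image); w <- ncol(band_image)
  if (is.null(h) || h < 7 || w < 7) stop("image must be at least 7 x 7")
  rows <- 4:(h - 3); cols <- 4:(w - 3)
  idx <- as.vector(outer(rows, (cols - 1L) * h, "+"))
  v <- band_image[idx]
  # compass prefilter: a contiguous arc of length `arc` must contain at least
  # floor(arc/4) of the 4 compass points (circle positions 1, 5, 9, 13)
  comp <- c(1L, 5L, 9L, 13L)
  req <- max(1L, arc %/% 4L)
  nb <- 0L; nd <- 0L
  for (j in comp) {
    s <- band_image[idx + fast_circle[j, 1] + fast_circle[j, 2] * h]
    nb <- nb + (s > v + threshold)
    nd <- nd + (s < v - threshold)
  }
  cand <- which(nb >= req | nd >= req)
  if (length(cand) == 0)
    return(structure(matrix(integer(0), 0, 2, dimnames = list(NULL, c("y", "x"))),
                     score = numeric(0)))
  ci <- idx[cand]; cv <- v[cand]
  nbr <- matrix(0, length(ci), 16)
  for (j in 1:16)
    nbr[, j] <- band_image[ci + fast_circle[j, 1] + fast_circle[j, 2] * h]
  is_corner <- circ_run_at_least(nbr > cv + threshold, arc) |
    circ_run_at_least(nbr < cv - threshold, arc)
  keep <- cand[is_corner]
  adiff <- abs(nbr[is_corner, , drop = FALSE] - cv[is_corner]) - threshold
  adiff[adiff < 0] <- 0
  score <- numeric(length(idx))
  score[keep] <- rowSums(adiff)
  if (length(keep) == 0)
    return(structure(matrix(integer(0), 0, 2, dimnames = list(NULL, c("y", "x"))),
                     score = numeric(0)))
  if (nms) {
    smat <- matrix(-Inf, h, w)
    smat[idx[keep]] <- score[keep]
    ok <- rep(TRUE, length(keep))
    p <- idx[keep]
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      q <- p + dy + dx * h
      sp <- smat[p]; sq <- smat[q]
      ok <- ok & (sp > sq | (sp == sq & p < q))
    }
    keep <- keep[ok]
  }
  p <- idx[keep]
  structure(cbind(y = (p - 1L) %% h + 1L, x = (p - 1L) %/% h + 1L),
            score = score[keep])
}

# generic accessors working for spectral and filter-simulated images
image_array <- function(x) {
  if (inherits(x, "spectral_image") || inherits(x, "multiband_image")) x$data
  else stop("expected a spectral_image or multiband_image")
}

# named list of single-band matrices used for keypoint detection
image_band_planes <- function(x, bands = default_band_set()) {
  if (inherits(x, "spectral_image")) {
    r <- band_reduce(x, bands)
    stats::setNames(lapply(seq_len(dim(r)[3]), function(i) r[, , i]),
                    dimnames(r)[[3]])
  } else if (inherits(x, "multiband_image")) {
    stats::setNames(lapply(seq_len(dim(x$data)[3]), function(i) x$data[, , i]),
                    x$band_names)
  } else stop("expected a spectral_image or multiband_image")
}

#' Collect disk-averaged spectra at keypoint locations
#'
#' Each pooled spectrum is the per-channel mean over a discrete disk
#' (default radius 2 px) centred on the keypoint, clipped at image borders.
#'
#' @param img a [spectral_image] or [multiband_image].
#' @param points integer matrix with columns `y`, `x`.
#' @param radius disk radius in pixels (default 2; 0 yields raw pixel spectra).
#' @param source optional tag recorded in the provenance (e.g. band name).
#' @return An object of class `spectra_pool`: `spectra` (N x C matrix),
#'   `provenance` (data.frame `y`, `x`, `source`) and the image's channel
#'   semantics (`calibration` or `band_names`).
#' @export
collect_spectra <- function(img, points, radius = 2, source = NA_character_) {
  a <- image_array(img)
  h <- dim(a)[1]; w <- dim(a)[2]; nc <- dim(a)[3]
  points <- matrix(as.integer(points), ncol = 2,
                   dimnames = list(NULL, c("y", "x")))
  if (nrow(points) > 0 &&
      (any(points[, 1] < 1 | points[, 1] > h | points[, 2] < 1 | points[, 2] > w)))
    stop("keypoint outside the image")
  X <- matrix(a, h * w, nc)
  acc <- matrix(0, nrow(points), nc)
  cnt <- numeric(nrow(points))
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2 + 1e-9, ]
  for (j in seq_len(nrow(offs))) {
    yy <- points[, 1] + offs$dy[j]; xx <- points[, 2] + offs$dx[j]
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    if (!any(ok)) next
    acc[ok, ] <- acc[ok, ] + X[(xx[ok] - 1L) * h + yy[ok], , drop = FALSE]
    cnt[ok] <- cnt[ok] + 1
  }
  structure(list(
    spectra = acc / pmax(cnt, 1),
    provenance = data.frame(y = points[, 1], x = points[, 2], source = source),
    calibration = if (inherits(img, "spectral_image"))
      list(wavelength_start = img$wavelength_start, bandwidth = img$bandwidth),
    band_names = if (inherits(img, "multiband_image")) img$band_names),
    class = "spectra_pool")
}

#' Pool keypoint spectra across images and bands
#'
#' Runs the full marker-selection front end on a set of images: reduce each
#' image to band planes, detect FAST keypoints on every plane independently,
#' collect disk-averaged spectra from the original cube at those points, and
#' concatenate everything into one pool (duplicates across bands retained).
#'
#' @param images list of [spectral_image] or [multiband_image] objects.
#' @param bands [band_set] used for the reduction (spectral input only).
#' @param threshold FAST threshold.
#' @param radius pooling disk radius.
#' @return A `spectra_pool`.
#' @export
pool_spectra <- function(images, bands = default_band_set(), threshold = 20,
                         radius = 2) {
  pools <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    planes <- image_band_planes(img, bands)
    for (bn in names(planes)) {
      kp <- detect_keypoints(planes[[bn]], threshold = threshold)
      if (nrow(kp) == 0) next
      p <- collect_spectra(img, kp, radius = radius, source = bn)
      p$provenance$image <- i
      pools[[length(pools) + 1]] <- p
    }
  }
  if (length(pools) == 0) stop("no keypoints detected in any image")
  out <- pools[[1]]
  out$spectra <- do.call(rbind, lapply(pools, `[[`, "spectra"))
  out$provenance <- do.call(rbind, lapply(pools, `[[`, "provenance"))
  out
}

# k-means++ initialisation + Lloyd iterations, best of `nstart` restarts.
# Assumes the RNG state has been set by the caller.
kmeans_pp <- function(X, k, nstart = 10, iter.max = 100) {
  n <- nrow(X)
  if (n < k) stop("fewer rows than clusters")
  if (nrow(unique(X)) < k)
    stop("fewer distinct spectra than clusters (degenerate input)")
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- matrix(0, k, ncol(X))
    i1 <- sample.int(n, 1)
    centers[1, ] <- X[i1, ]
    d2 <- rowSums((X - rep(centers[1, ], each = n))^2)
    for (j in seq_len(k - 1) + 1) {
      if (sum(d2) <= 0) pick <- sample.int(n, 1)
      else pick <- sample.int(n, 1, prob = d2)
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums((X - rep(centers[j, ], each = n))^2))
    }
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers, iter.max = iter.max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  best
}

#' Build spectral markers by k-means quantization of a spectra pool
#'
#' Centroids are computed on raw, un-normalised spectra with the Euclidean
#' metric (intensity differences are informative: HP and RC differ chiefly
#' by amplitude), using k-means++ initialisation and the best of `nstart`
#' restarts; deterministic given `seed`.
#'
#' @param pool a `spectra_pool` (or plain numeric matrix of spectra).
#' @param k number of markers; the workflow supports k = 4-20.
#' @param seed RNG seed.
#' @param nstart restarts (default 10).
#' @return An object of class `marker_set` with `centroids` (k x C), `k`,
#'   `seed`, channel semantics, and `annotations` (filled by
#'   [annotate_markers()]).
#' @export
build_markers <- function(pool, k, seed = 1, nstart = 10) {
  X <- if (inherits(pool, "spectra_pool")) pool$spectra else as.matrix(pool)
  if (nrow(X) < k) stop("pool holds fewer spectra than the requested k")
  km <- withr::with_seed(seed, kmeans_pp(X, k, nstart = nstart))
  structure(list(
    centroids = unname(km$centers), k = k, seed = seed,
    annotations = NULL,
    calibration = if (inherits(pool, "spectra_pool")) pool$calibration,
    band_names = if (inherits(pool, "spectra_pool")) pool$band_names),
    class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> k = %d, %d channels", x$k, ncol(x$centroids)))
  if (!is.null(x$annotations))
    cat(" [", paste(x$annotations, collapse = " "), "]")
  cat("\n"); invisible(x)
}

# per-centroid mean intensity within each named band
centroid_band_means <- function(ms, bands = default_band_set()) {
  C <- ms$centroids
  if (!is.null(ms$band_names)) {
    bm <- C[, match(names(bands), ms$band_names), drop = FALSE]
  } else {
    cal <- ms$calibration %||% list(wavelength_start = 400, bandwidth = 10)
    bm <- sapply(bands, function(b) {
      ch <- band_channels(cal$wavelength_start, cal$bandwidth, ncol(C), b)
      if (length(ch) == 0) stop("band selects no channel of the markers")
      rowMeans(C[, ch, drop = FALSE])
    })
    bm <- matrix(bm, nrow = nrow(C))
  }
  colnames(bm) <- names(bands)
  bm
}

#' Annotate markers with semantic component labels
#'
#' Rule-based interpretation of the quantized spectra, mirroring how the
#' marker profiles are read off their band structure:
#' * `SHG` - the SHG-band mean exceeds `shg_ratio` times the larger of the
#'   other two band means (sharp narrow peak);
#' * `WD` - among the rest, the shorter-band mean is at least `wd_ratio`
#'   times the longer-band mean (broad spectrum);
#' * remaining centroids are longer-wavelength skewed; when their
#'   longer-band amplitudes span at least a factor `rc_ratio` they are split
#'   at the midpoint between the lowest and highest amplitude into `HP`
#'   (low) and `RC` (high), otherwise all are `HP`;
#' * a centroid whose every band mean falls below `min_signal` is `other`.
#'
#' All thresholds are workflow heuristics and exposed as arguments.
#'
#' @param ms a [marker_set].
#' @param bands [band_set] defining shorter/SHG/longer (names must include
#'   `"shorter"`, `"SHG"`, `"longer"`).
#' @param shg_ratio,wd_ratio,rc_ratio,min_signal annotation thresholds.
#' @return The marker set with `annotations` filled.
#' @export
annotate_markers <- function(ms, bands = default_band_set(), shg_ratio = 2,
                             wd_ratio = 0.5, rc_ratio = 2, min_signal = 4) {
  bm <- centroid_band_means(ms, bands)
  sh <- bm[, "shorter"]; sg <- bm[, "SHG"]; lg <- bm[, "longer"]
  ann <- rep("other", nrow(bm))
  live <- pmax(sh, sg, lg) >= min_signal
  is_shg <- live & sg > shg_ratio * pmax(sh, lg)
  ann[is_shg] <- "SHG"
  rest <- live & !is_shg
  is_wd <- rest & sh >= wd_ratio * lg
  ann[is_wd] <- "WD"
  rem <- which(rest & !is_wd)
  if (length(rem) > 0) {
    amp <- lg[rem]
    if (length(rem) > 1 && max(amp) >= rc_ratio * min(amp)) {
      mid <- (min(amp) + max(amp)) / 2
      ann[rem] <- ifelse(amp > mid, "RC", "HP")
    } else ann[rem] <- "HP"
  }
  ms$annotations <- ann
  ms
}

#' Serialize a marker set to JSON / read it back
#'
#' @param ms a [marker_set].
#' @param path output JSON path.
#' @return `path` invisibly; `read_marker_set()` returns a [marker_set].
#' @export
write_marker_set <- function(ms, path) {
  jsonlite::write_json(
    list(centroids = ms$centroids, k = ms$k, seed = ms$seed,
         annotations = ms$annotations, calibration = ms$calibration,
         band_names = ms$band_names),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_marker_set
#' @export
read_marker_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- j$centroids
  if (!is.matrix(cent)) cent <- matrix(unlist(cent), nrow = j$k, byrow = TRUE)
  structure(list(centroids = cent,
                 k = j$k, seed = j$seed,
                 annotations = j$annotations,
                 calibration = j$calibration, band_names = j$band_names),
            class = "marker_set")
}
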