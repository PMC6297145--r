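#' Connected components of one marker class
#'
#' Extracts the simply-connected objects of a class from a segmentation map.
#' Connectivity defaults to 8 (diagonally touching pixels belong to the same
#' object, appropriate for thin fibrils); components smaller than
#' `min_object_size` pixels are discarded as single-pixel noise.
#'
#' @param seg a [segmentation_map], or a logical matrix treated directly as
#'   the object mask.
#' @param marker_class class annotation (ignored for logical input).
#' @param connectivity 4 or 8.
#' @param min_object_size minimum object area in px (default 2).
#' @return A `component_table`: data.frame with columns `object`, `class`,
#'   `area`, `centroid_y`, `centroid_x`.
#' @export
label_objects <- function(seg, marker_class = "RC", connectivity = 8,
                          min_object_size = 2) {
  if (inherits(seg, "segmentation_map") &&
      !marker_class %in% c(seg$annotations, "signal"))
    stop("unknown marker class: ", marker_class)
  mask <- if (is.logical(seg)) seg
    else if (identical(marker_class, "signal")) seg$labels > 0
    else class_mask(seg, marker_class)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  memb <- connected_components(mask, connectivity)
  empty <- data.frame(object = integer(0), class = character(0),
                      area = integer(0), centroid_y = numeric(0),
                      centroid_x = numeric(0))
  class(empty) <- c("component_table", "data.frame")
  if (length(memb$sizes) == 0) return(empty)
  keep <- which(memb$sizes >= min_object_size)
  if (length(keep) == 0) return(empty)
  idx <- which(mask)
  h <- nrow(mask)
  yy <- (idx - 1L) %% h + 1L; xx <- (idx - 1L) %/% h + 1L
  cy <- rowsum(as.numeric(yy), memb$membership)[, 1] / memb$sizes
  cx <- rowsum(as.numeric(xx), memb$membership)[, 1] / memb$sizes
  out <- data.frame(object = seq_along(keep),
                    class = if (is.logical(seg)) "mask" else marker_class,
                    area = memb$sizes[keep],
                    centroid_y = cy[keep], centroid_x = cx[keep])
  class(out) <- c("component_table", "data.frame")
  out
}

# connected components of a logical matrix via an igraph pixel-adjacency graph
connected_components <- function(mask, connectivity = 8) {
  idx <- which(mask)
  if (length(idx) == 0)
    return(list(membership = integer(0), sizes = integer(0)))
  h <- nrow(mask); w <- ncol(mask)
  fmap <- integer(h * w); fmap[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  yy <- (idx - 1L) %% h + 1L; xx <- (idx - 1L) %/% h + 1L
  for (o in offs) {
    y2 <- yy + o[1]; x2 <- xx + o[2]
    ok <- y2 >= 1L & y2 <= h & x2 <= w
    j <- (x2[ok] - 1L) * h + y2[ok]
    ok2 <- mask[j]
    edges[[length(edges) + 1]] <- cbind(fmap[idx[ok]][ok2], fmap[j[ok2]])
  }
  el <- do.call(rbind, edges)
  g <- if (is.null(el) || nrow(el) == 0)
    igraph::make_empty_graph(length(idx), directed = FALSE)
  else igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(membership = comp$membership, sizes = as.integer(comp$csize))
}

#' Object count per unit signal area
#'
#' @param ct a `component_table` from [label_objects()].
#' @param total_signal_area number of high-signal pixels in the image.
#' @return `nrow(ct) / total_signal_area`.
#' @export
count_ratio <- function(ct, total_signal_area) {
  if (total_signal_area <= 0) stop("total signal area must be positive")
  nrow(ct) / total_signal_area
}

#' Mean nearest-neighbour distance between objects
#'
#' For each object, the Euclidean distance from its centroid to the centroid
#' of the closest other object; averaged over objects. Smaller values mean
#' denser, locally accumulated objects.
#'
#' @param ct a `component_table` with at least two objects.
#' @return Mean nearest-neighbour distance in pixels.
#' @export
mean_nearest_neighbor_distance <- function(ct) {
  if (nrow(ct) < 2) stop("nearest-neighbour distance needs at least 2 objects")
  d <- as.matrix(stats::dist(cbind(ct$centroid_y, ct$centroid_x)))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' SHG area ratio of a maximum-intensity projection
#'
#' Binarizes the SHG band plane (default: Otsu's threshold) and returns the
#' fraction of foreground pixels relative to the total image area — the
#' collagen-deposition readout computed on MIP images.
#'
#' @param mip a [spectral_image] (typically from
#'   [max_intensity_projection()]).
#' @param bands [band_set] providing the `SHG` band.
#' @param threshold `"otsu"` or a fixed numeric cutoff on the 8-bit scale.
#' @return Fraction in `[0, 1]`.
#' @export
shg_area_ratio <- function(mip, bands = default_band_set(),
                           threshold = "otsu") {
  r <- band_reduce(mip, bands)
  plane <- r[, , "SHG"]
  if (identical(threshold, "otsu")) {
    if (max(plane) <= min(plane)) {
      warning("constant SHG band; area ratio is 0")
      return(0)
    }
    threshold <- otsu_threshold(plane)
  }
  sum(plane > threshold) / length(plane)
}

#' Two-sample Kolmogorov-Smirnov group comparison
#'
#' Two-sided two-sample KS test on a morphometric readout measured in two
#' groups of images, with a significance flag at alpha = 0.05.
#'
#' @param samples_a,samples_b numeric vectors (non-empty).
#' @return list with `statistic` (D), `p.value`, and `significant`.
#' @export
compare_groups <- function(samples_a, samples_b) {
  if (length(samples_a) == 0 || length(samples_b) == 0)
    stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(samples_a, samples_b,
                                        alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       significant = kt$p.value < 0.05)
}

#' Morphometry report for one segmented image
#'
#' Per-class object counts, count-per-signal-area ratios, mean areas and
#' mean nearest-neighbour distances, plus the total signal area.
#'
#' @param seg a [segmentation_map].
#' @param classes annotations to report (default HP/SHG/WD/RC).
#' @param connectivity,min_object_size passed to [label_objects()].
#' @return data.frame, one row per class, with attribute
#'   `total_signal_area`.
#' @export
morphometry_report <- function(seg, classes = c("HP", "SHG", "WD", "RC"),
                               connectivity = 8, min_object_size = 2) {
  classes <- intersect(classes, seg$annotations)
  tsa <- sum(seg$labels > 0)
  rows <- lapply(classes, function(cl) {
    ct <- label_objects(seg, cl, connectivity, min_object_size)
    data.frame(class = cl, n_objects = nrow(ct),
               count_ratio = if (tsa > 0) nrow(ct) / tsa else NA_real_,
               mean_area = if (nrow(ct) > 0) mean(ct$area) else NA_real_,
               mean_nnd = if (nrow(ct) >= 2)
                 mean_nearest_neighbor_distance(ct) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "total_signal_area") <- tsa
  out
}
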