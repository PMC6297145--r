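#' Bag-of-features configuration
#'
#' The classifier's tunables: division level `l` (the image is cut into
#' `2^l x 2^l` non-overlapping square patches; for 512 px images l = 2..5
#' gives patch sides 128/64/32/16), codebook size `c`, number of
#' cross-validation folds (4 reproduces the reference protocol), marker
#' annotations to exclude from the features (e.g. `"SHG"`), the linear-SVM
#' cost, and the seed driving fold assignment and codebook clustering.
#'
#' @param l division level.
#' @param c codebook size (visual-word count).
#' @param folds cross-validation folds.
#' @param exclude character vector of marker annotations to drop.
#' @param cost SVM regularisation constant (default 100, calibrated to
#'   unit-L1 term vectors whose entries are O(1/c); on raw count histograms
#'   this corresponds to a modest penalty).
#' @param seed RNG seed.
#' @param nstart k-means restarts for codebook construction.
#' @return An object of class `bof_config`.
#' @export
bof_config <- function(l = 5, c = 50, folds = 4, exclude = character(),
                       cost = 100, seed = 1, nstart = 5) {
  stopifnot(l >= 1, c >= 1, folds >= 2)
  structure(list(l = l, c = c, folds = folds, exclude = exclude,
                 cost = cost, seed = seed, nstart = nstart),
            class = "bof_config")
}

#' Patch side length at a division level
#'
#' @param image_side image side in pixels.
#' @param l division level; `2^l` must divide `image_side`.
#' @return Side length of one patch in pixels.
#' @export
patch_side <- function(image_side, l) {
  if (image_side %% 2^l != 0)
    stop(sprintf("image side %d is not divisible by 2^%d", image_side, l))
  image_side %/% 2^l
}

# patch id (row-major over the 2^l x 2^l grid) for every pixel
patch_index <- function(h, w, l) {
  sy <- patch_side(h, l); sx <- patch_side(w, l)
  iy <- (seq_len(h) - 1L) %/% sy          # 0-based block row
  ix <- (seq_len(w) - 1L) %/% sx
  outer(iy, ix, function(a, b) a * (2L^l) + b + 1L)
}

#' Split a label image into grid patches
#'
#' Non-overlapping `2^l x 2^l` grid of square patches, returned in row-major
#' order; reassembling the list in order reproduces the input bit-exactly.
#'
#' @param seg a [segmentation_map] or plain matrix; side divisible by `2^l`.
#' @param l division level.
#' @return list of `4^l` label matrices.
#' @export
grid_patches <- function(seg, l) {
  m <- if (inherits(seg, "segmentation_map")) seg$labels else seg
  sy <- patch_side(nrow(m), l); sx <- patch_side(ncol(m), l)
  g <- 2L^l
  out <- vector("list", g * g)
  for (i in seq_len(g)) for (j in seq_len(g))
    out[[(i - 1L) * g + j]] <-
      m[((i - 1L) * sy + 1L):(i * sy), ((j - 1L) * sx + 1L):(j * sx),
        drop = FALSE]
  out
}

#' Marker histogram of one patch
#'
#' Relative frequency of markers 1..k among the non-background pixels of a
#' patch. An all-background patch carries no marker evidence and is flagged
#' empty (`NA` vector with attribute `empty = TRUE`).
#'
#' @param patch integer label matrix with values in 0..k.
#' @param k marker count.
#' @return Numeric k-vector summing to 1, or `NA`s for an empty patch.
#' @export
patch_feature <- function(patch, k) {
  nz <- patch[patch > 0]
  if (length(nz) == 0)
    return(structure(rep(NA_real_, k), empty = TRUE))
  structure(tabulate(nz, nbins = k) / length(nz), empty = FALSE)
}

#' Marker histograms for every patch of an image
#'
#' Vectorised equivalent of applying [patch_feature()] to each element of
#' [grid_patches()], in the same row-major order.
#'
#' @param seg a [segmentation_map].
#' @param l division level.
#' @param k marker count (default taken from `seg`).
#' @return `4^l x k` matrix of L1-normalised histograms; empty patches are
#'   `NA` rows, flagged in the logical attribute `empty`.
#' @export
image_patch_features <- function(seg, l, k = seg$k) {
  lab <- seg$labels
  pid <- patch_index(nrow(lab), ncol(lab), l)
  np <- 4L^l
  nz <- lab > 0
  counts <- matrix(tabulate((lab[nz] - 1L) * np + pid[nz], nbins = np * k),
                   np, k)
  tot <- rowSums(counts)
  f <- counts / ifelse(tot == 0, 1, tot)
  f[tot == 0, ] <- NA_real_
  structure(f, empty = tot == 0)
}

#' Drop excluded marker dimensions from patch features
#'
#' Removes the histogram dimensions of all markers whose annotation is in
#' `exclude` and renormalises the remaining mass; patches left with no mass
#' become empty (`NA` rows).
#'
#' @param features feature matrix from [image_patch_features()].
#' @param annotations per-marker annotations (length k).
#' @param exclude annotations to drop; must exist among `annotations`.
#' @return Reduced feature matrix with updated `empty` attribute.
#' @export
exclude_marker_classes <- function(features, annotations, exclude) {
  if (length(exclude) == 0) return(features)
  if (!all(exclude %in% annotations))
    stop("excluded annotation(s) not present among the markers")
  keep <- !(annotations %in% exclude)
  if (!any(keep)) stop("exclusion would remove all markers")
  f <- features[, keep, drop = FALSE]
  tot <- rowSums(f)
  tot[is.na(tot)] <- 0
  out <- f / ifelse(tot == 0, 1, tot)
  out[tot == 0, ] <- NA_real_
  structure(out, empty = tot == 0)
}

#' Build a visual-word codebook from patch features
#'
#' k-means quantization (Euclidean, k-means++ initialisation, best of
#' `nstart` restarts) of the pooled patch features of the training images;
#' empty patches are dropped. Deterministic given `seed`.
#'
#' @param features matrix of patch features (rows may contain `NA` = empty).
#' @param c codebook size.
#' @param seed RNG seed.
#' @param nstart restarts.
#' @return An object of class `codebook` with `words` (c x k matrix).
#' @export
build_codebook <- function(features, c, seed = 1, nstart = 5) {
  X <- features[stats::complete.cases(features), , drop = FALSE]
  if (nrow(X) == 0) stop("no non-empty patch features")
  if (nrow(X) < c) stop("fewer patch features than codebook size")
  km <- withr::with_seed(seed, kmeans_pp(X, c, nstart = nstart))
  structure(list(words = unname(km$centers), c = c, seed = seed),
            class = "codebook")
}

#' Term vector of an image
#'
#' Assigns every non-empty patch to its nearest visual word (1-nearest
#' neighbour, ties to the lowest word index) and returns the L1-normalised
#' histogram of word occurrences.
#'
#' @param features feature matrix from [image_patch_features()] (or a
#'   [segmentation_map], in which case `l` must be given).
#' @param cb a [codebook].
#' @param l division level, only when passing a segmentation map.
#' @return Numeric length-`c` vector summing to 1.
#' @export
term_vector <- function(features, cb, l = NULL) {
  if (inherits(features, "segmentation_map")) {
    if (is.null(l)) stop("l is required when passing a segmentation map")
    features <- image_patch_features(features, l)
  }
  X <- features[stats::complete.cases(features), , drop = FALSE]
  if (nrow(X) == 0) stop("all patches are empty; term vector undefined")
  if (ncol(X) != ncol(cb$words))
    stop("feature dimensionality does not match the codebook")
  w <- nearest_centroid(X, cb$words)
  tabulate(w, nbins = cb$c) / nrow(X)
}

#' Train the maximum-margin classifier on term vectors
#'
#' Linear-kernel SVM (one-vs-rest for more than two classes), regularisation
#' constant `cost`; deterministic given the input.
#'
#' @param term_vectors numeric matrix, one image per row.
#' @param labels class labels (coerced to factor).
#' @param cost SVM cost (default 100; see [bof_config()]).
#' @param seed RNG seed (kept for interface symmetry; training itself is
#'   deterministic).
#' @return An object of class `bof_classifier`.
#' @export
train_classifier <- function(term_vectors, labels, cost = 100, seed = 1) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("training needs at least two classes")
  if (any(table(y) < 2)) stop("each class needs at least two samples")
  fit <- withr::with_seed(seed,
    e1071::svm(as.matrix(term_vectors), y, kernel = "linear", cost = cost,
               scale = FALSE))
  structure(list(fit = fit, levels = levels(y)), class = "bof_classifier")
}

#' @export
predict.bof_classifier <- function(object, newdata, ...) {
  as.character(stats::predict(object$fit, as.matrix(newdata)))
}

#' Stratified k-fold cross-validation of the BoF pipeline
#'
#' Folds are stratified by class with a fixed seed. Within each fold the
#' codebook is built from the training images only (no leakage into the
#' test fold), term vectors are computed for all images against that
#' codebook, a linear SVM is trained, and the held-out fold is predicted.
#' Marker exclusion (`cfg$exclude`) is applied to the patch features before
#' codebook construction.
#'
#' @param segs list of [segmentation_map]s (all with the same k and
#'   annotations).
#' @param labels class label per image.
#' @param cfg a [bof_config].
#' @return list with `total_accuracy` (mean over folds), `per_class`
#'   (fold-averaged recall per class), `pooled_confusion`, `folds`
#'   (data.frame per fold), and `codebooks`.
#' @export
cross_validate <- function(segs, labels, cfg = bof_config()) {
  y <- factor(labels)
  if (any(table(y) < cfg$folds))
    stop("every class needs at least as many images as folds")
  ann <- segs[[1]]$annotations
  feats <- lapply(segs, image_patch_features, l = cfg$l)
  if (length(cfg$exclude) > 0)
    feats <- lapply(feats, exclude_marker_classes, annotations = ann,
                    exclude = cfg$exclude)
  fold_of <- withr::with_seed(cfg$seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      i <- sample(which(y == cl))
      f[i] <- rep(seq_len(cfg$folds), length.out = length(i))
    }
    f
  })
  fold_rows <- list(); codebooks <- list()
  conf <- matrix(0, nlevels(y), nlevels(y),
                 dimnames = list(truth = levels(y), pred = levels(y)))
  recalls <- matrix(NA_real_, cfg$folds, nlevels(y),
                    dimnames = list(NULL, levels(y)))
  for (fd in seq_len(cfg$folds)) {
    tr <- which(fold_of != fd); te <- which(fold_of == fd)
    pooled <- do.call(rbind, feats[tr])
    cb <- build_codebook(pooled, cfg$c, seed = cfg$seed + fd,
                         nstart = cfg$nstart)
    codebooks[[fd]] <- cb
    tv <- t(vapply(feats, term_vector, numeric(cfg$c), cb = cb))
    clf <- train_classifier(tv[tr, , drop = FALSE], y[tr], cost = cfg$cost,
                            seed = cfg$seed + fd)
    pred <- predict(clf, tv[te, , drop = FALSE])
    truth <- as.character(y[te])
    for (cl in levels(y)) {
      sel <- truth == cl
      if (any(sel)) recalls[fd, cl] <- mean(pred[sel] == cl)
    }
    conf <- conf + table(factor(truth, levels(y)), factor(pred, levels(y)))
    fold_rows[[fd]] <- data.frame(fold = fd, n_test = length(te),
                                  accuracy = mean(pred == truth))
  }
  folds <- do.call(rbind, fold_rows)
  list(total_accuracy = mean(folds$accuracy),
       per_class = colMeans(recalls, na.rm = TRUE),
       pooled_confusion = conf,
       folds = folds,
       codebooks = codebooks,
       config = cfg)
}

#' Cross-validated accuracy over a parameter grid
#'
#' Runs [cross_validate()] for every combination of division level and
#' codebook size and tabulates the fold-averaged accuracies.
#'
#' @param segs,labels as in [cross_validate()].
#' @param l_values,c_values grids (defaults: l = 2..5, c = 10/20/50/100).
#' @param folds,exclude,cost,seed,nstart passed to [bof_config()].
#' @return data.frame with columns `l`, `c`, `total_accuracy` and one
#'   per-class accuracy column per class.
#' @export
bof_grid <- function(segs, labels, l_values = 2:5,
                     c_values = c(10, 20, 50, 100), folds = 4,
                     exclude = character(), cost = 100, seed = 1, nstart = 5) {
  rows <- list()
  for (l in l_values) for (cc in c_values) {
    cv <- cross_validate(segs, labels,
                         bof_config(l = l, c = cc, folds = folds,
                                    exclude = exclude, cost = cost,
                                    seed = seed, nstart = nstart))
    rows[[length(rows) + 1]] <- cbind(
      data.frame(l = l, c = cc, total_accuracy = cv$total_accuracy),
      as.data.frame(t(cv$per_class)))
  }
  do.call(rbind, rows)
}
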