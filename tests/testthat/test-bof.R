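test_that("grid patches tile the image and reassemble bit-exactly", {
  expect_equal(patch_side(512, 2), 128)
  expect_equal(patch_side(512, 3), 64)
  expect_equal(patch_side(512, 4), 32)
  expect_equal(patch_side(512, 5), 16)
  expect_error(patch_side(100, 3), "divisible")

  m <- withr::with_seed(3, matrix(sample(0:5, 16 * 16, TRUE), 16, 16))
  p <- grid_patches(m, 2)
  expect_length(p, 16)
  expect_equal(dim(p[[1]]), c(4, 4))
  g <- 4
  back <- matrix(0L, 16, 16)
  for (i in 1:g) for (j in 1:g)
    back[((i - 1) * 4 + 1):(i * 4), ((j - 1) * 4 + 1):(j * 4)] <-
      p[[(i - 1) * g + j]]
  expect_identical(back, m)

  p1 <- grid_patches(m, 4)                # 2^4 = 16 = side -> 1 px patches
  expect_length(p1, 256)
  expect_equal(dim(p1[[1]]), c(1, 1))
})

test_that("patch features are marker histograms over non-background pixels", {
  pure <- matrix(3L, 4, 4)
  expect_equal(patch_feature(pure, 5), c(0, 0, 1, 0, 0), ignore_attr = TRUE)
  half <- matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4)
  expect_equal(patch_feature(half, 4), c(0.5, 0.5, 0, 0), ignore_attr = TRUE)
  empty <- matrix(0L, 4, 4)
  f <- patch_feature(empty, 3)
  expect_true(attr(f, "empty")); expect_true(all(is.na(f)))

  patch <- withr::with_seed(5, matrix(sample(0:4, 36, TRUE), 6, 6))
  expect_equal(as.vector(patch_feature(patch, 4)), oracle_patch_hist(patch, 4))
})

test_that("vectorised per-image features equal the per-patch loop", {
  lab <- withr::with_seed(6, matrix(sample(0:6, 32 * 32, TRUE), 32, 32))
  seg <- structure(list(labels = lab, k = 6L, annotations = NULL),
                   class = "segmentation_map")
  l <- 3
  fmat <- image_patch_features(seg, l)
  patches <- grid_patches(seg, l)
  for (i in seq_along(patches))
    expect_equal(as.vector(fmat[i, ]), oracle_patch_hist(patches[[i]], 6))
})

test_that("marker-class exclusion drops dimensions and renormalises", {
  ann <- c("HP", "SHG", "WD")
  f <- rbind(c(0.5, 0.5, 0), c(0, 1, 0), c(0.2, 0.3, 0.5))
  expect_identical(exclude_marker_classes(f, ann, character()), f)
  out <- exclude_marker_classes(f, ann, "SHG")
  expect_equal(out[1, ], c(1, 0))               # (0.5 HP, 0.5 SHG) -> pure HP
  expect_true(attr(out, "empty")[2])            # one-hot SHG becomes empty
  expect_equal(out[3, ], c(0.2, 0.5) / 0.7)
  expect_error(exclude_marker_classes(f, ann, c("HP", "SHG", "WD")), "all")
  expect_error(exclude_marker_classes(f, ann, "RC"), "not present")
})

test_that("codebook construction quantizes patch features deterministically", {
  base <- diag(4)
  feats <- base[rep(1:4, each = 5), ]
  cb <- build_codebook(feats, c = 4, seed = 1)
  expect_equal(sort(apply(cb$words, 1, which.max)), 1:4)
  expect_equal(cb$words[order(apply(cb$words, 1, which.max)), ], base,
               tolerance = 1e-9)

  cb1 <- build_codebook(feats, c = 1, seed = 1)
  expect_equal(as.vector(cb1$words), colMeans(feats))

  X <- withr::with_seed(8, matrix(stats::runif(20), 10, 2))
  cb2 <- build_codebook(X, c = 2, seed = 4)
  got <- oracle_nearest(X, cb2$words) - 1
  want <- oracle_two_means(X)$assignment
  agree <- mean(got == want)
  expect_true(agree == 1 || agree == 0)

  expect_error(build_codebook(matrix(NA_real_, 2, 3), c = 1), "non-empty")
})

test_that("term vectors histogram nearest-word assignments", {
  words <- diag(3)
  cb <- structure(list(words = words, c = 3, seed = 1), class = "codebook")
  feats <- words[rep(1, 4), ]
  expect_equal(term_vector(feats, cb), c(1, 0, 0))

  f2 <- withr::with_seed(9, matrix(stats::runif(48), 16, 3))
  f2 <- f2 / rowSums(f2)
  tv <- term_vector(f2, cb)
  expect_equal(sum(tv), 1)
  want <- tabulate(oracle_nearest(f2, words), 3) / 16
  expect_equal(tv, want)

  allna <- matrix(NA_real_, 4, 3)
  expect_error(term_vector(allna, cb), "empty")
})

test_that("the linear SVM separates separable data and not XOR", {
  X <- rbind(matrix(0.1, 4, 2) + diag(2)[c(1, 2, 1, 2), ] * 0.1,
             matrix(0.9, 4, 2))
  y <- rep(c("a", "b"), each = 4)
  clf <- train_classifier(X, y)
  expect_equal(predict(clf, X), y)
  expect_equal(predict(clf, X[3, , drop = FALSE]), "a")

  xor_x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0),
                 c(0.05, 0.05), c(0.95, 0.95), c(0.05, 0.95), c(0.95, 0.05))
  xor_y <- rep(c("a", "a", "b", "b"), 2)
  clf2 <- train_classifier(xor_x, xor_y)
  expect_lt(mean(predict(clf2, xor_x) == xor_y), 1)

  expect_error(train_classifier(X, rep("a", 8)), "two classes")
})

test_that("cross-validation is deterministic and leak-free", {
  segs <- lapply(1:8, function(s) {
    ph <- fixture_phantom(if (s <= 4) "control" else "fibrosis_2wk", 128,
                          seed = s + 70)
    gt_segmentation(ph)
  })
  labels <- rep(c("control", "fibrosis"), each = 4)
  cfg <- bof_config(l = 3, c = 5, folds = 4, seed = 2)
  cv1 <- cross_validate(segs, labels, cfg)
  cv2 <- cross_validate(segs, labels, cfg)
  expect_identical(cv1$total_accuracy, cv2$total_accuracy)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$codebooks[[1]]$words, cv2$codebooks[[1]]$words)
  # codebooks are rebuilt per training fold: different folds, different words
  expect_false(identical(cv1$codebooks[[1]]$words, cv1$codebooks[[2]]$words))
})

test_that("clearly separable phantom classes are classified perfectly", {
  segs <- lapply(1:12, function(s) {
    ph <- fixture_phantom(if (s <= 6) "control" else "fibrosis_2wk", 128,
                          seed = s + 70)
    gt_segmentation(ph)
  })
  labels <- rep(c("control", "fibrosis"), each = 6)
  cv <- cross_validate(segs, labels, bof_config(l = 3, c = 10, folds = 4,
                                                seed = 3))
  expect_equal(cv$total_accuracy, 1.0)
  expect_equal(unname(cv$per_class), c(1, 1))
})

test_that("images with identical term vectors classify at chance", {
  ph <- fixture_phantom("fibrosis_2wk", 128, seed = 77)
  segs <- rep(list(gt_segmentation(ph)), 8)
  labels <- rep(c("a", "b"), 4)
  accs <- vapply(1:5, function(s)
    cross_validate(segs, labels,
                   bof_config(l = 2, c = 3, folds = 4, seed = s))$total_accuracy,
    numeric(1))
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("accuracy does not degrade with finer division on average", {
  segs <- lapply(1:32, function(s) {
    ph <- fixture_phantom(if (s <= 16) "fibrosis_2wk" else "fibrosis_4wk", 128,
                          seed = s + 90)
    gt_segmentation(ph)
  })
  labels <- rep(c("w2", "w4"), each = 16)
  acc <- function(l, seed)
    cross_validate(segs, labels,
                   bof_config(l = l, c = 10, folds = 4,
                              seed = seed))$total_accuracy
  seeds <- 1:5
  a2 <- mean(vapply(seeds, function(s) acc(2, s), numeric(1)))
  a5 <- mean(vapply(seeds, function(s) acc(5, s), numeric(1)))
  expect_gte(a5, a2 - 0.02)
})

test_that("excluding SHG markers barely moves fibrosis-grade accuracy", {
  segs <- lapply(1:32, function(s) {
    ph <- fixture_phantom(if (s <= 16) "fibrosis_2wk" else "fibrosis_4wk", 128,
                          seed = s + 90)
    gt_segmentation(ph)
  })
  labels <- rep(c("w2", "w4"), each = 16)
  full <- cross_validate(segs, labels,
                         bof_config(l = 4, c = 10, folds = 4, seed = 6))
  noshg <- cross_validate(segs, labels,
                          bof_config(l = 4, c = 10, folds = 4, seed = 6,
                                     exclude = "SHG"))
  expect_lt(abs(full$total_accuracy - noshg$total_accuracy), 0.05)
})
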