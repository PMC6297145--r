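#' Emission spectra templates for the phantom components
#'
#' Smooth piecewise-linear emission templates for the five pixel components:
#' background, hepatic parenchyma (HP), second-harmonic fibrils (SHG),
#' white-dot vitamin-A sites (WD), and bright red-cell-like objects (RC).
#' Shapes follow the qualitative structure of liver intrinsic emission:
#' HP and RC rise between 500 and 650 nm with RC about three times brighter,
#' WD is broad across 400-650 nm, and SHG is a single narrow peak in the
#' 520-530 nm channel. Peak amplitudes on the 8-bit scale: HP 60, RC 180,
#' WD 80, SHG 200.
#'
#' @param n_channels channel count (default 25: 400-650 nm at 10 nm).
#' @param wavelength_start,bandwidth calibration (nm).
#' @return 5 x C matrix with rownames background/HP/SHG/WD/RC.
#' @export
spectral_profiles <- function(n_channels = 25, wavelength_start = 400,
                              bandwidth = 10) {
  wl <- wavelength_start + (seq_len(n_channels) - 0.5) * bandwidth
  hp <- ifelse(wl < 500, 6, 10 + 50 * (wl - 500) / 145)
  rc <- ifelse(wl < 500, 15, 30 + 150 * (wl - 500) / 145)
  wd <- 70 + 15 * (1 - abs(wl - 520) / 130)        # gentle broad hump, ~80
  shg <- numeric(n_channels)
  shg_ch <- band_channels(wavelength_start, bandwidth, n_channels, c(520, 530))
  shg[shg_ch] <- 200
  bg <- rep(1.5, n_channels)
  out <- rbind(background = bg, HP = hp, SHG = shg, WD = wd, RC = rc)
  colnames(out) <- wl
  out
}

#' Parametric description of a synthetic tissue image class
#'
#' Defaults encode three image classes: healthy control (no red-cell objects,
#' sparse collagen), 2-week fibrosis (collagen fibrils, moderate RC load) and
#' 4-week fibrosis (same composition but more and larger RC objects; the only
#' parameters that differ from 2-week are `rc_count` and `rc_mean_area`).
#' Object counts are specified at the 512 x 512 acquisition size and scaled
#' by area for other sizes, keeping object densities constant.
#'
#' @param class_label one of `"control"`, `"fibrosis_2wk"`, `"fibrosis_4wk"`.
#' @param image_size image side in pixels (default 512).
#' @param wd_count,rc_count objects per image; `NULL` uses the class default.
#' @param rc_mean_area mean RC object area (px).
#' @param shg_fraction target fraction of pixels covered by SHG fibrils.
#' @param noise_sd additive Gaussian noise standard deviation (8-bit units).
#' @param seed RNG seed making the phantom fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("control", "fibrosis_2wk", "fibrosis_4wk"),
                         image_size = 512, wd_count = NULL, rc_count = NULL,
                         rc_mean_area = NULL, shg_fraction = NULL,
                         noise_sd = 3, seed = 1) {
  class_label <- match.arg(class_label)
  f <- (image_size / 512)^2
  def <- switch(class_label,
    control      = list(wd = max(6,  round(48 * f)), rc = 0L,
                        rc_area = 0,  shg = 0.01),
    fibrosis_2wk = list(wd = max(12, round(96 * f)), rc = max(2L, as.integer(round(12 * f))),
                        rc_area = 300, shg = 0.05),
    fibrosis_4wk = list(wd = max(12, round(96 * f)), rc = max(3L, as.integer(round(30 * f))),
                        rc_area = 700, shg = 0.05))
  wd_count <- wd_count %||% def$wd
  rc_count <- rc_count %||% def$rc
  rc_mean_area <- rc_mean_area %||% def$rc_area
  shg_fraction <- shg_fraction %||% def$shg
  if (wd_count < 0 || rc_count < 0) stop("object counts must be nonnegative")
  if (shg_fraction < 0 || shg_fraction >= 1) stop("shg_fraction must lie in [0, 1)")
  if (class_label == "control" && rc_count > 0)
    stop("control phantoms carry no red-cell-like objects (rc_count must be 0)")
  structure(list(class_label = class_label, image_size = image_size,
                 wd_count = wd_count, rc_count = rc_count,
                 rc_mean_area = rc_mean_area, shg_fraction = shg_fraction,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

# hepatocyte-mosaic brightness field: irregular rectangular cells (~`cell` px
# across) with per-cell intensity and darker intercellular borders
cell_mosaic <- function(n, cell = 16, lo = 0.75, hi = 1.25, border = 0.55) {
  cuts <- function() {
    b <- 0
    while (b[length(b)] < n)
      b <- c(b, b[length(b)] + max(6, round(stats::rnorm(1, cell, cell / 4))))
    b
  }
  rb <- cuts(); cb <- cuts()
  iy <- findInterval(seq_len(n) - 0.5, rb); ix <- findInterval(seq_len(n) - 0.5, cb)
  S <- matrix(stats::runif(length(rb) * length(cb), lo, hi), length(rb))
  M <- S[iy, ix]
  on_border <- outer(seq_len(n) %in% rb, rep(TRUE, n)) |
    outer(rep(TRUE, n), seq_len(n) %in% cb)
  M[on_border] <- M[on_border] * border
  M
}

# smooth multiplicative field in [1-amp, 1+amp], bilinear over a coarse grid
smooth_field <- function(n, cells = 8, amp = 0.12) {
  g <- matrix(stats::runif((cells + 1)^2, 1 - amp, 1 + amp), cells + 1)
  pos <- (seq_len(n) - 0.5) / n * cells
  i0 <- pmin(floor(pos), cells - 1); fr <- pos - i0
  a <- g[i0 + 1, i0 + 1]; b <- g[i0 + 2, i0 + 1]
  c_ <- g[i0 + 1, i0 + 2]; d <- g[i0 + 2, i0 + 2]
  fy <- matrix(fr, n, n); fx <- matrix(fr, n, n, byrow = TRUE)
  a * (1 - fy) * (1 - fx) + b * fy * (1 - fx) + c_ * (1 - fy) * fx + d * fy * fx
}

# random smooth path: returns matrix of (row, col) points, clipped to image
smooth_path <- function(n, start, theta0, len, wobble) {
  dth <- stats::rnorm(len, 0, wobble)
  th <- theta0 + cumsum(dth)
  y <- start[1] + cumsum(sin(th)); x <- start[2] + cumsum(cos(th))
  keep <- y >= 1 & y <= n & x >= 1 & x <= n
  if (any(!keep)) { stop_at <- which(!keep)[1] - 1; if (stop_at < 1) return(NULL)
    y <- y[seq_len(stop_at)]; x <- x[seq_len(stop_at)] }
  cbind(round(y), round(x))
}

# stamp disk of radius r around points onto logical matrix, returns indices
stamp_points <- function(n, pts, r) {
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2 + 0.25, ]
  idx <- integer(0)
  for (j in seq_len(nrow(offs))) {
    y <- pts[, 1] + offs$dy[j]; x <- pts[, 2] + offs$dx[j]
    ok <- y >= 1 & y <= n & x >= 1 & x <= n
    idx <- c(idx, (x[ok] - 1L) * n + y[ok])
  }
  unique(idx)
}

#' Generate a synthetic liver-tissue spectral phantom
#'
#' Renders a spectral cube plus a ground-truth label image. Hepatic
#' parenchyma fills the field as a shaded mosaic carved by dark sinusoid
#' channels; curvilinear SHG fibrils run along the sinusoids (their emission
#' adds to any underlying parenchyma fluorescence); white-dot sites line the
#' sinusoid channels; red-cell-like objects are bright disks. Additive
#' Gaussian noise is applied and intensities clipped to `[0, 255]`.
#'
#' Label codes: 0 background, 1 HP, 2 SHG, 3 WD, 4 RC.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `image` (a [spectral_image]), `labels`
#'   (H x W integer matrix) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  budget <- spec$wd_count * 5 + spec$rc_count * spec$rc_mean_area * 2.6 +
    spec$shg_fraction * n^2
  if (budget > 0.6 * n^2)
    stop("object budget exceeds the image area")
  withr::with_seed(spec$seed, {
    lab <- matrix(1L, n, n)                      # HP everywhere
    # --- sinusoid channels (dark vascular network) ---
    n_sin <- max(3, round(10 * n / 512))
    sin_idx <- integer(0)
    for (i in seq_len(n_sin)) {
      pts <- smooth_path(n, start = stats::runif(2, 1, n),
                         theta0 = stats::runif(1, 0, 2 * pi),
                         len = round(1.3 * n), wobble = 0.12)
      if (!is.null(pts)) sin_idx <- c(sin_idx, stamp_points(n, pts, 2))
    }
    sin_idx <- unique(sin_idx)
    lab[sin_idx] <- 0L
    # --- SHG fibrils: thin curves seeded on the sinusoid network ---
    shg_target <- round(spec$shg_fraction * n^2)
    fibril_scale <- rep(0, n * n)                # per-pixel SHG brightness
    shg_underlay <- rep(0, n * n)                # 1 = parenchyma shines through
    tries <- 0
    while (sum(lab == 2L) < shg_target && tries < 60 * max(1, n_sin) * 20) {
      tries <- tries + 1
      seed_px <- if (length(sin_idx)) sample(sin_idx, 1) else sample.int(n * n, 1)
      start <- c((seed_px - 1L) %% n + 1L, (seed_px - 1L) %/% n + 1L)
      pts <- smooth_path(n, start, stats::runif(1, 0, 2 * pi),
                         len = sample(30:120, 1), wobble = 0.06)
      if (is.null(pts) || nrow(pts) < 5) next
      # fine fibrils overlie parenchyma (its autofluorescence shines
      # through); thicker septum-like bundles are dense scar that displaces
      # hepatocytes and carries no parenchymal underlay
      thick <- sample(1:2, 1)
      idx <- stamp_points(n, pts, thick)
      s <- stats::runif(1, 0.6, 1.0)             # fibril brightness
      fibril_scale[idx] <- s
      shg_underlay[idx] <- if (thick == 2) 0 else as.numeric(lab[idx] == 1L)
      lab[idx] <- 2L
    }
    # --- RC disks ---
    rc_centers <- matrix(numeric(0), 0, 3)
    if (spec$rc_count > 0) {
      tries <- 0
      while (nrow(rc_centers) < spec$rc_count && tries < 4000) {
        tries <- tries + 1
        a <- spec$rc_mean_area * stats::runif(1, 0.7, 1.3)
        r <- max(1.5, sqrt(a / pi))
        cy <- stats::runif(1, r + 2, n - r - 1); cx <- stats::runif(1, r + 2, n - r - 1)
        if (nrow(rc_centers) > 0) {
          dmin <- sqrt((rc_centers[, 1] - cy)^2 + (rc_centers[, 2] - cx)^2)
          if (any(dmin < r + rc_centers[, 3] + 3)) next
        }
        rc_centers <- rbind(rc_centers, c(cy, cx, r))
      }
      if (nrow(rc_centers) < spec$rc_count)
        stop("object budget exceeds the image area (cannot place RC objects)")
      for (i in seq_len(nrow(rc_centers))) {
        r <- rc_centers[i, 3]; ri <- ceiling(r)
        ys <- max(1, round(rc_centers[i, 1]) - ri):min(n, round(rc_centers[i, 1]) + ri)
        xs <- max(1, round(rc_centers[i, 2]) - ri):min(n, round(rc_centers[i, 2]) + ri)
        dd <- outer((ys - rc_centers[i, 1])^2, (xs - rc_centers[i, 2])^2, "+")
        sel <- which(dd <= r^2, arr.ind = TRUE)
        lab[cbind(ys[sel[, 1]], xs[sel[, 2]])] <- 4L
      }
    }
    # --- WD dots adjacent to sinusoids ---
    wd_scale <- rep(1, n * n)
    if (spec$wd_count > 0) {
      near <- matrix(FALSE, n, n); near[sin_idx] <- TRUE
      near <- as.matrix(EBImage::imageData(EBImage::dilate(
        EBImage::Image(near * 1), EBImage::makeBrush(7, shape = "box")))) > 0
      # stellate-cell-associated dots line the sinusoid channels (space of
      # Disse): prefer sites on the dark sinusoids, then their parenchymal
      # margin, then any parenchyma pixel
      cand_sin <- which(lab == 0L)
      cand_near <- which(near & lab == 1L)
      cand_far <- which(!near & lab == 1L)
      cand <- c(sample(cand_sin), sample(cand_near), sample(cand_far))
      placed <- matrix(numeric(0), 0, 2)
      # dots 2-4 px across (areas 4-12 px)
      shapes <- list(
        cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)),                       # 2 px square
        cbind(c(0, 1, -1, 0, 0), c(0, 0, 0, 1, -1)),               # 3 px plus
        as.matrix(expand.grid(-1:1, -1:1)),                        # 3 px square
        rbind(as.matrix(expand.grid(-1:1, -1:1)),
              cbind(c(2, -2, 0), c(0, 0, 2))))                     # 4 px blob
      ci <- 0
      while (nrow(placed) < spec$wd_count && ci < length(cand)) {
        ci <- ci + 1
        py <- (cand[ci] - 1L) %% n + 1L; px <- (cand[ci] - 1L) %/% n + 1L
        if (nrow(placed) > 0 &&
            any(pmax(abs(placed[, 1] - py), abs(placed[, 2] - px)) < 6)) next
        sh <- shapes[[sample.int(4, 1)]]
        yy <- py + sh[, 1]; xx <- px + sh[, 2]
        if (any(yy > n) || any(xx > n) || any(yy < 1) || any(xx < 1)) next
        ii <- (xx - 1L) * n + yy
        if (any(!lab[ii] %in% c(0L, 1L))) next
        lab[ii] <- 3L
        wd_scale[ii] <- stats::runif(1, 0.85, 1.15)
        placed <- rbind(placed, c(py, px))
      }
      if (nrow(placed) < spec$wd_count)
        stop("object budget exceeds the image area (cannot place WD objects)")
    }
    # --- intensities ---
    nc <- 25
    P <- spectral_profiles(nc)
    fld <- smooth_field(n)
    hp_field <- fld * cell_mosaic(n)
    sc <- as.vector(hp_field)
    sc[lab == 0L] <- 1
    sc[lab == 3L] <- wd_scale[lab == 3L]
    # cell-like RC objects carry granular internal texture (~5 px), so
    # feature detectors sample their interiors, not just their rims
    sc[lab == 4L] <- (fld * cell_mosaic(n, cell = 5, border = 1))[lab == 4L]
    # row lookup: label 0 -> background, 1 -> HP, 2 -> SHG, 3 -> WD, 4 -> RC
    M <- P[as.vector(lab) + 1L, , drop = FALSE] * sc
    shg_px <- which(as.vector(lab) == 2L)
    if (length(shg_px)) {
      # fine fibrils over former parenchyma keep the HP emission underneath
      M[shg_px, ] <- outer(fibril_scale[shg_px], P["SHG", ]) +
        outer(hp_field[shg_px] * shg_underlay[shg_px], P["HP", ])
    }
    M <- round(M + stats::rnorm(length(M), 0, spec$noise_sd))
    M[M < 0] <- 0
    M[M > 255] <- 255
    storage.mode(M) <- "integer"
    cube <- array(M, dim = c(n, n, nc))
    list(image = spectral_image(cube), labels = lab, spec = spec)
  })
}

#' Generate a balanced labelled phantom dataset
#'
#' Produces `n_per_class` phantoms per class template with the reproducible
#' seed schedule `seed_i = base_seed + i` (`i` running over all images,
#' class-major). The manifest records the full spec of every image, so a
#' dataset can be regenerated image by image without holding all cubes in
#' memory (`materialize = FALSE`).
#'
#' @param specs named list of [phantom_spec] templates, one per class.
#' @param n_per_class images per class.
#' @param base_seed first seed of the schedule.
#' @param materialize if `TRUE`, return generated phantoms in `$images`.
#' @return list with `manifest` (data.frame) and, if materialized, `images`.
#' @export
generate_dataset <- function(specs, n_per_class, base_seed = 1,
                             materialize = TRUE) {
  if (n_per_class < 1) stop("n_per_class must be at least 1")
  rows <- list(); i <- 0
  for (cl in names(specs)) {
    sp <- specs[[cl]]
    for (j in seq_len(n_per_class)) {
      rows[[length(rows) + 1]] <- data.frame(
        class_label = sp$class_label, image_size = sp$image_size,
        wd_count = sp$wd_count, rc_count = sp$rc_count,
        rc_mean_area = sp$rc_mean_area, shg_fraction = sp$shg_fraction,
        noise_sd = sp$noise_sd, seed = base_seed + i,
        stringsAsFactors = FALSE)
      i <- i + 1
    }
  }
  manifest <- do.call(rbind, rows)
  out <- list(manifest = manifest)
  if (materialize)
    out$images <- lapply(seq_len(nrow(manifest)), function(r)
      phantom_from_manifest(manifest[r, ]))
  out
}

#' Regenerate one phantom from a manifest row
#'
#' @param row single-row data.frame as produced by [generate_dataset()].
#' @return A phantom, as from [generate_phantom()].
#' @export
phantom_from_manifest <- function(row) {
  generate_phantom(phantom_spec(
    class_label = row$class_label, image_size = row$image_size,
    wd_count = row$wd_count, rc_count = row$rc_count,
    rc_mean_area = row$rc_mean_area, shg_fraction = row$shg_fraction,
    noise_sd = row$noise_sd, seed = row$seed))
}
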