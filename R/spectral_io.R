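#' Calibrated spectral image cube
#'
#' Container for a single-plane spectral acquisition: an H x W x C array of
#' nonnegative 8-bit intensities together with its wavelength calibration.
#' Channel `i` (1-based) covers the half-open interval
#' `[wavelength_start + (i-1)*bandwidth, wavelength_start + i*bandwidth)` nm.
#'
#' @param data numeric or integer H x W x C array with values in `[0, 255]`.
#' @param wavelength_start first channel's lower wavelength bound (nm).
#' @param bandwidth channel width (nm).
#' @param pixel_size optional pixel pitch (micrometres per pixel).
#' @return An object of class `spectral_image`.
#' @examples
#' img <- spectral_image(array(0L, c(8, 8, 25)))
#' num_channels(400, 650, 10)
#' @export
spectral_image <- function(data, wavelength_start = 400, bandwidth = 10,
                           pixel_size = NULL) {
  if (length(dim(data)) != 3)
    stop("`data` must be a 3-d array (rows x cols x channels)")
  if (any(data < 0) || any(data > 255))
    stop("intensities must lie in [0, 255]; convert 12-bit data with to_8bit()")
  structure(
    list(data = data, wavelength_start = wavelength_start,
         bandwidth = bandwidth, pixel_size = pixel_size),
    class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_image> %d x %d px, %d channels (%g-%g nm @ %g nm)\n",
              d[1], d[2], d[3], x$wavelength_start,
              x$wavelength_start + d[3] * x$bandwidth, x$bandwidth))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$data)

#' Z-stack of spectral images
#'
#' @param slices list of [spectral_image] objects sharing shape and calibration.
#' @param z_step axial step between slices (micrometres), must be positive.
#' @return An object of class `zstack`.
#' @export
zstack <- function(slices, z_step = 2) {
  if (length(slices) == 0) stop("a z-stack needs at least one slice")
  if (!all(vapply(slices, inherits, logical(1), "spectral_image")))
    stop("all slices must be spectral_image objects")
  d0 <- dim(slices[[1]]$data)
  ok <- vapply(slices, function(s)
    identical(dim(s$data), d0) &&
      s$wavelength_start == slices[[1]]$wavelength_start &&
      s$bandwidth == slices[[1]]$bandwidth, logical(1))
  if (!all(ok)) stop("slices differ in shape or calibration")
  if (z_step <= 0) stop("z_step must be positive")
  structure(list(slices = slices, z_step = z_step), class = "zstack")
}

#' Named wavelength bands
#'
#' A band is a closed interval `[low, high]` nm; a band selects the spectral
#' channels fully contained in it.
#'
#' @param ... named length-2 numeric vectors, e.g. `SHG = c(520, 530)`.
#' @return An object of class `band_set` (named list of intervals).
#' @export
band_set <- function(...) {
  bands <- list(...)
  if (is.null(names(bands)) || any(names(bands) == ""))
    stop("all bands must be named")
  if (anyDuplicated(names(bands))) stop("band names must be unique")
  ok <- vapply(bands, function(b) length(b) == 2 && b[2] > b[1], logical(1))
  if (!all(ok)) stop("each band must be c(low, high) with high > low")
  structure(bands, class = "band_set")
}

#' Default three-band reduction: shorter / SHG / longer wavelengths
#'
#' The shorter autofluorescence band 400-500 nm, the narrow second-harmonic
#' band 520-530 nm, and the longer autofluorescence band 550-650 nm.
#' @return A [band_set].
#' @export
default_band_set <- function() {
  band_set(shorter = c(400, 500), SHG = c(520, 530), longer = c(550, 650))
}

#' Number of spectral channels implied by a calibration
#'
#' @param start,end wavelength range (nm), `end > start`.
#' @param bandwidth channel width (nm); must divide `end - start`.
#' @return Integer channel count, e.g. `num_channels(400, 650, 10)` is 25.
#' @export
num_channels <- function(start, end, bandwidth) {
  if (end <= start) stop("end must exceed start")
  n <- (end - start) / bandwidth
  if (abs(n - round(n)) > 1e-9)
    stop("bandwidth does not evenly divide the wavelength range")
  as.integer(round(n))
}

#' Second-harmonic emission wavelength
#'
#' SHG is emitted at exactly half the excitation wavelength; for 1050 nm
#' multi-photon excitation the collagen SHG signal appears at 525 nm.
#'
#' @param excitation_nm excitation wavelength (nm).
#' @return Emission wavelength (nm).
#' @export
shg_wavelength <- function(excitation_nm) excitation_nm / 2

#' Convert 12-bit intensities to 8-bit
#'
#' Linear rescale `v -> floor(v * 255 / 4095)`: monotone, 0 maps to 0 and
#' 4095 maps to 255 exactly.
#'
#' @param x numeric array/vector with values in `[0, 4095]`.
#' @return Same shape, integer-valued in `[0, 255]`.
#' @export
to_8bit <- function(x) {
  if (any(x < 0) || any(x > 4095)) stop("values outside the 12-bit range [0, 4095]")
  out <- floor(x * 255 / 4095)
  storage.mode(out) <- "integer"
  out
}

# channel indices (1-based) fully contained in [low, high]
band_channels <- function(wavelength_start, bandwidth, n_channels, band) {
  lo <- wavelength_start + (seq_len(n_channels) - 1) * bandwidth
  hi <- lo + bandwidth
  which(lo >= band[1] & hi <= band[2] + 1e-9)
}

#' Reduce a spectral cube to a few wavelength bands
#'
#' Each output plane is the mean of the spectral channels whose intervals are
#' fully contained in the band. The mean (rather than the raw channel sum)
#' keeps band images on the 8-bit scale.
#'
#' @param img a [spectral_image].
#' @param bands a [band_set]; defaults to [default_band_set()].
#' @return H x W x B array; `dimnames[[3]]` carries the band names.
#' @export
band_reduce <- function(img, bands = default_band_set()) {
  stopifnot(inherits(img, "spectral_image"))
  d <- dim(img$data)
  planes <- lapply(names(bands), function(nm) {
    ch <- band_channels(img$wavelength_start, img$bandwidth, d[3], bands[[nm]])
    if (length(ch) == 0)
      stop(sprintf("band '%s' contains no spectral channel", nm))
    if (length(ch) == 1) img$data[, , ch] else rowMeans(img$data[, , ch, drop = FALSE], dims = 2)
  })
  out <- array(unlist(planes), dim = c(d[1], d[2], length(bands)),
               dimnames = list(NULL, NULL, names(bands)))
  out
}

#' Maximum intensity projection of a z-stack
#'
#' Projects the per-pixel, per-channel maximum over all slices onto a single
#' spectral image; identity on a single-slice stack.
#'
#' @param stack a [zstack].
#' @return A [spectral_image].
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  acc <- stack$slices[[1]]$data
  for (s in stack$slices[-1]) acc <- pmax(acc, s$data)
  s1 <- stack$slices[[1]]
  spectral_image(acc, s1$wavelength_start, s1$bandwidth, s1$pixel_size)
}

#' Read a spectral stack from a multi-page TIFF
#'
#' Pages are ordered channel-fastest, then z. A page count equal to the
#' declared channel count yields a [spectral_image]; an integer multiple
#' yields a [zstack]; anything else is a calibration error. 12-bit input is
#' converted to 8-bit on read.
#'
#' @param path TIFF file path. A sidecar `<path>.json` written by
#'   [write_spectral_stack()] overrides the calibration arguments.
#' @param channels declared channel count (default 25).
#' @param wavelength_start,bandwidth calibration (nm).
#' @param bits input bit depth, 8 or 12.
#' @param z_step axial step for z-stacks (micrometres).
#' @param pixel_size optional pixel pitch (micrometres per pixel).
#' @return A [spectral_image] or [zstack].
#' @export
read_spectral_stack <- function(path, channels = 25, wavelength_start = 400,
                                bandwidth = 10, bits = 8, z_step = 2,
                                pixel_size = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    channels <- meta$channels %||% channels
    wavelength_start <- meta$wavelength_start %||% wavelength_start
    bandwidth <- meta$bandwidth %||% bandwidth
    z_step <- meta$z_step %||% z_step
    pixel_size <- meta$pixel_size %||% pixel_size
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  n <- length(pages)
  if (n %% channels != 0)
    stop(sprintf("page count %d is not a multiple of the declared %d channels",
                 n, channels))
  pages <- lapply(pages, function(p) if (bits == 12) to_8bit(p) else p)
  one <- function(pg) {
    d <- dim(pg[[1]])
    cube <- array(unlist(pg), dim = c(d[1], d[2], channels))
    spectral_image(cube, wavelength_start, bandwidth, pixel_size)
  }
  nz <- n %/% channels
  if (nz == 1) return(one(pages))
  slices <- lapply(seq_len(nz), function(i)
    one(pages[((i - 1) * channels + 1):(i * channels)]))
  zstack(slices, z_step = z_step)
}

#' Write a spectral stack to a multi-page TIFF with a JSON sidecar
#'
#' Inverse of [read_spectral_stack()]: pixel data round-trip bit-exactly.
#'
#' @param x a [spectral_image] or [zstack].
#' @param path output TIFF path; calibration goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spectral_stack <- function(x, path) {
  imgs <- if (inherits(x, "zstack")) x$slices else list(x)
  s1 <- imgs[[1]]
  pages <- unlist(lapply(imgs, function(im)
    lapply(seq_len(dim(im$data)[3]), function(c) im$data[, , c] / 255)),
    recursive = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  meta <- list(channels = dim(s1$data)[3],
               wavelength_start = s1$wavelength_start,
               bandwidth = s1$bandwidth,
               pixel_size = s1$pixel_size)
  if (inherits(x, "zstack")) meta$z_step <- x$z_step
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
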