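#' Hyperspectral image stack with per-channel wavelength centers
#'
#' A `spectral_image` bundles a channel x row x col intensity array with the
#' emission wavelength (nm) at the center of each detection channel, mirroring
#' the output of a spectral confocal detector that collects emission in
#' approximately 9 nm wide bands.
#'
#' @param data numeric array, channel x row x col; all values finite,
#'   raw data may contain zeros.
#' @param channel_centers numeric vector of wavelengths (nm), strictly
#'   increasing, one per channel plane.
#' @return An object of class `spectral_image` with elements `data` and
#'   `channel_centers`.
#' @examples
#' img <- spectral_image(array(1, dim = c(20, 8, 8)), channel_grid("pro12a"))
#' @export
spectral_image <- function(data, channel_centers) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (channel x row x col)")
  channel_centers <- as.numeric(channel_centers)
  if (length(channel_centers) != dim(data)[1L])
    stop("length(channel_centers) must equal the number of channel planes")
  if (any(diff(channel_centers) <= 0))
    stop("`channel_centers` must be strictly increasing")
  if (!all(is.finite(data)))
    stop("all intensities must be finite")
  structure(list(data = data, channel_centers = channel_centers),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("spectral_image: %d channels (%.0f-%.0f nm), %d x %d px\n",
              d[1], min(x$channel_centers), max(x$channel_centers), d[2], d[3]))
  invisible(x)
}

#' Default detection-channel grids
#'
#' Uniform channel-center grids for the two detector configurations used with
#' these probes: 20 channels spanning 423-601 nm (Pro12A, 405 nm excitation)
#' and 22 channels spanning 503-700 nm (NR12S/NR12A, 488 nm excitation).
#'
#' @param probe one of `"pro12a"`, `"nr12s"`, `"nr12a"`.
#' @return numeric vector of channel-center wavelengths (nm).
#' @export
channel_grid <- function(probe = c("pro12a", "nr12s", "nr12a")) {
  probe <- match.arg(tolower(probe), c("pro12a", "nr12s", "nr12a"))
  if (probe == "pro12a") seq(423, 601, length.out = 20)
  else seq(503, 700, length.out = 22)
}

#' Region of interest on an image grid
#'
#' @param rows,cols integer pixel coordinates (1-based, equal length).
#' @param label free-text label (e.g. "ordered", "background").
#' @return An object of class `roi`.
#' @export
roi <- function(rows, cols, label = "") {
  if (length(rows) != length(cols)) stop("rows and cols must have equal length")
  if (length(rows) == 0L) stop("ROI must be non-empty")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 label = label), class = "roi")
}

check_roi_bounds <- function(r, img) {
  d <- dim(img$data)
  if (any(r$rows < 1L | r$rows > d[2L]) || any(r$cols < 1L | r$cols > d[3L]))
    stop("ROI pixels out of image bounds")
  invisible(TRUE)
}

#' Map a wavelength to the nearest detection channel
#'
#' Returns the index of the channel whose center is nearest to `wavelength`;
#' ties are broken toward the bluer (lower-wavelength) channel. Queries more
#' than one channel spacing outside the grid are rejected.
#'
#' @param img a [spectral_image].
#' @param wavelength query wavelength (nm).
#' @return integer channel index (1-based).
#' @export
channel_for_wavelength <- function(img, wavelength) {
  cc <- img$channel_centers
  spacing <- mean(diff(cc))
  if (wavelength < min(cc) - spacing || wavelength > max(cc) + spacing)
    stop(sprintf("wavelength %.1f nm outside tolerated range [%.1f, %.1f]",
                 wavelength, min(cc) - spacing, max(cc) + spacing))
  d <- abs(cc - wavelength)
  # which.min returns the first (bluer) index on exact ties
  which.min(d)
}

#' Subtract a background ROI from every channel
#'
#' Computes, per channel, the mean intensity over the background ROI and
#' subtracts it from the whole plane; negative results are clamped to zero so
#' that downstream GP values stay within [-1, 1].
#'
#' @param img a [spectral_image].
#' @param bg a background [roi].
#' @return a background-corrected [spectral_image].
#' @export
subtract_background <- function(img, bg) {
  if (!inherits(bg, "roi")) stop("`bg` must be an roi")
  check_roi_bounds(bg, img)
  d <- dim(img$data)
  idx <- cbind(bg$rows, bg$cols)
  out <- img$data
  for (ch in seq_len(d[1L])) {
    plane <- img$data[ch, , ]
    out[ch, , ] <- pmax(plane - mean(plane[idx]), 0)
  }
  spectral_image(out, img$channel_centers)
}

#' Extract an emission spectrum from an ROI
#'
#' Per channel, the mean intensity over the ROI pixels (the "Z-profile" of the
#' region through the stack). With `normalize = TRUE` the spectrum is divided
#' by its maximum so the peak equals 1.
#'
#' @param img a [spectral_image].
#' @param r an [roi].
#' @param normalize divide by the maximum intensity?
#' @return An `emission_spectrum`: list with `wavelengths` (nm),
#'   `intensities`, and `normalized` flag.
#' @export
extract_spectrum <- function(img, r, normalize = FALSE) {
  if (!inherits(r, "roi")) stop("`r` must be an roi")
  check_roi_bounds(r, img)
  idx <- cbind(r$rows, r$cols)
  v <- apply(img$data, 1L, function(plane) mean(plane[idx]))
  if (normalize) {
    m <- max(v)
    if (m <= 0) stop("cannot normalize an all-zero spectrum")
    v <- v / m
  }
  emission_spectrum(img$channel_centers, v, normalized = normalize)
}

#' Construct an emission spectrum
#'
#' @param wavelengths wavelengths (nm).
#' @param intensities intensities (arbitrary units, or peak-normalized).
#' @param normalized is the spectrum peak-normalized?
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, normalized = FALSE) {
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length")
  if (normalized &&
      (abs(max(intensities) - 1) > 1e-9 || any(intensities < 0 | intensities > 1 + 1e-12)))
    stop("normalized spectrum must lie in [0, 1] with max 1")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 normalized = isTRUE(normalized)),
            class = "emission_spectrum")
}

#' Read / write a spectral image as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per channel; channel centers stored in `<path>.json`.
#'
#' @param img a [spectral_image].
#' @param path TIFF file path; the sidecar is written at `paste0(path, ".json")`.
#' @return `write_spectral_tiff` returns `path` invisibly;
#'   `read_spectral_tiff` returns a [spectral_image].
#' @export
write_spectral_tiff <- function(img, path) {
  scale <- max(img$data, 1)
  pages <- lapply(seq_len(dim(img$data)[1L]),
                  function(ch) img$data[ch, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(channel_centers = img$channel_centers,
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_spectral_tiff
#' @export
read_spectral_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (ch in seq_along(pages)) arr[ch, , ] <- pages[[ch]] * meta$intensity_scale
  spectral_image(arr, meta$channel_centers)
}

#' Export spectra to CSV
#'
#' Writes columns `wavelength_nm`, `intensity`, `normalized_intensity`.
#'
#' @param spec an `emission_spectrum` (un-normalized intensities preferred).
#' @param path output CSV path.
#' @export
write_spectrum_csv <- function(spec, path) {
  m <- max(spec$intensities)
  utils::write.csv(data.frame(wavelength_nm = spec$wavelengths,
                              intensity = spec$intensities,
                              normalized_intensity =
                                if (m > 0) spec$intensities / m else spec$intensities),
                   path, row.names = FALSE)
  invisible(path)
}
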