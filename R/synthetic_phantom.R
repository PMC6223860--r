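#' Configuration for synthetic ROI generation
#'
#' Describes one synthetic "acquisition": square ROIs in Hounsfield units (HU)
#' containing either pure stationary Gaussian noise (signal-absent) or noise
#' plus a centred 2-D Gaussian lesion (signal-present). Defaults reproduce the
#' multicentre phantom design: 90 signal-absent and 40 signal-present images,
#' a 5-mm FWHM lesion at 20 HU nominal contrast, on a medium-phantom pixel grid
#' (370 mm reconstruction FOV on an assumed 512 matrix).
#'
#' @param roi_size_px ROI side length in pixels (>= 8).
#' @param pixel_spacing_mm physical pixel pitch in mm (> 0).
#' @param n_signal_absent number of noise-only ROIs (>= 2; covariance
#'   estimation needs at least two samples).
#' @param n_signal_present number of lesion ROIs (>= 0).
#' @param lesion_fwhm_mm lesion full width at half maximum, mm. Must span at
#'   least 2 pixels so the lesion is resolvable on the grid.
#' @param lesion_amplitude_hu lesion peak contrast relative to background, HU.
#' @param background_hu uniform background level, HU.
#' @param noise_sd_hu target per-pixel noise standard deviation, HU (>= 0).
#' @param noise_model `"white"` (i.i.d. Gaussian pixels) or `"correlated"`
#'   (white noise shaped in the frequency domain by a radial power-law filter,
#'   a crude stand-in for filtered-backprojection texture).
#' @param correlation_exponent exponent of the radial filter (amplitude
#'   proportional to f^(exponent/2)); used only for the correlated model.
#' @param seed integer RNG seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return an object of class `synthetic_config`.
#' @seealso [phantom_preset()] for the small/medium/large FOV presets,
#'   [generate_dataset()] to realise the images.
#' @export
synthetic_config <- function(roi_size_px = 64L,
                             pixel_spacing_mm = 370 / 512,
                             n_signal_absent = 90L,
                             n_signal_present = 40L,
                             lesion_fwhm_mm = 5,
                             lesion_amplitude_hu = 20,
                             background_hu = 0,
                             noise_sd_hu = 10,
                             noise_model = c("white", "correlated"),
                             correlation_exponent = 1,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot_scalar_num(roi_size_px, "roi_size_px", positive = TRUE, integer = TRUE)
  stopifnot_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  stopifnot_scalar_num(n_signal_absent, "n_signal_absent", integer = TRUE)
  stopifnot_scalar_num(n_signal_present, "n_signal_present", integer = TRUE)
  stopifnot_scalar_num(lesion_fwhm_mm, "lesion_fwhm_mm", positive = TRUE)
  stopifnot_scalar_num(lesion_amplitude_hu, "lesion_amplitude_hu")
  stopifnot_scalar_num(background_hu, "background_hu")
  stopifnot_scalar_num(noise_sd_hu, "noise_sd_hu")
  stopifnot_scalar_num(correlation_exponent, "correlation_exponent")
  stopifnot_scalar_num(seed, "seed", integer = TRUE)
  if (roi_size_px < 8L)
    stop("`roi_size_px` must be >= 8", call. = FALSE)
  if (n_signal_absent < 2L)
    stop("`n_signal_absent` must be >= 2 (covariance estimation)", call. = FALSE)
  if (n_signal_present < 0L)
    stop("`n_signal_present` must be >= 0", call. = FALSE)
  if (noise_sd_hu < 0)
    stop("`noise_sd_hu` must be >= 0", call. = FALSE)
  if (lesion_fwhm_mm / pixel_spacing_mm < 2)
    stop("lesion FWHM must span at least 2 pixels (lesion_fwhm_mm / pixel_spacing_mm >= 2)",
         call. = FALSE)
  structure(list(
    roi_size_px = as.integer(roi_size_px),
    pixel_spacing_mm = pixel_spacing_mm,
    n_signal_absent = as.integer(n_signal_absent),
    n_signal_present = as.integer(n_signal_present),
    lesion_fwhm_mm = lesion_fwhm_mm,
    lesion_amplitude_hu = lesion_amplitude_hu,
    background_hu = background_hu,
    noise_sd_hu = noise_sd_hu,
    noise_model = noise_model,
    correlation_exponent = correlation_exponent,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Phantom-size presets for the three reconstruction fields of view
#'
#' The three abdominal phantom sizes were reconstructed at 320, 370 and 420 mm
#' FOV. The acquisition matrix size is not fixed by the protocol; a 512 matrix
#' is assumed (configurable), giving pixel spacings 0.625, ~0.7227 and
#' ~0.8203 mm for small/medium/large.
#'
#' @param size `"small"`, `"medium"` or `"large"`.
#' @param matrix_size assumed reconstruction matrix (default 512).
#' @param ... further arguments passed to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
phantom_preset <- function(size = c("small", "medium", "large"),
                           matrix_size = 512L, ...) {
  size <- match.arg(size)
  fov <- c(small = 320, medium = 370, large = 420)[[size]]
  synthetic_config(pixel_spacing_mm = fov / matrix_size, ...)
}

#' Centred 2-D Gaussian lesion field
#'
#' Evaluates amplitude * exp(-d^2 / (2 sigma^2)) at every pixel, where d is the
#' physical distance (mm) from the ROI centre pixel and
#' sigma = fwhm / (2 sqrt(2 ln 2)). The centre pixel is row/column
#' `floor(N/2)` in 0-based coordinates and holds the exact maximum.
#'
#' @param roi_size_px ROI side length in pixels.
#' @param pixel_spacing_mm pixel pitch in mm.
#' @param fwhm_mm full width at half maximum in mm.
#' @param amplitude_hu peak amplitude in HU.
#' @return a `roi_size_px` x `roi_size_px` numeric matrix.
#' @examples
#' s <- make_gaussian_signal(64, 370 / 512, 5, 20)
#' max(s)  # 20 at the centre pixel
#' @export
make_gaussian_signal <- function(roi_size_px, pixel_spacing_mm, fwhm_mm,
                                 amplitude_hu) {
  stopifnot_scalar_num(roi_size_px, "roi_size_px", positive = TRUE, integer = TRUE)
  stopifnot_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  stopifnot_scalar_num(fwhm_mm, "fwhm_mm", positive = TRUE)
  stopifnot_scalar_num(amplitude_hu, "amplitude_hu")
  n <- as.integer(roi_size_px)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  centre <- floor(n / 2)                       # 0-based centre index
  x <- (seq_len(n) - 1L - centre) * pixel_spacing_mm
  d2 <- outer(x^2, x^2, `+`)
  amplitude_hu * exp(-d2 / (2 * sigma^2))
}

#' Stationary Gaussian noise field
#'
#' Draws a zero-mean Gaussian noise matrix from the current RNG stream. The
#' white model has i.i.d. pixels with the requested SD. The correlated model
#' shapes a white field in the frequency domain with a radially symmetric
#' filter proportional to f^(exponent/2), with the DC bin forced to exactly
#' zero and a cosine taper from 60% of Nyquist to Nyquist; the filter is
#' normalised so the per-pixel SD equals `noise_sd_hu` in expectation.
#'
#' Uses (and advances) the current RNG state; seed control belongs to the
#' caller, see [generate_dataset()].
#'
#' @param roi_size_px field side length in pixels.
#' @param noise_model `"white"` or `"correlated"`.
#' @param noise_sd_hu target per-pixel SD (>= 0; 0 yields an all-zero field).
#' @param correlation_exponent radial filter exponent (correlated model only).
#' @return a square numeric matrix.
#' @export
make_noise_field <- function(roi_size_px, noise_model = c("white", "correlated"),
                             noise_sd_hu = 10, correlation_exponent = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot_scalar_num(roi_size_px, "roi_size_px", positive = TRUE, integer = TRUE)
  stopifnot_scalar_num(noise_sd_hu, "noise_sd_hu")
  if (noise_sd_hu < 0) stop("`noise_sd_hu` must be >= 0", call. = FALSE)
  n <- as.integer(roi_size_px)
  if (noise_sd_hu == 0) return(matrix(0, n, n))
  white <- matrix(rnorm(n * n, sd = noise_sd_hu), n, n)
  if (noise_model == "white") return(white)
  h <- correlated_noise_filter(n, correlation_exponent)
  shaped <- fft(fft(white) * h, inverse = TRUE) / (n * n)
  Re(shaped)
}

# Radial power-law filter on the unshifted DFT grid, DC exactly zero, cosine
# apodisation from 0.6 * Nyquist to Nyquist (zero beyond), unit mean power so
# the filtered field keeps the input pixel variance in expectation.
correlated_noise_filter <- function(n, exponent) {
  f <- radial_freq_grid(n)
  h <- f^(exponent / 2)
  h[1, 1] <- 0
  fn <- 0.5
  taper <- ifelse(f <= 0.6 * fn, 1,
                  ifelse(f >= fn, 0, 0.5 * (1 + cos(pi * (f - 0.6 * fn) / (0.4 * fn)))))
  h <- h * taper
  h / sqrt(mean(h^2))
}

#' Construct one ROI image
#'
#' The common container shared by the synthetic generator and the DICOM ROI
#' extractor: a square HU pixel matrix with physical spacing and a class label.
#'
#' @param pixels square numeric matrix of finite HU values.
#' @param pixel_spacing_mm pixel pitch in mm.
#' @param label `"signal_absent"` or `"signal_present"`.
#' @param lesion_diameter_mm nominal lesion diameter (signal-present only).
#' @param source_id free-text provenance tag.
#' @return an object of class `roi_image`.
#' @export
roi_image <- function(pixels, pixel_spacing_mm,
                      label = c("signal_absent", "signal_present"),
                      lesion_diameter_mm = NULL, source_id = "") {
  label <- match.arg(label)
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop("`pixels` must be a square matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("`pixels` must be finite-valued", call. = FALSE)
  stopifnot_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  if (label == "signal_absent" && !is.null(lesion_diameter_mm))
    stop("signal_absent ROIs carry no lesion diameter", call. = FALSE)
  if (!is.null(lesion_diameter_mm))
    stopifnot_scalar_num(lesion_diameter_mm, "lesion_diameter_mm", positive = TRUE)
  if (!is.null(lesion_diameter_mm))
    lesion_diameter_mm <- as.numeric(lesion_diameter_mm)
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 label = label, lesion_diameter_mm = lesion_diameter_mm,
                 source_id = as.character(source_id)),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image %dx%d px @ %.4f mm, %s%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_mm, x$label,
              if (is.null(x$lesion_diameter_mm)) ""
              else sprintf(", lesion %g mm", x$lesion_diameter_mm)))
  invisible(x)
}

#' Generate a labelled synthetic ROI dataset
#'
#' Realises the configured design: `n_signal_absent` noise-only ROIs followed
#' by `n_signal_present` ROIs carrying the centred Gaussian lesion. Every ROI
#' is `background + noise` (+ `signal` for the present class) with independent
#' noise fields; the whole list is bit-reproducible given the seed.
#'
#' @param config a [synthetic_config()].
#' @return a list of [roi_image()] objects, signal-absent first; the list
#'   carries the config as attribute `"config"`.
#' @examples
#' rois <- generate_dataset(synthetic_config(seed = 7))
#' table(vapply(rois, `[[`, "", "label"))  # 90 absent / 40 present
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mats <- generate_image_matrix(config)
  n <- config$roi_size_px
  labels <- attr(mats, "labels")
  rois <- lapply(seq_len(nrow(mats)), function(i) {
    present <- labels[i] == "signal_present"
    roi_image(matrix(mats[i, ], n, n),
              pixel_spacing_mm = config$pixel_spacing_mm,
              label = labels[i],
              lesion_diameter_mm = if (present) config$lesion_fwhm_mm else NULL,
              source_id = sprintf("synthetic:seed%d:%03d", config$seed, i))
  })
  attr(rois, "config") <- config
  rois
}

#' Generate the synthetic dataset as a flat image matrix
#'
#' Fast path for large simulations: identical generation maths (and identical
#' pixel values, given the same config) as [generate_dataset()], but returns
#' one row per ROI (vectorised column-major pixels) instead of a list of
#' objects. Row order is signal-absent first, then signal-present; labels in
#' attribute `"labels"`.
#'
#' @param config a [synthetic_config()].
#' @return an (n_absent + n_present) x roi_size_px^2 numeric matrix.
#' @export
generate_image_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$roi_size_px
  n_tot <- config$n_signal_absent + config$n_signal_present
  signal <- make_gaussian_signal(n, config$pixel_spacing_mm,
                                 config$lesion_fwhm_mm, config$lesion_amplitude_hu)
  sig_vec <- as.numeric(signal)
  out <- with_seed(config$seed, {
    m <- matrix(0, n_tot, n * n)
    for (i in seq_len(n_tot)) {
      noise <- make_noise_field(n, config$noise_model, config$noise_sd_hu,
                                config$correlation_exponent)
      row <- config$background_hu + as.numeric(noise)
      if (i > config$n_signal_absent) row <- row + sig_vec
      m[i, ] <- row
    }
    m
  })
  attr(out, "labels") <- rep(c("signal_absent", "signal_present"),
                             c(config$n_signal_absent, config$n_signal_present))
  attr(out, "roi_size_px") <- n
  attr(out, "pixel_spacing_mm") <- config$pixel_spacing_mm
  out
}
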