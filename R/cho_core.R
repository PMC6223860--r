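#' Dense difference-of-Gaussian channel parameters
#'
#' The channel bank is a geometric sequence of radial bandpass filters:
#' channel j has response
#' `C_j(rho) = exp(-0.5 (rho / (Q sigma_j))^2) - exp(-0.5 (rho / sigma_j)^2)`
#' with `sigma_j = sigma0 * alpha^(j-1)`. Defaults are the standard dense DDoG
#' setting: sigma0 = 0.005, alpha = 1.4, Q = 1.67, J = 10 channels. sigma_j is
#' interpreted in cycles/pixel (the convention of the DDoG literature these
#' defaults come from).
#'
#' @param sigma0 base channel width, cycles/pixel (> 0).
#' @param alpha geometric ratio between consecutive channel widths (> 1).
#' @param Q filter bandwidth (> 1).
#' @param n_channels number of channels J (>= 1).
#' @return an object of class `channel_params`.
#' @export
channel_params <- function(sigma0 = 0.005, alpha = 1.4, Q = 1.67,
                           n_channels = 10L) {
  stopifnot_scalar_num(sigma0, "sigma0", positive = TRUE)
  stopifnot_scalar_num(alpha, "alpha", positive = TRUE)
  stopifnot_scalar_num(Q, "Q", positive = TRUE)
  stopifnot_scalar_num(n_channels, "n_channels", positive = TRUE, integer = TRUE)
  if (alpha <= 1) stop("`alpha` must be > 1 (widths strictly increasing)", call. = FALSE)
  if (Q <= 1) stop("`Q` must be > 1", call. = FALSE)
  structure(list(sigma0 = sigma0, alpha = alpha, Q = Q,
                 n_channels = as.integer(n_channels)),
            class = "channel_params")
}

channel_sigmas <- function(params) {
  params$sigma0 * params$alpha^(seq_len(params$n_channels) - 1)
}

#' DDoG channel frequency response
#'
#' @param rho radial spatial frequency, cycles/pixel (vectorised, >= 0).
#' @param j channel index in 1..J.
#' @param params a [channel_params()].
#' @return numeric vector of responses; exactly 0 at rho = 0.
#' @examples
#' ddog_response(0.01, 3, channel_params())
#' @export
ddog_response <- function(rho, j, params = channel_params()) {
  stopifnot(inherits(params, "channel_params"))
  stopifnot_scalar_num(j, "j", positive = TRUE, integer = TRUE)
  if (j > params$n_channels)
    stop(sprintf("channel index j = %d out of range 1..%d", j, params$n_channels),
         call. = FALSE)
  if (any(rho < 0)) stop("`rho` must be >= 0", call. = FALSE)
  sj <- params$sigma0 * params$alpha^(j - 1)
  exp(-0.5 * (rho / (params$Q * sj))^2) - exp(-0.5 * (rho / sj)^2)
}

#' Build the channel bank for a given ROI size
#'
#' Samples each channel's radial response at the frequency of every DFT bin of
#' an N x N ROI (bins at k/N cycles/pixel per axis), forces the DC bin to
#' exactly zero, and obtains the real spatial template by inverse DFT. The
#' spatial templates form the (N^2) x J matrix U used by [channelize()].
#'
#' @param roi_size_px ROI side length in pixels (>= 8).
#' @param params a [channel_params()].
#' @return an object of class `channel_bank` with elements `params`,
#'   `roi_size_px`, `U` (spatial templates, one column per channel) and
#'   `freq_responses` (N x N x J array of sampled responses, unshifted DFT
#'   ordering).
#' @export
build_channel_bank <- function(roi_size_px, params = channel_params()) {
  stopifnot_scalar_num(roi_size_px, "roi_size_px", positive = TRUE, integer = TRUE)
  if (roi_size_px < 8L) stop("`roi_size_px` must be >= 8", call. = FALSE)
  stopifnot(inherits(params, "channel_params"))
  n <- as.integer(roi_size_px)
  rho <- radial_freq_grid(n)
  J <- params$n_channels
  U <- matrix(0, n * n, J)
  fr <- array(0, dim = c(n, n, J))
  for (j in seq_len(J)) {
    cj <- ddog_response_grid(rho, j, params)
    cj[1, 1] <- 0                       # DC response exactly zero
    fr[, , j] <- cj
    # responses are real and even on the grid, so the inverse DFT is real
    U[, j] <- as.numeric(Re(fft(cj, inverse = TRUE))) / (n * n)
  }
  structure(list(params = params, roi_size_px = n, U = U,
                 freq_responses = fr),
            class = "channel_bank")
}

# vectorised-over-grid variant of ddog_response (no per-call validation)
ddog_response_grid <- function(rho, j, params) {
  sj <- params$sigma0 * params$alpha^(j - 1)
  exp(-0.5 * (rho / (params$Q * sj))^2) - exp(-0.5 * (rho / sj)^2)
}

#' @export
print.channel_bank <- function(x, ...) {
  cat(sprintf("<channel_bank J=%d, %dx%d px, sigma0=%g alpha=%g Q=%g>\n",
              x$params$n_channels, x$roi_size_px, x$roi_size_px,
              x$params$sigma0, x$params$alpha, x$params$Q))
  invisible(x)
}

#' Channelise a set of images
#'
#' Projects each image onto the spatial channel templates: row i of the result
#' is t(U) g_i for vectorised image g_i. Accepts a list of [roi_image()]
#' objects, a single matrix image, or a flat image matrix (rows = vectorised
#' images) as produced by [generate_image_matrix()].
#'
#' @param images list of `roi_image`, one N x N matrix, or an n x N^2 matrix.
#' @param bank a [channel_bank()] whose `roi_size_px` matches the images.
#' @return an n x J numeric matrix of channel vectors (class
#'   `channelised_set`), with a `"labels"` attribute when the input carries
#'   labels.
#' @export
channelize <- function(images, bank) {
  stopifnot(inherits(bank, "channel_bank"))
  n <- bank$roi_size_px
  labels <- NULL
  if (inherits(images, "roi_image")) images <- list(images)
  if (is.list(images)) {
    for (i in seq_along(images)) {
      p <- images[[i]]$pixels
      if (nrow(p) != n || ncol(p) != n)
        stop(sprintf("image %d is %dx%d but the bank expects %dx%d",
                     i, nrow(p), ncol(p), n, n), call. = FALSE)
    }
    labels <- vapply(images, `[[`, "", "label")
    g <- t(vapply(images, function(im) as.numeric(im$pixels), numeric(n * n)))
  } else if (is.matrix(images) && nrow(images) == n && ncol(images) == n) {
    g <- matrix(as.numeric(images), 1L)
  } else if (is.matrix(images) && ncol(images) == n * n) {
    g <- images
    labels <- attr(images, "labels")
  } else {
    stop("`images` does not match the bank's ROI size", call. = FALSE)
  }
  v <- g %*% bank$U
  colnames(v) <- paste0("ch", seq_len(ncol(v)))
  structure(v, labels = labels, class = c("channelised_set", "matrix", "array"))
}

#' Signal-absent channel covariance
#'
#' Sample covariance of the channel vectors with mean subtraction and
#' denominator (n - 1); symmetric by construction.
#'
#' @param vset an n x J matrix of channel vectors (n >= 2).
#' @return a J x J symmetric covariance matrix K.
#' @export
estimate_covariance <- function(vset) {
  v <- unclass(vset)
  if (!is.matrix(v) || !is.numeric(v))
    stop("`vset` must be a numeric matrix of channel vectors", call. = FALSE)
  if (nrow(v) < 2L)
    stop("covariance estimation needs at least 2 channelised images", call. = FALSE)
  k <- stats::cov(v)
  (k + t(k)) / 2
}

#' Channelised theoretical lesion signal
#'
#' Builds the centred Gaussian lesion image (same construction as
#' [make_gaussian_signal()]) and channelises it. The default unit amplitude is
#' deliberate: the downstream AUC is invariant to template scale, and unit
#' amplitude keeps the template solve well scaled.
#'
#' @param bank a [channel_bank()].
#' @param fwhm_mm lesion FWHM in mm (default 5).
#' @param pixel_spacing_mm pixel pitch in mm.
#' @param amplitude signal peak amplitude (default 1).
#' @return a J-vector v_theo.
#' @export
theoretical_signal_channelised <- function(bank, fwhm_mm = 5, pixel_spacing_mm,
                                           amplitude = 1) {
  stopifnot(inherits(bank, "channel_bank"))
  stopifnot_scalar_num(fwhm_mm, "fwhm_mm", positive = TRUE)
  stopifnot_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  stopifnot_scalar_num(amplitude, "amplitude")
  if (fwhm_mm / pixel_spacing_mm < 2)
    warning("lesion FWHM spans fewer than 2 pixels; aliasing risk", call. = FALSE)
  sig <- make_gaussian_signal(bank$roi_size_px, pixel_spacing_mm, fwhm_mm,
                              amplitude)
  as.numeric(channelize(sig, bank))
}

#' Hotelling template from covariance and channelised signal
#'
#' Solves (K + ridge I) w = v_theo by a symmetric (Cholesky) solve — no
#' explicit inverse. The reciprocal condition number of the regularised
#' covariance is attached as attribute `"rcond"`; a condition number above
#' 1e12 raises a singular-covariance error advising a ridge or more
#' signal-absent images.
#'
#' @param K J x J symmetric covariance.
#' @param v_theo J-vector channelised signal.
#' @param ridge non-negative ridge added to the diagonal (default 0).
#' @return the template w (J-vector) with attribute `"rcond"`.
#' @export
build_template <- function(K, v_theo, ridge = 0) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("`K` must be a square matrix", call. = FALSE)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("`K` must be symmetric", call. = FALSE)
  stopifnot_scalar_num(ridge, "ridge")
  if (ridge < 0) stop("`ridge` must be >= 0", call. = FALSE)
  if (length(v_theo) != nrow(K))
    stop("`v_theo` length must match dim(K)", call. = FALSE)
  Kr <- (K + t(K)) / 2 + diag(ridge, nrow(K))
  rc <- tryCatch(rcond(Kr), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12)
    stop(paste("covariance matrix is singular or near-singular",
               "(condition number > 1e12); add a ridge or supply more",
               "signal-absent images"), call. = FALSE)
  ch <- chol(Kr)
  w <- backsolve(ch, forwardsolve(t(ch), v_theo))
  attr(w, "rcond") <- rc
  w
}

#' Decision variables for both image classes
#'
#' Scores every channelised image with the template: lambda = t(w) v. Output
#' ordering matches input ordering; in the standard design this yields 90
#' signal-absent and 40 signal-present scores.
#'
#' @param w template J-vector.
#' @param absent channelised signal-absent set (n0 x J).
#' @param present channelised signal-present set (n1 x J).
#' @return an object of class `score_set`: list with `lambda_absent` and
#'   `lambda_present`.
#' @export
decision_variables <- function(w, absent, present) {
  w <- as.numeric(w)
  a <- unclass(absent); p <- unclass(present)
  if (!is.matrix(a) || ncol(a) != length(w))
    stop("`absent` channel dimension does not match the template", call. = FALSE)
  if (!is.matrix(p) || ncol(p) != length(w))
    stop("`present` channel dimension does not match the template", call. = FALSE)
  structure(list(lambda_absent = as.numeric(a %*% w),
                 lambda_present = as.numeric(p %*% w)),
            class = "score_set")
}

#' Fit a CHO model on signal-absent images
#'
#' Convenience wrapper bundling covariance estimation, theoretical-signal
#' channelisation and the template solve. An optional mean-signal mode uses
#' the empirical mean difference between classes instead of the theoretical
#' Gaussian (the theoretical signal is the default because it avoids
#' overfitting the small signal-present sample).
#'
#' @param absent channelised signal-absent set, or a list of signal-absent
#'   `roi_image`s (channelised internally).
#' @param bank the [channel_bank()] used.
#' @param pixel_spacing_mm pixel pitch in mm (needed for the theoretical
#'   signal).
#' @param fwhm_mm lesion FWHM in mm (default 5).
#' @param amplitude theoretical-signal amplitude (default 1; AUC-invariant).
#' @param ridge ridge for the template solve (default 0).
#' @param signal_mode `"theoretical"` (default) or `"mean"`; the mean mode
#'   requires `present`.
#' @param present channelised signal-present set, only for `signal_mode =
#'   "mean"`.
#' @return an object of class `cho_model`: list with `bank`, `K`, `v_theo`,
#'   `w`, `ridge`.
#' @export
fit_cho <- function(absent, bank, pixel_spacing_mm, fwhm_mm = 5, amplitude = 1,
                    ridge = 0, signal_mode = c("theoretical", "mean"),
                    present = NULL) {
  signal_mode <- match.arg(signal_mode)
  if (is.list(absent) && !is.matrix(absent)) absent <- channelize(absent, bank)
  K <- estimate_covariance(absent)
  v_theo <- if (signal_mode == "theoretical") {
    theoretical_signal_channelised(bank, fwhm_mm, pixel_spacing_mm, amplitude)
  } else {
    if (is.null(present))
      stop("`signal_mode = \"mean\"` requires the signal-present set", call. = FALSE)
    if (is.list(present) && !is.matrix(present)) present <- channelize(present, bank)
    colMeans(unclass(present)) - colMeans(unclass(absent))
  }
  w <- build_template(K, v_theo, ridge)
  structure(list(bank = bank, K = K, v_theo = v_theo, w = w, ridge = ridge),
            class = "cho_model")
}

#' @export
print.cho_model <- function(x, ...) {
  cat(sprintf("<cho_model J=%d, ridge=%g, rcond(K)=%.3g>\n",
              length(x$w), x$ridge, attr(x$w, "rcond")))
  invisible(x)
}

#' Analytic CHO performance for known statistics
#'
#' Validation oracle: for Gaussian channel noise with true covariance K and a
#' known channelised signal, the ideal linear observer's detectability is
#' SNR^2 = t(v) solve(K) v and its AUC is pnorm(SNR / sqrt(2)).
#'
#' @param K_true true channel covariance (positive definite).
#' @param v_signal channelised signal J-vector.
#' @return the AUC in `[0.5, 1)`.
#' @export
analytic_cho_auc <- function(K_true, v_signal) {
  if (!is.matrix(K_true) || nrow(K_true) != ncol(K_true))
    stop("`K_true` must be square", call. = FALSE)
  ev <- eigen((K_true + t(K_true)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("`K_true` must be positive definite", call. = FALSE)
  snr2 <- sum(v_signal * solve((K_true + t(K_true)) / 2, v_signal))
  pnorm(sqrt(snr2) / sqrt(2))
}

#' Run the full CHO assessment on one labelled ROI dataset
#'
#' Channelises both classes, fits the template on the signal-absent class,
#' scores every image and returns the bootstrap AUC summary — the per-dataset
#' figure of merit of the whole pipeline.
#'
#' @param rois list of labelled [roi_image()]s, or a flat labelled image
#'   matrix from [generate_image_matrix()].
#' @param bank optional [channel_bank()]; built from the ROI size if missing.
#' @param fwhm_mm lesion FWHM for the theoretical signal (default 5 mm).
#' @param pixel_spacing_mm pixel pitch; taken from the data when available.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed bootstrap seed.
#' @param ridge template ridge (default 0).
#' @return an `auc_result`, see [bootstrap_auc()].
#' @export
run_cho_study <- function(rois, bank = NULL, fwhm_mm = 5,
                          pixel_spacing_mm = NULL, n_boot = 500L, seed = 1L,
                          ridge = 0) {
  if (is.matrix(rois)) {
    labels <- attr(rois, "labels")
    n_px <- attr(rois, "roi_size_px")
    if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- attr(rois, "pixel_spacing_mm")
    if (is.null(labels) || is.null(n_px))
      stop("flat image matrix must carry `labels` and `roi_size_px` attributes",
           call. = FALSE)
    if (is.null(bank)) bank <- build_channel_bank(n_px)
    v <- channelize(rois, bank)
  } else {
    labels <- vapply(rois, `[[`, "", "label")
    if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- rois[[1]]$pixel_spacing_mm
    if (is.null(bank)) bank <- build_channel_bank(nrow(rois[[1]]$pixels))
    v <- channelize(rois, bank)
  }
  if (is.null(pixel_spacing_mm))
    stop("`pixel_spacing_mm` is required", call. = FALSE)
  absent <- v[labels == "signal_absent", , drop = FALSE]
  present <- v[labels == "signal_present", , drop = FALSE]
  model <- fit_cho(absent, bank, pixel_spacing_mm, fwhm_mm, ridge = ridge)
  scores <- decision_variables(model$w, absent, present)
  bootstrap_auc(scores$lambda_absent, scores$lambda_present,
                n_boot = n_boot, seed = seed)
}
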