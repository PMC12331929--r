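#' Laser pulses integrated per pixel
#'
#' `floor(dwell x repetition rate)`: 4 pulses/pixel at 20 us dwell and
#' 200 kHz.
#'
#' @param scan a [scan_config()].
#' @return integer pulse count (>= 1).
#' @export
pulses_per_pixel <- function(scan) {
  n <- floor(scan$dwell_us * 1e-6 * scan$rep_rate_khz * 1e3)
  if (n < 1) stop("scan gives < 1 pulse per pixel (configuration error)")
  as.integer(n)
}

#' Frame period and frame rate
#'
#' `pixels x lines x dwell` (scanner turnaround ignored: the printed
#' 0.76 frame/s at 256 x 256 and 20 us equals the flyback-free product).
#'
#' @param scan a [scan_config()].
#' @return list with `period_s` and `rate_hz`.
#' @export
frame_period <- function(scan) {
  period <- scan$pixels * scan$lines * scan$dwell_us * 1e-6
  list(period_s = period, rate_hz = 1 / period)
}

#' Reconstructed photoacoustic image container
#'
#' @param pixels lines x pixels numeric matrix (mV).
#' @param pitch_um_per_px pixel pitch, um/pixel.
#' @param channel `"PA"`, `"optical"` or `"fiducial"`.
#' @param provenance named list (config hash, seed, source frames, ...).
#' @return an object of class `"pa_image"`.
#' @export
pa_image <- function(pixels, pitch_um_per_px, channel = "PA",
                     provenance = list()) {
  if (!all(is.finite(pixels))) stop("image pixels must be finite")
  if (pitch_um_per_px <= 0) stop("pixel pitch must be positive")
  structure(list(pixels = pixels, pitch_um_per_px = pitch_um_per_px,
                 channel = channel, provenance = provenance),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("pa_image [%s]: %d x %d px at %.3g um/px, range %.3g-%.3g\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pitch_um_per_px,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Assemble an image from a per-pixel trace set
#'
#' Pixel value = mean over that pixel's pulses of the gated amplitude
#' statistic of each trace (the real-time windowed-average pipeline), in
#' row-major raster order matching the scan.
#'
#' @param rts a `"raw_trace_set"` from [simulate_scan()].
#' @param statistic passed to [gated_peak()].
#' @return a [pa_image()] (channel `"PA"`).
#' @export
assemble_image <- function(rts, statistic = "peak_to_peak") {
  d <- dim(rts$traces)
  scan <- rts$scan
  if (d[3] < pulses_per_pixel(scan))
    stop("trace set has fewer pulses per pixel than the scan requires ",
         "(completeness error)")
  img <- matrix(0, nrow = d[1], ncol = d[2])
  for (iy in seq_len(d[1])) {
    for (ix in seq_len(d[2])) {
      vals <- vapply(seq_len(d[3]), function(ip) {
        gated_peak(raw_trace(rts$traces[iy, ix, ip, ], fs_ghz = rts$fs_ghz),
                   rts$gate_start_us, scan$gate_width_us, statistic)
      }, numeric(1))
      img[iy, ix] <- mean(vals)
    }
  }
  pa_image(img, rts$pitch_um_per_px, channel = "PA",
           provenance = list(seed = rts$seed,
                             pulses_per_pixel = d[3],
                             statistic = statistic,
                             focus_depth_um = rts$focus_depth_um))
}

#' Optical-channel image from a trace set
#'
#' @param rts a `"raw_trace_set"` simulated with `optical = TRUE`.
#' @return a [pa_image()] (channel `"optical"`).
#' @export
optical_image <- function(rts) {
  if (is.null(rts$optical)) stop("trace set carries no optical channel")
  pa_image(rts$optical, rts$pitch_um_per_px, channel = "optical",
           provenance = list(seed = rts$seed,
                             focus_depth_um = rts$focus_depth_um))
}

#' Average registered frames
#'
#' Pixelwise mean of identically shaped frames; white pixel noise drops by
#' sqrt(n frames).
#'
#' @param frames list of [pa_image()] objects.
#' @return a [pa_image()] whose provenance lists the source frames.
#' @export
frame_average <- function(frames) {
  stopifnot(length(frames) >= 1)
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  pitches <- vapply(frames, function(f) f$pitch_um_per_px, numeric(1))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      diff(range(pitches)) > 1e-9)
    stop("frames have mismatched shapes or pitches (geometry error)")
  acc <- Reduce(`+`, lapply(frames, function(f) f$pixels)) / length(frames)
  pa_image(acc, frames[[1]]$pitch_um_per_px, channel = frames[[1]]$channel,
           provenance = list(n_frames = length(frames),
                             sources = lapply(frames,
                                              function(f) f$provenance)))
}

#' Lateral point-spread-function kernel
#'
#' The 2D heated-profile (intensity-to-the-n) lateral PSF of the excitation,
#' normalized to unit sum, for deconvolution.
#'
#' @param optics an [optics_config()].
#' @param pitch_um_per_px image pixel pitch, um.
#' @param extent_px kernel half-width, pixels (`NULL`: 2 FWHM).
#' @return normalized 2D kernel matrix (odd dimensions).
#' @export
psf_from_optics <- function(optics, pitch_um_per_px, extent_px = NULL) {
  if (is.null(extent_px))
    extent_px <- max(2L, ceiling(2 * optics$w_xy_um / pitch_um_per_px))
  ax <- (-extent_px:extent_px) * pitch_um_per_px
  rho2 <- outer(ax^2, ax^2, `+`)
  k <- exp(-4 * log(2) * rho2 / optics$w_xy_um^2)  # heated-profile FWHM w_xy
  k / sum(k)
}

# zero-padded linear 2D convolution via FFT, "same" size
conv2_same <- function(x, k) {
  nx <- dim(x); nk <- dim(k)
  np <- nx + nk - 1
  X <- stats::fft(rbind(cbind(x, matrix(0, nx[1], np[2] - nx[2])),
                        matrix(0, np[1] - nx[1], np[2])))
  K <- stats::fft(rbind(cbind(k, matrix(0, nk[1], np[2] - nk[2])),
                        matrix(0, np[1] - nk[1], np[2])))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / prod(np)
  off <- (nk - 1) %/% 2
  full[off[1] + seq_len(nx[1]), off[2] + seq_len(nx[2])]
}

#' Richardson-Lucy deconvolution
#'
#' Multiplicative Richardson-Lucy iteration with a boundary-renormalized
#' kernel, preserving non-negativity and total flux. Negative input pixels
#' (noise excursions) are clipped to zero with a warning.
#'
#' @param img a [pa_image()] or numeric matrix.
#' @param psf non-negative kernel, normalized internally to unit sum.
#' @param iterations iteration count (default 10).
#' @return same class as `img`, deconvolved.
#' @export
deconvolve <- function(img, psf, iterations = 10) {
  is_img <- inherits(img, "pa_image")
  x <- if (is_img) img$pixels else img
  if (any(psf < 0) || sum(psf) <= 0)
    stop("`psf` must be non-negative with positive sum (invalid argument)")
  psf <- psf / sum(psf)
  if (any(x < 0)) {
    if (min(x) < -1e-9 * max(abs(x)))
      warning("negative pixels clipped to zero before deconvolution")
    x[x < 0] <- 0
  }
  psf_flip <- psf[rev(seq_len(nrow(psf))), rev(seq_len(ncol(psf))),
                  drop = FALSE]
  # boundary correction: response of the kernel to a flat unit image
  ones <- matrix(1, nrow(x), ncol(x))
  norm <- conv2_same(ones, psf)
  est <- x
  eps <- .Machine$double.eps
  for (i in seq_len(iterations)) {
    blur <- conv2_same(est, psf) / norm
    ratio <- x / pmax(blur, eps)
    est <- est * (conv2_same(ratio, psf_flip) / norm)
  }
  if (is_img) {
    img$pixels <- est
    img$provenance$deconvolution <- list(method = "richardson-lucy",
                                         iterations = iterations)
    img
  } else est
}
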