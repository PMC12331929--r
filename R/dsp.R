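#' Average a set of aligned pulse traces
#'
#' Samplewise mean of the first `n` traces; the standard noise-reduction step
#' (the bench protocol averages 250 laser pulses, cutting white noise by
#' about sqrt(250) ~ 15.8x).
#'
#' @param traces list of [raw_trace()] objects, or a pulses x samples matrix.
#' @param n number of leading traces to average (default: all).
#' @return a [raw_trace()] (metadata from the first trace when available).
#' @export
average_pulses <- function(traces, n = NULL) {
  if (is.matrix(traces)) {
    m <- traces
    fs <- 2.0; t0 <- 0
  } else {
    lens <- vapply(traces, function(t) length(t$mv), integer(1))
    if (length(unique(lens)) != 1L)
      stop("traces have mismatched lengths (alignment error)")
    t0s <- vapply(traces, function(t) t$t0_us, numeric(1))
    if (diff(range(t0s)) > 1e-9)
      stop("traces have mismatched trigger times (alignment error)")
    m <- do.call(rbind, lapply(traces, function(t) t$mv))
    fs <- traces[[1]]$fs_ghz; t0 <- traces[[1]]$t0_us
  }
  if (is.null(n)) n <- nrow(m)
  if (n < 1 || n > nrow(m)) stop("`n` must be between 1 and the trace count")
  raw_trace(colMeans(m[seq_len(n), , drop = FALSE]), fs_ghz = fs, t0_us = t0)
}

# Morlet wavelet spectrum at ordinary frequency f (MHz) for a bank centered
# at f_j (MHz): psi_hat(s_j w) = exp(-omega0^2 (f/f_j - 1)^2 / 2)
morlet_response <- function(f_mhz, f_center_mhz, omega0) {
  exp(-omega0^2 * (f_mhz / f_center_mhz - 1)^2 / 2)
}

cwt_freq_grid <- function(f_lo, f_hi, voices) {
  n_oct <- log2(f_hi / f_lo)
  f_lo * 2^(seq(0, n_oct, by = 1 / voices))
}

#' Continuous-wavelet-transform scalogram of a trace
#'
#' Analytic Morlet CWT magnitude over a log-spaced frequency grid. The
#' per-scale normalization is flat in amplitude (a unit tone gives the same
#' ridge magnitude at every frequency), so the ridge maximum identifies the
#' dominant frequency of the A-scan directly.
#'
#' @param tr a [raw_trace()] or pressure trace.
#' @param f_lo_mhz,f_hi_mhz frequency band of the scalogram, MHz; must lie
#'   below Nyquist.
#' @param voices scales per octave (frequency resolution of the grid).
#' @param omega0 Morlet center-frequency parameter (time-frequency tradeoff).
#' @return an object of class `"pam_scalogram"`: `magnitude` (freq x time),
#'   `freq_mhz`, `time_us`, `peak_freq_mhz` (frequency of the global ridge
#'   maximum), `wavelet`, `omega0`.
#' @export
scalogram <- function(tr, f_lo_mhz = 10, f_hi_mhz = 200, voices = 32,
                      omega0 = 6) {
  x <- tr$mv %||% tr$pa
  n <- length(x)
  fs_mhz <- tr$fs_ghz * 1e3
  if (f_hi_mhz >= fs_mhz / 2 || f_lo_mhz <= 0 || f_lo_mhz >= f_hi_mhz)
    stop("scalogram band must satisfy 0 < f_lo < f_hi < Nyquist")
  freqs <- cwt_freq_grid(f_lo_mhz, f_hi_mhz, voices)
  X <- stats::fft(x)
  fbin <- seq(0, n - 1) * fs_mhz / n
  pos <- fbin <= fs_mhz / 2          # analytic wavelet: positive frequencies
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  for (j in seq_along(freqs)) {
    psi <- numeric(n)
    psi[pos] <- morlet_response(fbin[pos], freqs[j], omega0)
    W <- stats::fft(X * psi, inverse = TRUE) / n
    mag[j, ] <- Mod(W)
  }
  pk <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  structure(
    list(magnitude = mag, freq_mhz = freqs,
         time_us = trace_time_us(tr),
         peak_freq_mhz = freqs[pk[1]],
         peak_time_us = trace_time_us(tr)[pk[2]],
         wavelet = "morlet", omega0 = omega0),
    class = "pam_scalogram"
  )
}

#' @export
print.pam_scalogram <- function(x, ...) {
  cat(sprintf(
    "scalogram (%s, omega0 %g): %d scales %.3g-%.3g MHz x %d samples\n",
    x$wavelet, x$omega0, length(x$freq_mhz), min(x$freq_mhz),
    max(x$freq_mhz), ncol(x$magnitude)))
  cat(sprintf("  ridge peak: %.3g MHz at %.3g us\n", x$peak_freq_mhz,
              x$peak_time_us))
  invisible(x)
}

#' Band-limited inverse-CWT denoising
#'
#' Reconstructs the trace from only those wavelet coefficients whose center
#' frequencies lie inside `[f_lo, f_hi]` (the standard trace-denoising step,
#' e.g. extracting the 50-90 MHz photoacoustic band). Summing the in-band
#' Morlet coefficients is a linear time-invariant operation, so it is applied
#' as its exact equivalent frequency response, normalized to unit in-band
#' gain; in-band components are preserved, out-of-band components are
#' suppressed by the Gaussian wavelet roll-off.
#'
#' @inheritParams scalogram
#' @return a trace of the same class as `tr`.
#' @export
band_denoise <- function(tr, f_lo_mhz = 50, f_hi_mhz = 90, voices = 32,
                         omega0 = 6) {
  x <- tr$mv %||% tr$pa
  n <- length(x)
  fs_mhz <- tr$fs_ghz * 1e3
  if (f_hi_mhz >= fs_mhz / 2 || f_lo_mhz <= 0 || f_lo_mhz >= f_hi_mhz)
    stop("denoising band must satisfy 0 < f_lo < f_hi < Nyquist (empty band)")
  freqs <- cwt_freq_grid(f_lo_mhz, f_hi_mhz, voices)
  k <- seq(0, n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  f_abs <- abs(k) * fs_mhz / n
  G <- rowSums(vapply(freqs, function(fj) morlet_response(f_abs, fj, omega0),
                      numeric(n)))
  G <- G / max(G)
  y <- Re(stats::fft(stats::fft(x) * G, inverse = TRUE)) / n
  if (is.null(tr$mv)) tr$pa <- y else tr$mv <- y
  tr
}

#' Gated amplitude statistic of a trace
#'
#' The pixel-value primitive of image formation: a scalar statistic of the
#' samples inside a time gate `[t_start, t_start + width]` placed on the
#' expected acoustic arrival (delay line + travel time).
#'
#' @param tr a [raw_trace()] or pressure trace.
#' @param t_start_us gate start, us.
#' @param width_us gate width, us.
#' @param statistic `"peak_to_peak"` (default; robust to the bipolar pulses
#'   the bandpass produces), `"max_abs"`, or `"mean_abs"`.
#' @return scalar statistic in trace units.
#' @export
gated_peak <- function(tr, t_start_us, width_us,
                       statistic = c("peak_to_peak", "max_abs", "mean_abs")) {
  statistic <- match.arg(statistic)
  x <- tr$mv %||% tr$pa
  t <- trace_time_us(tr)
  eps <- 1e-9
  if (t_start_us < t[1] - eps || t_start_us + width_us > t[length(t)] + eps)
    stop("gate lies outside the trace (window error)")
  w <- x[t >= t_start_us - eps & t <= t_start_us + width_us + eps]
  switch(statistic,
         peak_to_peak = max(w) - min(w),
         max_abs = max(abs(w)),
         mean_abs = mean(abs(w)))
}

pam_fit <- function(estimates, se, r = NA_real_, r_squared = NA_real_,
                    residual_rms = NA_real_, flags = character(0)) {
  structure(list(estimates = estimates, se = se, r = r,
                 r_squared = r_squared, residual_rms = residual_rms,
                 flags = flags),
            class = "pam_fit")
}

#' @export
print.pam_fit <- function(x, ...) {
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %.6g (se %.3g)\n", nm, x$estimates[[nm]],
                x$se[[nm]]))
  if (!is.na(x$r)) cat(sprintf("  R = %.4f\n", x$r))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Power-law exponent fit
#'
#' Least-squares slope of `log(y)` against `log(x)`; the exponent check that
#' confirms the photon order of the excitation (cubic for three-photon).
#'
#' @param x strictly positive predictor (e.g. laser power, mW).
#' @param y strictly positive response (e.g. PA amplitude, mV).
#' @return a `"pam_fit"` with estimates `exponent` and `log_prefactor`.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y))
    stop("need >= 3 paired points")
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit requires strictly positive values (domain error)")
  fm <- stats::lm(log(y) ~ log(x))
  sm <- suppressWarnings(summary(fm))
  pam_fit(
    estimates = c(exponent = unname(stats::coef(fm)[2]),
                  log_prefactor = unname(stats::coef(fm)[1])),
    se = c(exponent = sm$coefficients[2, 2],
           log_prefactor = sm$coefficients[1, 2]),
    r_squared = sm$r.squared,
    residual_rms = sqrt(mean(stats::residuals(fm)^2))
  )
}

#' Linear calibration fit
#'
#' Ordinary least squares `y ~ x` with the Pearson correlation coefficient,
#' as used for the signal-vs-concentration calibration.
#'
#' @param x predictor (e.g. concentration, mM).
#' @param y response (e.g. amplitude, mV).
#' @return a `"pam_fit"` with estimates `slope` and `intercept`, plus `r`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y))
    stop("need >= 3 paired points")
  if (stats::sd(x) == 0) stop("degenerate predictor (rank error)")
  fm <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fm))
  pam_fit(
    estimates = c(slope = unname(stats::coef(fm)[2]),
                  intercept = unname(stats::coef(fm)[1])),
    se = c(slope = sm$coefficients[2, 2],
           intercept = sm$coefficients[1, 2]),
    r = stats::cor(x, y),
    r_squared = sm$r.squared,
    residual_rms = sqrt(mean(stats::residuals(fm)^2))
  )
}

#' Exponential depth-decay fit
#'
#' Log-linear fit `ln(y) ~ z`; the 1/e length is `-1/slope`. A non-negative
#' slope is flagged as non-decaying (infinite length).
#'
#' @param z_um depths, um.
#' @param y strictly positive amplitudes.
#' @return a `"pam_fit"` with estimate `length_um` (1/e length) and `slope`.
#' @export
fit_exp_decay <- function(z_um, y) {
  if (length(z_um) < 3 || length(z_um) != length(y))
    stop("need >= 3 paired points")
  if (any(y <= 0)) stop("decay fit requires positive amplitudes (domain error)")
  fm <- stats::lm(log(y) ~ z_um)
  sm <- suppressWarnings(summary(fm))
  slope <- unname(stats::coef(fm)[2])
  se_s <- sm$coefficients[2, 2]
  span <- diff(range(z_um))
  # non-decaying: slope non-negative, or a 1/e length far beyond what the
  # sweep span can resolve (less than 1% total decay over the sweep)
  if (slope >= -1e-12 || -1 / slope > 100 * span) {
    return(pam_fit(estimates = c(length_um = Inf, slope = slope),
                   se = c(length_um = NA_real_, slope = se_s),
                   r_squared = sm$r.squared, flags = "non_decaying"))
  }
  pam_fit(
    estimates = c(length_um = -1 / slope, slope = slope),
    se = c(length_um = se_s / slope^2, slope = se_s),
    r_squared = sm$r.squared,
    residual_rms = sqrt(mean(stats::residuals(fm)^2))
  )
}

#' Relative fluorescence change and pairwise correlation of ROI traces
#'
#' For each ROI time series the baseline is the mean of the lowest decile of
#' samples and `dF/F = (F - baseline)/baseline`; connectivity between ROIs is
#' summarized by the Pearson correlation matrix of the dF/F traces.
#'
#' @param roi_traces samples x ROI numeric matrix or data frame.
#' @param detrend if `TRUE`, remove a linear photobleaching trend (fit over
#'   time, re-centered to the trace mean) before computing dF/F.
#' @return list with `dff` (matrix), `correlation` (ROI x ROI), `baseline`.
#' @export
dff_and_correlation <- function(roi_traces, detrend = FALSE) {
  m <- as.matrix(roi_traces)
  if (nrow(m) < 2) stop("need >= 2 samples per ROI")
  if (detrend) {
    t <- seq_len(nrow(m))
    m <- apply(m, 2, function(f) f - stats::fitted(stats::lm(f ~ t)) + mean(f))
  }
  k <- max(1L, ceiling(0.1 * nrow(m)))
  baseline <- apply(m, 2, function(f) mean(sort(f)[seq_len(k)]))
  if (any(baseline == 0)) stop("zero baseline (degenerate-baseline error)")
  dff <- sweep(sweep(m, 2, baseline), 2, baseline, "/")
  cm <- suppressWarnings(stats::cor(dff))
  cm[is.na(cm)] <- 1 * (row(cm) == col(cm))[is.na(cm)]  # constant traces
  diag(cm) <- 1
  list(dff = dff, correlation = cm, baseline = baseline)
}
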