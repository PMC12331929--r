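#' Ultrasound transducer and receiver chain model
#'
#' The detection-side parameters: delay line, passband, element geometry,
#' sensitivity, amplifier gain and receiver filters, plus the output noise
#' level. Presets exist for the two bench units: a 125 MHz transducer
#' (passband 68-197 MHz) and a 75 MHz transducer (45-122 MHz), both with a
#' 0.125 inch element, a 2.6 us silica delay line and 140 uV/Pa sensitivity,
#' read out through a 20-150 MHz pulser-receiver at 63 dB gain.
#'
#' @param center_freq_mhz transducer center frequency, MHz.
#' @param passband_mhz length-2 transducer passband, MHz.
#' @param t_delay_us delay-line time, us.
#' @param sensitivity_uv_pa element sensitivity, uV/Pa (before the amplifier).
#' @param element_diameter_mm element diameter, mm.
#' @param standoff_mm focus-to-element standoff, mm.
#' @param gain_db amplifier gain, dB (63 dB is linear ~1412).
#' @param highpass_mhz,lowpass_mhz receiver filter corners, MHz.
#' @param noise_rms_mv white output noise RMS per single trace, mV.
#' @param fs_ghz acquisition sampling rate, GHz.
#' @param acceptance_diameter_um half-amplitude diameter of the lateral
#'   acceptance at the default standoff, um.
#' @return an object of class `"transducer_model"`.
#' @export
transducer_model <- function(center_freq_mhz = 125,
                             passband_mhz = c(68, 197),
                             t_delay_us = 2.6,
                             sensitivity_uv_pa = 140,
                             element_diameter_mm = 3.175,
                             standoff_mm = 0.5,
                             gain_db = 63,
                             highpass_mhz = 20, lowpass_mhz = 150,
                             noise_rms_mv = 20,
                             fs_ghz = 2.0,
                             acceptance_diameter_um = 100) {
  stopifnot(length(passband_mhz) == 2, passband_mhz[1] < passband_mhz[2],
            sensitivity_uv_pa > 0, standoff_mm > 0, t_delay_us >= 0,
            fs_ghz * 1000 > 2 * passband_mhz[2])
  structure(
    list(center_freq_mhz = center_freq_mhz, passband_mhz = passband_mhz,
         t_delay_us = t_delay_us, sensitivity_uv_pa = sensitivity_uv_pa,
         element_diameter_mm = element_diameter_mm, standoff_mm = standoff_mm,
         gain_db = gain_db, gain_linear = db_to_linear(gain_db),
         highpass_mhz = highpass_mhz, lowpass_mhz = lowpass_mhz,
         noise_rms_mv = noise_rms_mv, fs_ghz = fs_ghz,
         acceptance_diameter_um = acceptance_diameter_um),
    class = "transducer_model"
  )
}

#' @rdname transducer_model
#' @param preset `"125mhz"` or `"75mhz"`.
#' @param ... overrides passed to [transducer_model()].
#' @export
transducer_preset <- function(preset = c("125mhz", "75mhz"), ...) {
  preset <- match.arg(preset)
  if (preset == "125mhz") {
    transducer_model(center_freq_mhz = 125, passband_mhz = c(68, 197), ...)
  } else {
    transducer_model(center_freq_mhz = 75, passband_mhz = c(45, 122), ...)
  }
}

#' @export
print.transducer_model <- function(x, ...) {
  cat(sprintf(
    "transducer: %g MHz (passband %g-%g MHz), delay %g us, %g uV/Pa\n",
    x$center_freq_mhz, x$passband_mhz[1], x$passband_mhz[2], x$t_delay_us,
    x$sensitivity_uv_pa))
  cat(sprintf(
    "  receiver: %g-%g MHz, gain %g dB (x%.0f), noise %g mV RMS, fs %g GHz\n",
    x$highpass_mhz, x$lowpass_mhz, x$gain_db, x$gain_linear, x$noise_rms_mv,
    x$fs_ghz))
  invisible(x)
}

#' Voltage A-scan container
#'
#' A single per-pixel (or averaged) voltage time series with its sampling
#' rate and trigger time.
#'
#' @param mv numeric vector of voltage samples, mV.
#' @param fs_ghz sampling rate, GHz.
#' @param t0_us trigger time of the first sample, us.
#' @param pixel,pulse optional indices for provenance.
#' @return an object of class `"raw_trace"`.
#' @export
raw_trace <- function(mv, fs_ghz = 2.0, t0_us = 0, pixel = NULL,
                      pulse = NULL) {
  if (!all(is.finite(mv))) stop("trace samples must be finite")
  structure(list(mv = as.numeric(mv), fs_ghz = fs_ghz, t0_us = t0_us,
                 pixel = pixel, pulse = pulse),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("raw_trace: %d samples at %g GHz (%.3g us), %.3g mV pk-pk\n",
              length(x$mv), x$fs_ghz, length(x$mv) / (x$fs_ghz * 1e3),
              diff(range(x$mv))))
  invisible(x)
}

#' Time axis of a trace (us)
#' @param tr a [raw_trace()] or pressure trace.
#' @return numeric vector of sample times in us.
#' @export
trace_time_us <- function(tr) {
  tr$t0_us + (seq_along(tr$mv %||% tr$pa) - 1) / (tr$fs_ghz * 1e3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial photoacoustic pressure
#'
#' Stress-confined conversion of the per-pulse heat density into initial
#' pressure, `p0 = Gamma * H` voxelwise, with the Grueneisen parameter the
#' dimensionless thermoacoustic efficiency (default 0.2, water-like).
#'
#' @param H heat density array/vector, J/m^3.
#' @param grueneisen Grueneisen parameter.
#' @return initial pressure (Pa), same shape as `H`.
#' @export
initial_pressure <- function(H, grueneisen = 0.2) {
  if (any(H < 0)) stop("`H` must be non-negative")
  grueneisen * H
}

# Far-field source wavelet: derivative-of-Gaussian, peak amplitude 1.
# Spectral peak f_pk = c / (w_z/2): the generated center frequency is
# inversely proportional to the axial *radius* of the heated volume
# (100 MHz for the default 30 um axial FWHM at 1500 m/s).
source_wavelet <- function(t_s, w_z_um, c_m_s) {
  f_pk <- c_m_s / (w_z_um / 2 * 1e-6)   # Hz
  sigma <- 1 / (2 * pi * f_pk)
  -(t_s / sigma) * exp(0.5 - t_s^2 / (2 * sigma^2))
}

#' Far-field pressure trace from an initial pressure map
#'
#' Superposition of spherical-wave contributions from every source voxel:
#' `p(t) = sum_v (a_eff / r_v) * p0_v * s(t - r_v/c)` with `s` a normalized
#' derivative-of-Gaussian wavelet whose spectral peak is set by the axial
#' source dimension, and `r_v` the voxel-to-element distance. The element is
#' on the beam axis below the grid, at distance `r_mm` from the grid center.
#'
#' @param p0 3D initial pressure array (Pa) at pitch `pitch_um`.
#' @param pitch_um voxel pitch of `p0`, um.
#' @param r_mm distance from the grid center to the element, mm.
#' @param c_m_s sound speed, m/s.
#' @param fs_ghz sampling rate of the output trace, GHz.
#' @param duration_us trace duration, us; must contain all arrivals.
#' @param w_z_um axial source FWHM controlling the wavelet width, um.
#' @param a_eff_um effective source radius for the 1/r spreading factor, um
#'   (default: lateral source radius `w_z_um`-independent, 1.1 um).
#' @return a pressure trace: list with `pa` (Pa), `fs_ghz`, `t0_us = 0`,
#'   class `"pa_trace"`.
#' @export
farfield_trace <- function(p0, pitch_um, r_mm, c_m_s = 1500, fs_ghz = 2.0,
                           duration_us = 5, w_z_um = 30, a_eff_um = 1.1) {
  if (!is.array(p0) || length(dim(p0)) != 3L)
    stop("`p0` must be a 3D array")
  d <- dim(p0)
  ctr <- d * pitch_um / 2
  # element position: on axis, r_mm below the grid center
  elem <- c(ctr[1], ctr[2], ctr[3] + r_mm * 1e3)
  nt <- round(duration_us * 1e-6 * fs_ghz * 1e9)
  t_s <- (seq_len(nt) - 1) / (fs_ghz * 1e9)
  out <- numeric(nt)
  nz <- which(p0 > 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    xyz <- (nz - 0.5) * pitch_um
    dr <- sqrt((xyz[, 1] - elem[1])^2 + (xyz[, 2] - elem[2])^2 +
                 (xyz[, 3] - elem[3])^2)               # um
    if (any(dr * 1e-6 / c_m_s > duration_us * 1e-6 - 4e-8))
      stop("`duration_us` too short to contain all arrivals (window error)")
    amp <- (a_eff_um / dr) * p0[nz]
    tau <- dr * 1e-6 / c_m_s
    for (k in seq_len(nrow(nz)))
      out <- out + amp[k] * source_wavelet(t_s - tau[k], w_z_um, c_m_s)
  }
  structure(list(pa = out, fs_ghz = fs_ghz, t0_us = 0), class = "pa_trace")
}

#' Frequency-dependent acoustic attenuation
#'
#' Multiplies the trace spectrum by `10^(-a * d * f^b / 20)` (amplitude dB),
#' the standard soft-tissue power-law attenuation. The default coefficient
#' `a = 4/270 ~ 0.0148` dB/(mm*MHz) reproduces a -4 dB loss through 2.7 mm of cortex
#' at 100 MHz.
#'
#' @param tr a `"pa_trace"` or [raw_trace()].
#' @param d_mm propagation path length, mm (>= 0).
#' @param a attenuation coefficient, dB/(mm*MHz^b).
#' @param b frequency exponent.
#' @return trace of the same class, attenuated.
#' @export
attenuate_spectrum <- function(tr, d_mm, a = 4 / 270, b = 1) {
  if (d_mm < 0) stop("`d_mm` must be >= 0")
  if (d_mm == 0 || a == 0) return(tr)
  x <- tr$mv %||% tr$pa
  n <- length(x)
  k <- seq(0, n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  f_mhz <- abs(k) * tr$fs_ghz * 1e3 / n
  gain <- 10^(-a * d_mm * f_mhz^b / 20)
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  if (is.null(tr$mv)) tr$pa <- y else tr$mv <- y
  tr
}

#' Lateral acceptance weight of the transducer
#'
#' Smooth radially symmetric sensitivity of the fixed on-axis element to a
#' source displaced laterally by `rho_um`, modeled as a Gaussian with
#' half-amplitude diameter equal to the configured acceptance diameter
#' (about 100 um at the default standoff).
#'
#' @param rho_um lateral offset of the source from the element axis, um.
#' @param transducer a [transducer_model()].
#' @param r_mm source-element distance, mm (the acceptance is treated as
#'   constant over the sub-mm standoffs used).
#' @return weight in `(0, 1]`, 1 on axis.
#' @export
aperture_weight <- function(rho_um, transducer = transducer_model(),
                            r_mm = transducer$standoff_mm) {
  if (any(rho_um < 0)) stop("`rho_um` must be >= 0")
  rho_half <- transducer$acceptance_diameter_um / 2
  exp(-log(2) * (rho_um / rho_half)^2)
}

# receiver filter cascade: transducer passband then 20-150 MHz receiver,
# all zero-phase 2nd-order Butterworth sections
receiver_filter <- function(x, transducer) {
  fs_mhz <- transducer$fs_ghz * 1e3
  nyq <- fs_mhz / 2
  bp <- signal::butter(2, transducer$passband_mhz / nyq, type = "pass")
  hp <- signal::butter(2, transducer$highpass_mhz / nyq, type = "high")
  lp <- signal::butter(2, transducer$lowpass_mhz / nyq, type = "low")
  y <- signal::filtfilt(bp, x)
  y <- signal::filtfilt(hp, y)
  signal::filtfilt(lp, y)
}

#' Transducer + amplifier response
#'
#' Converts a pressure trace at the element into the recorded voltage:
#' the trace is delayed by the delay line, band-limited by the transducer
#' passband composed with the receiver 20-150 MHz filters (zero-phase, so
#' arrival times are preserved), scaled by sensitivity and amplifier gain,
#' and white Gaussian output noise of the configured RMS is added.
#'
#' @param tr a `"pa_trace"` (Pa).
#' @param transducer a [transducer_model()].
#' @param seed seed for the noise draw (`NULL`: no reseeding).
#' @param noise_rms_mv noise RMS override, mV; default from the transducer.
#' @return a [raw_trace()] in mV.
#' @export
transduce <- function(tr, transducer = transducer_model(), seed = NULL,
                      noise_rms_mv = transducer$noise_rms_mv) {
  stopifnot(abs(tr$fs_ghz - transducer$fs_ghz) < 1e-12)
  x <- tr$pa
  k <- round(transducer$t_delay_us * 1e-6 * transducer$fs_ghz * 1e9)
  x <- c(numeric(k), x)[seq_along(x)]   # delay-line shift, same span
  y <- receiver_filter(x, transducer)
  mv <- y * transducer$sensitivity_uv_pa * 1e-3 * transducer$gain_linear
  if (noise_rms_mv > 0)
    mv <- mv + with_seed(seed, stats::rnorm(length(mv), 0, noise_rms_mv))
  raw_trace(mv, fs_ghz = transducer$fs_ghz, t0_us = tr$t0_us)
}
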