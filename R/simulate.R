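#' Bundled instrument configuration
#'
#' Collects the component models plus the few chain-level constants into one
#' list, with overridable defaults mirroring the bench instrument.
#'
#' @param optics an [optics_config()].
#' @param chrom a [chromophore()].
#' @param transducer a [transducer_model()].
#' @param grueneisen Grueneisen parameter (thermoacoustic efficiency).
#' @param coupling dimensionless collection/coupling efficiency of the
#'   acoustic chain; the default anchors the absolute voltage scale so the
#'   10 mM gel standard at 25 mW gives a 194 mV single-trace gated
#'   peak-to-peak (see the methods vignette).
#' @param gate_width_us pixel gate width, us.
#' @param n_avg default number of averaged pulses for point measurements.
#' @return a list of class `"pam_config"`.
#' @export
pam_config <- function(optics = optics_config(), chrom = chromophore(),
                       transducer = transducer_model(), grueneisen = 0.2,
                       coupling = .pam_coupling_default,
                       gate_width_us = 0.2, n_avg = 250) {
  structure(list(optics = optics, chrom = chrom, transducer = transducer,
                 grueneisen = grueneisen, coupling = coupling,
                 gate_width_us = gate_width_us, n_avg = n_avg),
            class = "pam_config")
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) configuration with optional `optics:`,
#' `chromophore:`, `transducer:` and chain-level keys, each entry overriding
#' the corresponding [pam_config()] default.
#'
#' @param path file path; `NULL` returns the defaults.
#' @return a `"pam_config"`.
#' @export
read_pam_config <- function(path = NULL) {
  if (is.null(path)) return(pam_config())
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  }
  pam_config(
    optics = do.call(optics_config, raw$optics %||% list()),
    chrom = do.call(chromophore, raw$chromophore %||% list()),
    transducer = do.call(transducer_model, raw$transducer %||% list()),
    grueneisen = raw$grueneisen %||% 0.2,
    coupling = raw$coupling %||% .pam_coupling_default,
    gate_width_us = raw$gate_width_us %||% 0.2,
    n_avg = raw$n_avg %||% 250
  )
}

#' @export
print.pam_config <- function(x, ...) {
  print(x$optics); print(x$transducer)
  cat(sprintf(
    "chain: Grueneisen %g, coupling %.4g, gate width %g us, %d-pulse average\n",
    x$grueneisen, x$coupling, x$gate_width_us, x$n_avg))
  invisible(x)
}

# Precomputed focal integration context shared across focus positions.
focal_context <- function(optics, chrom, kernel_pitch_um = NULL) {
  if (is.null(kernel_pitch_um)) kernel_pitch_um <- optics$w_xy_um / 6
  field <- focal_field(optics, pitch_um = kernel_pitch_um)
  off <- field$offsets_um
  grid <- as.matrix(expand.grid(x = off$x, y = off$y, z = off$z))
  In <- as.vector(field$intensity)^optics$n_photon
  pf <- peak_flux(optics)
  list(offsets = grid, In = In, dV = (kernel_pitch_um * 1e-6)^3,
       V_eff_m3 = sum(In) * (kernel_pitch_um * 1e-6)^3,
       pf = pf, eta = heat_fraction(chrom, optics), optics = optics,
       chrom = chrom)
}

# events/pulse and focal-average heat density at one focus position
yield_at <- function(ph, ctx, focus_um) {
  pts <- sweep(ctx$offsets, 2, focus_um, `+`)
  C <- phantom_concentration_at(ph, pts)
  Tz <- depth_transmission(pmax(pts[, 3], 0), ph$medium$L_I_um)
  n <- ctx$optics$n_photon
  ev_density <- (C * .const$N_A) * ctx$chrom$sigma_n *
    (ctx$pf$flux * Tz)^n * ctx$In * (ctx$optics$pulse_width_fs * 1e-15)
  events <- sum(ev_density) * ctx$dV
  heat_eff <- events / ctx$V_eff_m3 * ctx$eta * n * ctx$pf$E_photon
  list(events_per_pulse = events, heat_density_eff = heat_eff)
}

# noiseless voltage trace for a unit effective source pressure (1 Pa),
# including far-field wavelet, tissue attenuation, delay and receiver chain
unit_voltage_trace <- function(cfg, medium, r_mm, atten_path_mm,
                               duration_us = NULL) {
  tx <- cfg$transducer
  if (is.null(duration_us))
    duration_us <- tx$t_delay_us + r_mm * 1e-3 / medium$c_m_s * 1e6 + 0.9
  fs_hz <- tx$fs_ghz * 1e9
  nt <- round(duration_us * 1e-6 * fs_hz)
  t_s <- (seq_len(nt) - 1) / fs_hz
  t_arr <- r_mm * 1e-3 / medium$c_m_s
  w <- (cfg$optics$w_xy_um / 2 * 1e-6) / (r_mm * 1e-3) *
    source_wavelet(t_s - t_arr, cfg$optics$w_z_um, medium$c_m_s)
  tr <- structure(list(pa = cfg$coupling * w, fs_ghz = tx$fs_ghz, t0_us = 0),
                  class = "pa_trace")
  tr <- attenuate_spectrum(tr, atten_path_mm, medium$alpha_db_mm_mhz,
                           medium$alpha_exponent)
  transduce(tr, tx, noise_rms_mv = 0)
}

default_gate_start <- function(cfg, medium, r_mm) {
  cfg$transducer$t_delay_us + r_mm * 1e-3 / medium$c_m_s * 1e6 -
    cfg$gate_width_us / 2
}

#' Simulate a point (A-scan) measurement
#'
#' The full forward chain for a stationary focus: three-photon excitation of
#' the phantom at the focus, stress-confined pressure generation, far-field
#' propagation over the fixed measurement geometry, frequency-dependent
#' tissue attenuation, transducer/receiver response, pulse averaging and
#' gated peak extraction, together with the co-registered optical
#' (fluorescence) observable.
#'
#' The acoustic leg (1/r and attenuation path) is a property of the fixed
#' specimen-on-transducer geometry and does not follow the focus: depth
#' dependence enters only through the optical terms, as in the penetration
#' depth budget.
#'
#' @param ph a [phantom()].
#' @param cfg a [pam_config()].
#' @param focus_um length-3 focus position, um (`NULL`: lateral center at
#'   100 um depth).
#' @param r_mm focus-to-element acoustic path, mm (default: transducer
#'   standoff).
#' @param atten_path_mm tissue path for acoustic attenuation, mm (default
#'   `r_mm`).
#' @param n_avg averaged pulse count; white noise is drawn at
#'   `noise_rms/sqrt(n_avg)`, the distribution of an n-pulse average.
#' @param noise_rms_mv per-single-trace output noise RMS, mV.
#' @param seed noise seed.
#' @param ctx optional precomputed focal context (internal reuse).
#' @return list with `trace` ([raw_trace()], the averaged A-scan),
#'   `amplitude_mv` (gated peak-to-peak), `optical` (fluorescence signal,
#'   arbitrary units, noiseless), `gate_start_us`, `snr`.
#' @export
simulate_ascan <- function(ph, cfg = pam_config(), focus_um = NULL,
                           r_mm = cfg$transducer$standoff_mm,
                           atten_path_mm = r_mm,
                           n_avg = cfg$n_avg,
                           noise_rms_mv = cfg$transducer$noise_rms_mv,
                           seed = NULL, ctx = NULL) {
  d <- dim(ph$concentration)
  if (is.null(focus_um))
    focus_um <- c(d[1] * ph$pitch_um / 2, d[2] * ph$pitch_um / 2, 100)
  if (is.null(ctx)) ctx <- focal_context(cfg$optics, cfg$chrom)
  y <- yield_at(ph, ctx, focus_um)
  p_src <- initial_pressure(y$heat_density_eff, cfg$grueneisen)
  u <- unit_voltage_trace(cfg, ph$medium, r_mm, atten_path_mm)
  mv <- p_src * u$mv
  eff_noise <- noise_rms_mv / sqrt(n_avg)
  if (eff_noise > 0)
    mv <- mv + with_seed(seed, stats::rnorm(length(mv), 0, eff_noise))
  tr <- raw_trace(mv, fs_ghz = u$fs_ghz, t0_us = 0)
  gs <- default_gate_start(cfg, ph$medium, r_mm)
  amp <- gated_peak(tr, gs, cfg$gate_width_us)
  optical <- y$events_per_pulse * cfg$chrom$phi *
    depth_transmission(max(focus_um[3], 0), ph$medium$L_em_um)
  list(trace = tr, amplitude_mv = amp, optical = optical,
       gate_start_us = gs,
       snr = if (noise_rms_mv > 0) amp / eff_noise else Inf,
       p_src_pa = p_src)
}

#' Raster scan configuration
#'
#' Scan-timing and gating parameters of image acquisition. With the printed
#' defaults (256 x 256 pixels, 20 us dwell, 200 kHz repetition rate) a frame
#' takes 1.31 s (0.76 frame/s) and each pixel integrates 4 laser pulses.
#'
#' @param pixels,lines pixels per line and number of lines.
#' @param dwell_us pixel dwell time, us.
#' @param rep_rate_khz laser repetition rate during imaging, kHz.
#' @param fov_um field of view (square), um.
#' @param frame_averages frames to average.
#' @param gate_start_us gate start after the laser trigger, us (`NULL`:
#'   derived from the delay line and acoustic path at scan time).
#' @param gate_width_us gate width, us.
#' @return an object of class `"scan_config"`.
#' @export
scan_config <- function(pixels = 256, lines = pixels, dwell_us = 20,
                        rep_rate_khz = 200, fov_um = 230,
                        frame_averages = 4, gate_start_us = NULL,
                        gate_width_us = 0.2) {
  stopifnot(pixels >= 1, lines >= 1, dwell_us > 0, rep_rate_khz > 0,
            fov_um > 0, frame_averages >= 1)
  if (dwell_us * rep_rate_khz < 1e3)
    stop("dwell x repetition rate must give at least 1 pulse per pixel ",
         "(configuration error)")
  structure(list(pixels = as.integer(pixels), lines = as.integer(lines),
                 dwell_us = dwell_us, rep_rate_khz = rep_rate_khz,
                 fov_um = fov_um, frame_averages = as.integer(frame_averages),
                 gate_start_us = gate_start_us,
                 gate_width_us = gate_width_us),
            class = "scan_config")
}

#' Simulate a raster-scanned acquisition
#'
#' Scans the focus over a square field of view at fixed depth, simulating
#' `pulses_per_pixel` A-scan traces per pixel (each the noiseless forward
#' trace plus seeded white receiver noise) and, optionally, the simultaneous
#' optical channel. The transducer acceptance vignette can be applied with
#' `apply_aperture = TRUE`; by default the acceptance is treated as flat over
#' the field of view.
#'
#' @param ph a [phantom()].
#' @param scan a [scan_config()].
#' @param cfg a [pam_config()].
#' @param focus_depth_um focal-plane depth, um.
#' @param seed noise seed.
#' @param optical simulate the optical channel image too?
#' @param apply_aperture apply [aperture_weight()] about the scan center.
#' @param noise_rms_mv per-trace noise RMS override, mV.
#' @param r_mm acoustic path, mm.
#' @return an object of class `"raw_trace_set"`: `traces` (array
#'   `[lines, pixels, pulses, samples]`, mV), `fs_ghz`, `scan`, `gate_start_us`,
#'   `optical` (lines x pixels matrix or `NULL`), `amplitude_truth`
#'   (noiseless gated amplitudes), `seed`.
#' @export
simulate_scan <- function(ph, scan, cfg = pam_config(), focus_depth_um = 50,
                          seed = 1, optical = TRUE, apply_aperture = FALSE,
                          noise_rms_mv = cfg$transducer$noise_rms_mv,
                          r_mm = cfg$transducer$standoff_mm) {
  d <- dim(ph$concentration)
  ctx <- focal_context(cfg$optics, cfg$chrom)
  npp <- pulses_per_pixel(scan)
  u <- unit_voltage_trace(cfg, ph$medium, r_mm, r_mm)
  nt <- length(u$mv)
  gs <- scan$gate_start_us %||% default_gate_start(cfg, ph$medium, r_mm)
  xs <- (seq_len(scan$pixels) - 0.5) * scan$fov_um / scan$pixels
  ys <- (seq_len(scan$lines) - 0.5) * scan$fov_um / scan$lines
  # center the field of view on the phantom
  x0 <- d[1] * ph$pitch_um / 2 - scan$fov_um / 2
  y0 <- d[2] * ph$pitch_um / 2 - scan$fov_um / 2
  amp <- matrix(0, nrow = scan$lines, ncol = scan$pixels)
  opt <- if (optical) matrix(0, scan$lines, scan$pixels) else NULL
  esc <- depth_transmission(focus_depth_um, ph$medium$L_em_um)
  for (iy in seq_len(scan$lines)) {
    for (ix in seq_len(scan$pixels)) {
      y <- yield_at(ph, ctx, c(x0 + xs[ix], y0 + ys[iy], focus_depth_um))
      a <- initial_pressure(y$heat_density_eff, cfg$grueneisen)
      if (apply_aperture) {
        rho <- sqrt((xs[ix] - scan$fov_um / 2)^2 +
                      (ys[iy] - scan$fov_um / 2)^2)
        a <- a * aperture_weight(rho, cfg$transducer, r_mm)
      }
      amp[iy, ix] <- a
      if (optical) opt[iy, ix] <- y$events_per_pulse * cfg$chrom$phi * esc
    }
  }
  traces <- array(0, dim = c(scan$lines, scan$pixels, npp, nt))
  noise <- if (noise_rms_mv > 0) {
    with_seed(seed, stats::rnorm(length(traces), 0, noise_rms_mv))
  } else 0
  base <- outer(amp, rep(1, npp))                      # [lines, pixels, pulses]
  traces[] <- as.vector(outer(base, u$mv)) + noise
  structure(
    list(traces = traces, fs_ghz = u$fs_ghz, scan = scan,
         gate_start_us = gs, optical = opt,
         amplitude_truth = amp * gated_peak(u, gs, scan$gate_width_us),
         seed = seed, focus_depth_um = focus_depth_um,
         pitch_um_per_px = scan$fov_um / scan$pixels),
    class = "raw_trace_set"
  )
}

#' @export
print.raw_trace_set <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf(
    "raw_trace_set: %d x %d pixels, %d pulses/pixel, %d samples at %g GHz\n",
    d[1], d[2], d[3], d[4], x$fs_ghz))
  invisible(x)
}
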