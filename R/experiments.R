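#' Concentration calibration series
#'
#' Simulates the gel-standard concentration series (default grid 1, 2, 4.6,
#' 9.3, 18.75 mM) through the full forward chain and fits the linear
#' signal-vs-concentration calibration.
#'
#' @param concentrations_mM concentration grid, mM.
#' @param cfg a [pam_config()].
#' @param noise_rms_mv per-single-trace output noise RMS, mV (0 = noiseless).
#' @param n_avg pulses averaged per measurement.
#' @param seed base seed; each concentration uses a derived child seed.
#' @param focus_depth_um measurement focus depth in the gel, um.
#' @return list of class `"pam_experiment"`: `table` (data frame with
#'   concentration, PA amplitude, optical signal, SNR), `fit` (a
#'   `"pam_fit"` from [fit_linear()]), `kind`, `seed`.
#' @export
run_concentration_series <- function(concentrations_mM =
                                       c(1, 2, 4.6, 9.3, 18.75),
                                     cfg = pam_config(), noise_rms_mv = 0,
                                     n_avg = cfg$n_avg, seed = 1,
                                     focus_depth_um = 100) {
  if (length(concentrations_mM) < 1) stop("empty concentration grid")
  if (any(concentrations_mM < 0)) stop("concentrations must be >= 0")
  ctx <- focal_context(cfg$optics, cfg$chrom)
  rows <- lapply(seq_along(concentrations_mM), function(i) {
    ph <- make_gel_cylinder(concentrations_mM[i], diameter_mm = 0.4,
                            height_mm = 1.58, pitch_um = 8)
    m <- simulate_ascan(ph, cfg,
                        focus_um = c(200, 200, focus_depth_um),
                        n_avg = n_avg, noise_rms_mv = noise_rms_mv,
                        seed = child_seed(seed, i), ctx = ctx)
    data.frame(concentration_mM = concentrations_mM[i],
               pa_amplitude_mv = m$amplitude_mv,
               optical = m$optical, snr = m$snr)
  })
  tab <- do.call(rbind, rows)
  fit <- if (nrow(tab) >= 3) {
    fit_linear(tab$concentration_mM, tab$pa_amplitude_mv)
  } else NULL
  structure(list(table = tab, fit = fit, kind = "concentration_series",
                 seed = seed), class = "pam_experiment")
}

#' Laser power series
#'
#' Simulates the power sweep between the noise floor (6 mW) and the maximum
#' laser power (25 mW) and fits the power-law exponent of the photoacoustic
#' amplitude, the check that confirms the photon order (3.000 for the
#' noiseless three-photon chain).
#'
#' @param powers_mw power grid at the objective, mW.
#' @inheritParams run_concentration_series
#' @param concentration_mM gel standard concentration, mM.
#' @return a `"pam_experiment"` with a [fit_power_law()] fit.
#' @export
run_power_series <- function(powers_mw = seq(6, 25, length.out = 6),
                             cfg = pam_config(), noise_rms_mv = 0,
                             n_avg = cfg$n_avg, seed = 1,
                             concentration_mM = 10,
                             focus_depth_um = 100) {
  if (length(powers_mw) < 1) stop("empty power grid")
  if (any(powers_mw <= 0)) stop("powers must be > 0")
  ph <- make_gel_cylinder(concentration_mM, diameter_mm = 0.4,
                          height_mm = 1.58, pitch_um = 8)
  rows <- lapply(seq_along(powers_mw), function(i) {
    o <- cfg$optics; o$power_mw <- powers_mw[i]
    cfg_i <- cfg; cfg_i$optics <- o
    m <- simulate_ascan(ph, cfg_i, focus_um = c(200, 200, focus_depth_um),
                        n_avg = n_avg, noise_rms_mv = noise_rms_mv,
                        seed = child_seed(seed, i))
    data.frame(power_mw = powers_mw[i], pa_amplitude_mv = m$amplitude_mv,
               optical = m$optical, snr = m$snr)
  })
  tab <- do.call(rbind, rows)
  fit <- if (nrow(tab) >= 3 && all(tab$pa_amplitude_mv > 0)) {
    fit_power_law(tab$power_mw, tab$pa_amplitude_mv)
  } else NULL
  structure(list(table = tab, fit = fit, kind = "power_series", seed = seed),
            class = "pam_experiment")
}

# depths whose focal volume is fully immersed (not clipped by the surface)
immersed_mask <- function(depths_um, optics) {
  depths_um >= 1.25 * optics$w_z_um  # axial grid half-extent of the kernel
}

#' Photoacoustic depth sweep
#'
#' Sweeps the focus from the specimen surface downward at constant power and
#' fits the 1/e decay length of the photoacoustic amplitude. With the brain
#' preset the n-photon excitation attenuation (intensity 1/e length
#' `L_I = 750` um, signal 1/e length `L_I/3`) reproduces the 250 um
#' extinction length of the deep-recording experiments. Stations whose focal
#' volume is clipped by the specimen surface (within about one focal
#' half-length of z = 0) are reported but excluded from the fit, which would
#' otherwise measure geometry rather than attenuation.
#'
#' @param depths_um focus depth grid, um.
#' @param preset medium preset name for the tissue block.
#' @inheritParams run_concentration_series
#' @param power_mw constant excitation power, mW (53 mW as in the deep
#'   recordings).
#' @param concentration_mM uniform tissue concentration, mM.
#' @param n_seeds if > 1 and `noise_rms_mv > 0`, the fit is repeated over
#'   this many noise seeds and the median fitted length is reported.
#' @return a `"pam_experiment"` with a [fit_exp_decay()] fit; for
#'   multi-seed runs also `lengths_um` (per-seed fits).
#' @export
run_depth_sweep <- function(depths_um = seq(0, 700, by = 100),
                            preset = "brain", cfg = pam_config(),
                            noise_rms_mv = 0, n_avg = cfg$n_avg, seed = 1,
                            power_mw = 53, concentration_mM = 10,
                            n_seeds = 1) {
  o <- cfg$optics; o$power_mw <- power_mw; cfg$optics <- o
  thickness_mm <- (max(depths_um) + 2 * cfg$optics$w_z_um) / 1e3
  ph <- make_gel_cylinder(concentration_mM, diameter_mm = 0.6,
                          height_mm = max(1, thickness_mm), pitch_um = 10,
                          medium = preset)
  if (max(depths_um) > dim(ph$concentration)[3] * ph$pitch_um)
    stop("depth grid extends beyond the phantom (geometry error)")
  ctx <- focal_context(cfg$optics, cfg$chrom)
  base <- vapply(seq_along(depths_um), function(i) {
    simulate_ascan(ph, cfg, focus_um = c(300, 300, depths_um[i]),
                   n_avg = n_avg, noise_rms_mv = 0, ctx = ctx)$amplitude_mv
  }, numeric(1))
  mask <- immersed_mask(depths_um, cfg$optics)
  eff_noise <- noise_rms_mv / sqrt(n_avg)
  measure_once <- function(s) {
    if (eff_noise > 0) {
      # noise perturbs the gated peak-to-peak reading of each station
      base + with_seed(s, stats::rnorm(length(base), 0, eff_noise))
    } else base
  }
  fit_one <- function(amp) {
    ok <- mask & amp > 0
    if (sum(ok) < 3) return(NULL)
    fit_exp_decay(depths_um[ok], amp[ok])
  }
  amp1 <- measure_once(child_seed(seed, 1))
  fit <- fit_one(amp1)
  lengths <- NULL
  if (n_seeds > 1 && eff_noise > 0) {
    lengths <- vapply(seq_len(n_seeds), function(k) {
      f <- fit_one(measure_once(child_seed(seed, k)))
      if (is.null(f)) NA_real_ else f$estimates[["length_um"]]
    }, numeric(1))
    fit$estimates[["length_um_median"]] <- stats::median(lengths,
                                                         na.rm = TRUE)
  }
  tab <- data.frame(depth_um = depths_um, pa_amplitude_mv = amp1,
                    in_fit = mask)
  structure(list(table = tab, fit = fit, kind = "depth_sweep", seed = seed,
                 lengths_um = lengths, preset = preset),
            class = "pam_experiment")
}

#' Dual-channel (photoacoustic vs optical) depth comparison
#'
#' Simulates both detection channels down a spherical organoid phantom and
#' reports each channel's noise floor and floor-crossing depth. The optical
#' channel decays with both the excitation attenuation and the steep 50 um
#' emission extinction; its default floor is calibrated so the noiseless
#' organoid channel meets it at 400 um, the observed optical penetration
#' limit. The photoacoustic floor is the output noise RMS of the averaged
#' measurement; its crossing lies beyond the full organoid depth.
#'
#' @param depths_um depth grid, um.
#' @param preset medium preset for the organoid.
#' @inheritParams run_depth_sweep
#' @param diameter_mm organoid diameter, mm.
#' @param optical_floor optical-channel noise floor (same arbitrary units as
#'   the optical signal); `NULL` = calibrated to a 400 um crossing.
#' @param pa_floor_mv photoacoustic floor, mV; `NULL` = averaged noise RMS.
#' @return a `"pam_experiment"` with `table` (per-depth amplitudes and SNRs),
#'   `floors`, and `crossings_um` (per-channel floor-crossing depths from the
#'   fitted exponential decays).
#' @export
run_dual_channel_depth <- function(depths_um = seq(0, 1100, by = 100),
                                   preset = "organoid", cfg = pam_config(),
                                   noise_rms_mv = 0, n_avg = cfg$n_avg,
                                   seed = 1, power_mw = 53,
                                   concentration_mM = 10, diameter_mm = 1.2,
                                   optical_floor = NULL, pa_floor_mv = NULL) {
  o <- cfg$optics; o$power_mw <- power_mw; cfg$optics <- o
  ph <- make_organoid(diameter_mm = diameter_mm,
                      concentration_profile = concentration_mM,
                      pitch_um = 10, medium = preset)
  if (max(depths_um) > diameter_mm * 1e3)
    stop("depth grid extends beyond the organoid (geometry error)")
  ctx <- focal_context(cfg$optics, cfg$chrom)
  ctr <- dim(ph$concentration)[1] * ph$pitch_um / 2
  res <- lapply(seq_along(depths_um), function(i) {
    m <- simulate_ascan(ph, cfg, focus_um = c(ctr, ctr, depths_um[i]),
                        n_avg = n_avg, noise_rms_mv = noise_rms_mv,
                        seed = child_seed(seed, i), ctx = ctx)
    c(pa = m$amplitude_mv, optical = m$optical)
  })
  pa <- vapply(res, `[[`, numeric(1), "pa")
  op <- vapply(res, `[[`, numeric(1), "optical")
  mask <- immersed_mask(depths_um, cfg$optics)
  fit_pa <- fit_exp_decay(depths_um[mask], pa[mask])
  fit_op <- fit_exp_decay(depths_um[mask], op[mask])
  amp0 <- function(fit, z0, a0) a0 * exp(z0 / fit$estimates[["length_um"]])
  # extrapolated surface amplitudes from the immersed-region fits
  pa0 <- amp0(fit_pa, depths_um[mask][1], pa[mask][1])
  op0 <- amp0(fit_op, depths_um[mask][1], op[mask][1])
  if (is.null(pa_floor_mv))
    pa_floor_mv <- cfg$transducer$noise_rms_mv / sqrt(n_avg)
  if (is.null(optical_floor))
    optical_floor <- op0 * exp(-400 / fit_op$estimates[["length_um"]])
  crossing <- function(a0, floor, L) {
    if (a0 <= floor) return(0)
    if (!is.finite(L)) return(Inf)
    L * log(a0 / floor)
  }
  crossings <- c(
    pa = crossing(pa0, pa_floor_mv, fit_pa$estimates[["length_um"]]),
    optical = crossing(op0, optical_floor, fit_op$estimates[["length_um"]])
  )
  tab <- data.frame(depth_um = depths_um, pa_amplitude_mv = pa,
                    optical = op,
                    pa_snr = pa / pa_floor_mv,
                    optical_snr = op / optical_floor,
                    in_fit = mask)
  structure(list(table = tab, kind = "dual_channel_depth", seed = seed,
                 fit_pa = fit_pa, fit_optical = fit_op,
                 floors = list(pa_mv = pa_floor_mv,
                               optical = optical_floor),
                 crossings_um = crossings, preset = preset),
            class = "pam_experiment")
}

#' @export
print.pam_experiment <- function(x, ...) {
  cat(sprintf("pam_experiment: %s (%d conditions, seed %s)\n", x$kind,
              nrow(x$table), format(x$seed)))
  print(utils::head(x$table, 12), row.names = FALSE)
  if (!is.null(x$fit)) { cat("fit:\n"); print(x$fit) }
  if (!is.null(x$crossings_um)) {
    cat(sprintf("floor crossings: PA %.3g um, optical %.3g um\n",
                x$crossings_um[["pa"]], x$crossings_um[["optical"]]))
  }
  invisible(x)
}

#' Acquisition timing report
#'
#' Pulse-train and scan-timing arithmetic: pulses per pixel, frame period
#' and rate, stretched trigger-pulse width for a target duty cycle
#' (2.5 us at 50% duty and 200 kHz), and samples per pulse window at the
#' acquisition rate.
#'
#' @param rep_rate_khz laser repetition rate, kHz.
#' @param dwell_us pixel dwell, us.
#' @param duty_target trigger duty cycle in `[0, 1)`.
#' @param pixels,lines frame geometry.
#' @param fs_ghz acquisition sampling rate, GHz.
#' @return named list of timing quantities.
#' @export
timing_report <- function(rep_rate_khz = 200, dwell_us = 20,
                          duty_target = 0.5, pixels = 256, lines = 256,
                          fs_ghz = 2.0) {
  if (rep_rate_khz <= 0 || dwell_us <= 0 || pixels < 1 || lines < 1)
    stop("timing inputs must be positive")
  if (duty_target < 0 || duty_target >= 1)
    stop("`duty_target` must be in [0, 1) (invalid argument)")
  scan <- scan_config(pixels = pixels, lines = lines, dwell_us = dwell_us,
                      rep_rate_khz = rep_rate_khz)
  fp <- frame_period(scan)
  pulse_period_us <- 1e3 / rep_rate_khz
  list(
    pulses_per_pixel = pulses_per_pixel(scan),
    frame_period_s = fp$period_s,
    frame_rate_hz = fp$rate_hz,
    stretched_pulse_width_us = duty_target * pulse_period_us,
    pulse_period_us = pulse_period_us,
    samples_per_pulse_window = round(pulse_period_us * 1e-6 * fs_ghz * 1e9)
  )
}

#' Penetration depth budget
#'
#' The closed-form attenuation budget of the two detection paths through a
#' tissue thickness: the optical emission escape factor `exp(-d/L_em)`
#' (3.5e-24 through 2.7 mm at the 50 um near-UV extinction length), the
#' acoustic power-law loss `a * d * f^b` in dB (-4 dB through 2.7 mm near
#' 100 MHz), and the geometric 1/r pressure factor from the micron-scale
#' source to the element.
#'
#' @param depth_mm tissue path, mm.
#' @param L_em_um emission 1/e extinction length, um.
#' @param f_mhz acoustic band center, MHz.
#' @param a,b acoustic attenuation coefficient (dB/(mm*MHz^b)) and exponent.
#' @param r_mm source-element distance, mm.
#' @param a_eff_um effective source radius, um.
#' @return named list: `optical_factor`, `acoustic_db`, `acoustic_factor`,
#'   `one_over_r_factor`.
#' @export
depth_budget <- function(depth_mm = 2.7, L_em_um = 50, f_mhz = 100,
                         a = 4 / 270, b = 1, r_mm = 2.7, a_eff_um = 1.1) {
  if (depth_mm < 0 || L_em_um <= 0 || f_mhz <= 0 || r_mm <= 0)
    stop("budget inputs must be positive")
  acoustic_db <- a * depth_mm * f_mhz^b
  list(
    optical_factor = exp(-depth_mm * 1e3 / L_em_um),
    acoustic_db = acoustic_db,
    acoustic_factor = 10^(-acoustic_db / 20),
    one_over_r_factor = a_eff_um / (r_mm * 1e3)
  )
}
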