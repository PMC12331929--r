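# Shared fixtures built in code.

# windowed tone burst trace (amplitude 1) at fs GHz
tone_burst <- function(f_mhz, fs_ghz = 2, n = 8000, t0_us = 1,
                       dur_us = 1, amp = 1) {
  t <- (seq_len(n) - 1) / (fs_ghz * 1e3)
  raw_trace(amp * sin(2 * pi * f_mhz * t) *
              exp(-((t - t0_us - dur_us / 2) / (dur_us / 3))^2),
            fs_ghz = fs_ghz)
}

# continuous tone (no window)
tone_cw <- function(f_mhz, fs_ghz = 2, n = 8000, amp = 1) {
  t <- (seq_len(n) - 1) / (fs_ghz * 1e3)
  raw_trace(amp * sin(2 * pi * f_mhz * t), fs_ghz = fs_ghz)
}

rms <- function(x) sqrt(mean(x^2))

# small uniform slab phantom for scan tests (brain-like medium, gel optics)
uniform_slab <- function(conc = 10, side_um = 240, depth_um = 160,
                         pitch_um = 4, medium = "gel") {
  n <- ceiling(side_um / pitch_um)
  nz <- ceiling(depth_um / pitch_um)
  phantom(array(conc, dim = c(n, n, nz)), pitch_um, medium)
}

fast_scan <- function(pixels = 8, fov_um = 80, dwell_us = 20,
                      rep_rate_khz = 100, ...) {
  scan_config(pixels = pixels, dwell_us = dwell_us,
              rep_rate_khz = rep_rate_khz, fov_um = fov_um, ...)
}
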