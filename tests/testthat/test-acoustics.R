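test_that("initial pressure is the Grueneisen scaling of the heat map", {
  H <- array(stats::runif(24, 0, 5), c(2, 3, 4))
  expect_true(all(initial_pressure(H, 0) == 0))
  expect_equal(initial_pressure(H, 0.4), 2 * initial_pressure(H, 0.2))
  # elementwise oracle
  p <- initial_pressure(H, 0.2)
  for (i in seq_along(H)) expect_identical(p[i], 0.2 * H[i])
  expect_error(initial_pressure(array(-1, c(1, 1, 1))), "non-negative")
})

test_that("single-voxel far-field arrival sits at r/c", {
  p0 <- array(0, c(3, 3, 3)); p0[2, 2, 2] <- 1
  tr <- farfield_trace(p0, pitch_um = 2, r_mm = 6, c_m_s = 1500,
                       duration_us = 6)
  t <- trace_time_us(tr)
  # the derivative-of-Gaussian zero crossing between its two extrema
  arrival <- mean(c(t[which.max(tr$pa)], t[which.min(tr$pa)]))
  expect_equal(arrival, 4.0, tolerance = 1e-3)
})

test_that("far-field superposition is exact", {
  p2 <- array(0, c(3, 3, 1)); p2[1, 2, 1] <- 1; p2[3, 2, 1] <- 1
  p1 <- array(0, c(3, 3, 1)); p1[1, 2, 1] <- 1
  tr2 <- farfield_trace(p2, 2, 6, duration_us = 6)
  tr1 <- farfield_trace(p1, 2, 6, duration_us = 6)
  expect_equal(tr2$pa, 2 * tr1$pa, tolerance = 1e-12)
})

test_that("far-field trace equals a brute-force voxel-sum oracle", {
  set.seed(42)
  p0 <- array(stats::runif(8^3, 0, 100), c(8, 8, 8))
  pitch <- 3; r_mm <- 2; c_ms <- 1500; fs <- 2
  tr <- farfield_trace(p0, pitch, r_mm, c_ms, fs_ghz = fs, duration_us = 2.5,
                       w_z_um = 30, a_eff_um = 1.1)
  # independent oracle: nested loops, own wavelet formula
  nt <- length(tr$pa)
  t_s <- (seq_len(nt) - 1) / (fs * 1e9)
  f_pk <- c_ms / (15e-6); sig <- 1 / (2 * pi * f_pk)
  elem <- c(8 * pitch / 2, 8 * pitch / 2, 8 * pitch / 2 + r_mm * 1e3)
  oracle <- numeric(nt)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    dr <- sqrt(((i - 0.5) * pitch - elem[1])^2 +
                 ((j - 0.5) * pitch - elem[2])^2 +
                 ((k - 0.5) * pitch - elem[3])^2)
    tau <- t_s - dr * 1e-6 / c_ms
    oracle <- oracle + (1.1 / dr) * p0[i, j, k] *
      (-(tau / sig) * exp(0.5 - tau^2 / (2 * sig^2)))
  }
  expect_lt(max(abs(tr$pa - oracle)) / max(abs(oracle)), 1e-9)
})

test_that("too-short acquisition windows are refused", {
  p0 <- array(1, c(2, 2, 2))
  expect_error(farfield_trace(p0, 2, r_mm = 6, duration_us = 2), "window")
})

test_that("spectral attenuation matches the closed per-frequency form", {
  n <- 4096; fs <- 2
  t <- (seq_len(n) - 1) / (fs * 1e3)
  tone <- raw_trace(sin(2 * pi * 100 * t), fs_ghz = fs)
  # d = 0 is the identity
  expect_identical(attenuate_spectrum(tone, 0)$mv, tone$mv)
  # -4 dB through 2.7 mm at 100 MHz with the calibrated default coefficient
  att <- attenuate_spectrum(tone, 2.7)
  mid <- 1000:3000
  expect_equal(max(abs(att$mv[mid])), 10^(-4 / 20), tolerance = 1e-3)
  # two-tone separability: attenuating the sum equals summing per-tone
  tone2 <- raw_trace(sin(2 * pi * 40 * t), fs_ghz = fs)
  both <- raw_trace(tone$mv + tone2$mv, fs_ghz = fs)
  expect_equal(attenuate_spectrum(both, 2.7)$mv,
               attenuate_spectrum(tone, 2.7)$mv +
                 attenuate_spectrum(tone2, 2.7)$mv,
               tolerance = 1e-12)
})

test_that("aperture weight is 1 on axis, 0.5 at the acceptance radius,
           and monotone", {
  tx <- transducer_model()
  expect_equal(aperture_weight(0, tx), 1)
  expect_equal(aperture_weight(50, tx), 0.5)
  w <- aperture_weight(seq(0, 500, by = 1), tx)
  expect_true(all(diff(w) <= 0))
  expect_error(aperture_weight(-1, tx), ">= 0")
})

test_that("transducer chain: delay, DC rejection, zero and linear response", {
  tx <- transducer_model()
  zero <- structure(list(pa = numeric(8000), fs_ghz = 2, t0_us = 0),
                    class = "pa_trace")
  expect_true(all(transduce(zero, tx, noise_rms_mv = 0)$mv == 0))
  # impulse energy centroid lands at the 2.6 us delay line
  imp <- structure(list(pa = c(1, numeric(9999)), fs_ghz = 2, t0_us = 0),
                   class = "pa_trace")
  out <- transduce(imp, tx, noise_rms_mv = 0)
  centroid <- sum(trace_time_us(out) * out$mv^2) / sum(out$mv^2)
  expect_equal(centroid, 2.6, tolerance = 0.02)
  # DC input is rejected by the 20 MHz high-pass (away from the step edge)
  dc <- structure(list(pa = rep(1, 8000), fs_ghz = 2, t0_us = 0),
                  class = "pa_trace")
  odc <- transduce(dc, tx, noise_rms_mv = 0)
  in_scale <- tx$sensitivity_uv_pa * 1e-3 * tx$gain_linear
  expect_lt(max(abs(odc$mv[6800:7600])) / in_scale, 1e-6)
  # linearity of the noiseless chain
  burst <- structure(list(pa = tone_burst(80, n = 8000)$mv, fs_ghz = 2,
                          t0_us = 0), class = "pa_trace")
  y1 <- transduce(burst, tx, noise_rms_mv = 0)$mv
  burst3 <- burst; burst3$pa <- 3 * burst$pa
  y3 <- transduce(burst3, tx, noise_rms_mv = 0)$mv
  expect_equal(y3, 3 * y1, tolerance = 1e-12)
})

test_that("transducer noise is seeded and has the configured RMS", {
  tx <- transducer_model(noise_rms_mv = 20)
  zero <- structure(list(pa = numeric(20000), fs_ghz = 2, t0_us = 0),
                    class = "pa_trace")
  a <- transduce(zero, tx, seed = 11)
  b <- transduce(zero, tx, seed = 11)
  expect_identical(a$mv, b$mv)
  expect_equal(rms(a$mv), 20, tolerance = 0.05)
})

test_that("simulated gel A-scan: arrival time, spectral band and 1/r scale", {
  cfg <- pam_config()
  ph <- make_gel_cylinder(10, diameter_mm = 0.4, height_mm = 1.58,
                          pitch_um = 8)
  m <- simulate_ascan(ph, cfg, focus_um = c(200, 200, 100),
                      noise_rms_mv = 0)
  # arrival = delay line + r/c within one sample of the envelope peak
  t <- trace_time_us(m$trace)
  t_exp <- cfg$transducer$t_delay_us +
    cfg$transducer$standoff_mm * 1e-3 / ph$medium$c_m_s * 1e6
  i_pk <- which.max(abs(m$trace$mv))
  expect_lt(abs(t[i_pk] - t_exp), 0.01)  # within the pulse width
  # spectral peak of the A-scan lies in the loose 40-130 MHz design band
  sc <- scalogram(m$trace, 20, 300)
  expect_gt(sc$peak_freq_mhz, 40)
  expect_lt(sc$peak_freq_mhz, 130)
  # pressure at the element is ~a_eff/r below the source pressure
  ratio <- (1.1 / (cfg$transducer$standoff_mm * 1e3))
  expect_gt(ratio, 1e-4); expect_lt(ratio, 1e-2)
  peak_pa <- max(abs(m$trace$mv)) / (cfg$transducer$sensitivity_uv_pa *
                                       1e-3 * cfg$transducer$gain_linear)
  expect_lt(peak_pa / m$p_src_pa, 1e-2)
})

test_that("whole chain is linear in source pressure", {
  cfg <- pam_config()
  ph1 <- make_gel_cylinder(5, diameter_mm = 0.4, height_mm = 1.0,
                           pitch_um = 8)
  ph2 <- make_gel_cylinder(10, diameter_mm = 0.4, height_mm = 1.0,
                           pitch_um = 8)
  m1 <- simulate_ascan(ph1, cfg, focus_um = c(200, 200, 100),
                       noise_rms_mv = 0)
  m2 <- simulate_ascan(ph2, cfg, focus_um = c(200, 200, 100),
                       noise_rms_mv = 0)
  expect_equal(m2$trace$mv, 2 * m1$trace$mv, tolerance = 1e-9)
  expect_equal(m2$amplitude_mv, 2 * m1$amplitude_mv, tolerance = 1e-9)
})

test_that("transducer presets carry the two bench passbands", {
  t125 <- transducer_preset("125mhz")
  t75 <- transducer_preset("75mhz")
  expect_equal(t125$passband_mhz, c(68, 197))
  expect_equal(t75$passband_mhz, c(45, 122))
  expect_equal(t125$element_diameter_mm, 3.175)
  expect_error(transducer_model(passband_mhz = c(200, 100)))
})
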