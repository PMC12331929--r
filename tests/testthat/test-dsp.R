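test_that("pulse averaging: identity, exact mean, and sqrt(n) noise law", {
  m <- rbind(c(1, 2, 3, 4), c(3, 2, 1, 0), c(5, 5, 5, 5))
  expect_equal(average_pulses(m, 1)$mv, c(1, 2, 3, 4))
  expect_equal(average_pulses(m, 3)$mv, c(3, 3, 3, 3))
  expect_equal(average_pulses(m)$mv, c(3, 3, 3, 3))
  tr <- list(raw_trace(1:4), raw_trace(c(2, 2, 2, 2)))
  expect_equal(average_pulses(tr)$mv, c(1.5, 2, 2.5, 3))
  expect_error(average_pulses(list(raw_trace(1:4), raw_trace(1:5))),
               "alignment")
  # sqrt(250) noise reduction, averaged over 20 repeats
  ratios <- with_seed(99, vapply(1:20, function(i) {
    noise <- matrix(stats::rnorm(250 * 400), nrow = 250)
    rms(noise[1, ]) / rms(average_pulses(noise, 250)$mv)
  }, numeric(1)))
  expect_equal(mean(ratios), sqrt(250), tolerance = 0.1)
})

test_that("scalogram locates pure tones and separates a two-tone burst", {
  expect_equal(scalogram(tone_burst(88), 40, 160)$peak_freq_mhz, 88,
               tolerance = 3 / 88)
  expect_equal(scalogram(tone_burst(10, dur_us = 2), 5, 40)$peak_freq_mhz,
               10, tolerance = 0.5 / 10)
  # two ridges, cross-checked against an FFT oracle on the same trace
  tr <- raw_trace(tone_burst(30)$mv + tone_burst(90)$mv)
  sc <- scalogram(tr, 15, 150)
  ridge <- apply(sc$magnitude, 1, max)
  locmax <- which(diff(sign(diff(ridge))) == -2) + 1
  found <- sort(sc$freq_mhz[locmax[order(ridge[locmax],
                                         decreasing = TRUE)][1:2]])
  spec <- Mod(stats::fft(tr$mv))[1:4000]
  fax <- (0:3999) * 2000 / 8000
  keep <- fax >= 15 & fax <= 150
  pk1 <- fax[keep][which.max(spec[keep])]
  expect_equal(found[1], 30, tolerance = 0.05)
  expect_equal(found[2], 90, tolerance = 0.05)
  expect_true(any(abs(found - pk1) / pk1 < 0.05))
  # peak frequency is invariant to amplitude scaling
  sc2 <- scalogram(raw_trace(5 * tr$mv), 15, 150)
  expect_equal(sc2$peak_freq_mhz, sc$peak_freq_mhz)
})

test_that("scalogram rejects bands outside Nyquist", {
  expect_error(scalogram(tone_burst(50), 10, 1200), "Nyquist")
  expect_error(band_denoise(tone_burst(50), 90, 50), "band")
})

test_that("band denoising preserves the passband, kills the stopband,
           and is nearly idempotent", {
  inband <- tone_cw(70)
  out <- band_denoise(inband, 50, 90)
  mid <- 2000:6000
  expect_equal(max(abs(out$mv[mid])), 1, tolerance = 0.1)
  stopb <- band_denoise(tone_cw(10), 50, 90)
  expect_lt(max(abs(stopb$mv[mid])), 0.1)
  twice <- band_denoise(out, 50, 90)
  expect_lt(rms(twice$mv - out$mv) / rms(out$mv), 0.05)
})

test_that("band denoising improves the SNR of a noisy in-band pulse", {
  improvements <- vapply(1:20, function(s) {
    clean <- tone_burst(70, dur_us = 0.5)$mv
    noisy <- clean + with_seed(1000 + s,
                               stats::rnorm(length(clean), 0, 0.5))
    tr <- raw_trace(noisy)
    den <- band_denoise(tr, 60, 90)
    snr_of <- function(x) {
      sig <- max(abs(x[2800:3200]))          # pulse centered at 1.25 us
      sig / rms(x[5000:7000])                # off-pulse noise
    }
    snr_of(den$mv) / snr_of(noisy)
  }, numeric(1))
  expect_gt(mean(improvements), 1.5)
  expect_gt(mean(improvements > 1), 0.9)
})

test_that("gated peak statistics follow their definitions", {
  z <- raw_trace(numeric(4000))
  expect_equal(gated_peak(z, 0.5, 0.5), 0)
  x <- numeric(4000); x[1200:1400] <- 1     # rectangular pulse inside gate
  expect_equal(gated_peak(raw_trace(x), 0.5, 0.5, "max_abs"), 1)
  # hand-computed peak-to-peak of a listed 8-sample trace
  tr8 <- raw_trace(c(0, 2, -3, 1, 5, -1, 0, 2), fs_ghz = 1e-3)  # 1 us steps
  expect_equal(gated_peak(tr8, 0, 7), 5 - (-3))
  expect_equal(gated_peak(tr8, 0, 7, "mean_abs"), mean(abs(tr8$mv)))
  expect_error(gated_peak(z, 1.9, 0.5), "window")
})

test_that("power-law fit recovers exact and noisy exponents", {
  x <- seq(6, 25, length.out = 8)
  expect_equal(unname(fit_power_law(x, x^3)$estimates[["exponent"]]), 3,
               tolerance = 1e-9)
  expect_equal(unname(fit_power_law(x, 2 * x)$estimates[["exponent"]]), 1,
               tolerance = 1e-9)
  expect_error(fit_power_law(c(-1, 2, 3), c(1, 2, 3)), "positive")
  # noisy data: agree with an independent nonlinear least-squares oracle
  set.seed(5)
  y <- x^3 * exp(stats::rnorm(length(x), 0, 0.05))
  f1 <- fit_power_law(x, y)
  nl <- stats::nls(y ~ a * x^b, start = list(a = 1, b = 3),
                   control = stats::nls.control(warnOnly = TRUE))
  b_hat <- stats::coef(nl)[["b"]]
  joint <- 2 * (f1$se[["exponent"]] +
                  summary(nl)$coefficients["b", "Std. Error"])
  expect_lt(abs(f1$estimates[["exponent"]] - b_hat), joint)
})

test_that("linear fit reports OLS slope and the covariance-formula R", {
  x <- c(1, 2, 4.6, 9.3, 18.75)
  y <- 3.2 * x + 0.5
  f <- fit_linear(x, y)
  expect_equal(unname(f$estimates[["slope"]]), 3.2, tolerance = 1e-9)
  expect_equal(f$r, 1, tolerance = 1e-9)
  set.seed(8)
  y2 <- y + stats::rnorm(5, 0, 2)
  f2 <- fit_linear(x, y2)
  r_oracle <- sum((x - mean(x)) * (y2 - mean(y2))) /
    sqrt(sum((x - mean(x))^2) * sum((y2 - mean(y2))^2))
  expect_equal(f2$r, r_oracle, tolerance = 1e-12)
  expect_error(fit_linear(rep(1, 4), 1:4), "rank|degenerate")
})

test_that("exponential decay fit: exact recovery, non-decay flag,
           and noisy recovery within 5%", {
  z <- seq(0, 700, by = 100)
  expect_equal(
    unname(fit_exp_decay(z, exp(-z / 250))$estimates[["length_um"]]),
    250, tolerance = 1e-9)
  flat <- fit_exp_decay(z, rep(2, length(z)))
  expect_true(is.infinite(flat$estimates[["length_um"]]))
  expect_true("non_decaying" %in% flat$flags)
  expect_error(fit_exp_decay(z, c(-1, rep(1, 7))), "positive")
  lengths <- with_seed(21, vapply(1:50, function(i) {
    y <- exp(-z / 250) * (1 + stats::rnorm(length(z), 0, 0.10))
    fit_exp_decay(z, pmax(y, 1e-6))$estimates[["length_um"]]
  }, numeric(1)))
  expect_lt(abs(stats::median(lengths) - 250) / 250, 0.05)
})

test_that("dF/F and Pearson correlation follow their definitions", {
  # constant trace: baseline c, dF/F identically 0
  m <- cbind(a = rep(4, 20), b = rep(4, 20))
  out <- dff_and_correlation(m)
  expect_equal(unname(out$baseline), c(4, 4))
  expect_true(all(out$dff == 0))
  expect_equal(out$correlation, diag(2), ignore_attr = TRUE)
  # identical active traces correlate at 1
  f <- 5 + sin(seq(0, 6, length.out = 50))
  out2 <- dff_and_correlation(cbind(f, f))
  expect_equal(out2$correlation[1, 2], 1, tolerance = 1e-12)
  # textbook Pearson formula on two listed 10-sample traces
  f1 <- c(5, 6, 7, 5, 9, 10, 6, 5, 7, 8)
  f2 <- c(4, 4, 6, 5, 8, 11, 5, 4, 6, 9)
  out3 <- dff_and_correlation(cbind(f1, f2))
  d1 <- (f1 - min(f1)) / min(f1); d2 <- (f2 - min(f2)) / min(f2)
  pear <- sum((d1 - mean(d1)) * (d2 - mean(d2))) /
    sqrt(sum((d1 - mean(d1))^2) * sum((d2 - mean(d2))^2))
  expect_equal(out3$correlation[1, 2], pear, tolerance = 1e-12)
  # baseline is the mean of the lowest decile (1 sample here)
  expect_equal(unname(out3$baseline), c(min(f1), min(f2)))
  # matrix properties
  set.seed(3)
  big <- matrix(stats::rnorm(200, 10), ncol = 5)
  cm <- dff_and_correlation(big)$correlation
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  expect_error(dff_and_correlation(cbind(rep(0, 10))), "baseline")
})
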