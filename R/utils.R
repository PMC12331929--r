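# Physical constants (SI)
.const <- list(
  h      = 6.62607015e-34,   # Planck, J s
  c      = 2.99792458e8,     # light speed, m/s
  N_A    = 6.02214076e23     # Avogadro, 1/mol
)

# Absolute-scale anchor of the acoustic chain: a single dimensionless
# collection/coupling efficiency calibrated once so that the reference bench
# condition (10 mM gel standard, 25 mW at the objective, default transducer
# and amplifier) yields a single-trace gated peak-to-peak of 194 mV.
# See the methods vignette ("Absolute scale calibration").
.pam_coupling_default <- 8.927691e-02

#' Evaluate code with a locally seeded RNG
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulation helpers do not disturb the global stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic child seed derivation (kept below 2^31)
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 100000L) * 17989L + (as.integer(stage) %% 17989L)
}

#' Decibel/linear amplitude conversion
#'
#' Amplitude convention: `linear = 10^(db/20)`. The 63 dB receiver gain of the
#' pulser-receiver corresponds to a linear gain of about 1412.
#'
#' @param db gain in dB.
#' @return linear amplitude gain.
#' @export
db_to_linear <- function(db) 10^(db / 20)

#' @rdname db_to_linear
#' @param linear linear amplitude gain.
#' @export
linear_to_db <- function(linear) 20 * log10(linear)

#' Signal-to-noise ratio of a gated measurement
#'
#' The instrument convention: gated peak-to-peak signal amplitude divided by
#' the output noise RMS, both in mV (e.g. 194 mV / 20 mV = 9.7).
#'
#' @param signal_mv gated peak-to-peak amplitude, mV.
#' @param noise_rms_mv output noise RMS, mV.
#' @return dimensionless SNR.
#' @export
snr_ratio <- function(signal_mv, noise_rms_mv) {
  if (any(noise_rms_mv <= 0)) stop("`noise_rms_mv` must be positive")
  signal_mv / noise_rms_mv
}

# linear interpolation of the FWHM of a sampled symmetric profile
profile_fwhm <- function(x, y) {
  y <- y / max(y)
  above <- which(y >= 0.5)
  if (length(above) < 1) return(NA_real_)
  i1 <- above[1]; i2 <- above[length(above)]
  left <- if (i1 == 1) x[1] else {
    stats::approx(y[c(i1 - 1, i1)], x[c(i1 - 1, i1)], xout = 0.5)$y
  }
  right <- if (i2 == length(x)) x[length(x)] else {
    stats::approx(y[c(i2 + 1, i2)], x[c(i2 + 1, i2)], xout = 0.5)$y
  }
  right - left
}
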