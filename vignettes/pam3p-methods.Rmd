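---
title: "pam3p: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pam3p: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pam3p)
```

## What this package models

`pam3p` is a desk-scale digital twin of a label-free multiphoton
photoacoustic microscope built around three-photon excitation of NAD(P)H at
1300 nm. NAD(P)H is an endogenous metabolic coenzyme with a low (~5%)
fluorescence quantum yield and near-ultraviolet emission (~450 nm) that
tissue absorbs within tens of micrometers. The instrument concept exploits
exactly those weaknesses: most of the absorbed three-photon energy relaxes
non-radiatively, heats the femtoliter focal volume, and — because the
femtosecond pulse is far shorter than the acoustic transit time across the
heated spot (stress confinement) — launches an ultrasound pulse that reaches
a transducer below the specimen with only dB-scale losses, where the
fluorescence channel loses twenty-plus orders of magnitude through the same
tissue.

The package provides every stage of that chain as composable, testable
pieces: synthetic specimens with known ground truth (`phantom` functions),
the excitation/heating model (`optics` functions), the acoustic detection
chain (`acoustics` functions), trace processing (`dsp` functions), image
formation (`recon` functions) and the standard in-silico calibration
experiments (`run_*`, `timing_report`, `depth_budget`). Nothing here fits
real data for you; the point is that every quantitative design claim of such
an instrument can be exercised end-to-end on phantoms whose truth is known.

## Excitation model

The focal intensity is a separable normalized profile `Ihat` with peak 1.
Heat is generated in proportion to `Ihat^n` (n = 3 by default), so the
*heated* profile is what the acoustics sees. We parameterize directly in
heated-profile FWHMs: `w_xy = 2.2` um lateral and `w_z = 30` um axial at
NA 0.4 and 1300 nm — the design sizes of the instrument — and scale them as
`lambda/NA` (lateral) and `lambda/NA^2` (axial) for other settings. A
Gaussian lateral profile is the default; a circular-aperture (Airy) option
is matched to the same heated FWHM. The convention "2.2 um means the FWHM of
the heated profile" is a deliberate pin: the diameter-vs-radius and
I-vs-I^3 conventions are not derivable from the headline numbers alone, and
this choice guarantees the acoustic source geometry matches the stated
heated volume.

Peak pulse intensity comes from average power as
`I_pk = (P / f_rep) / (tau_p * A_eff)` with `A_eff = pi w_I^2 / (4 ln 2)`
the effective area of the intensity profile (`w_I = w_xy * sqrt(n)`).
Temporal pulse-shape factors are absorbed into the single chain calibration
described below; only relative scalings (power law, linearity) are
physically testable at desk scale.

Per-voxel heating is
`H = C * N_A * sigma_n * (I_pk * T(z) * Ihat)^n * tau_p * eta_h * n * E_photon`
(J/m^3 per pulse), linear in concentration and proportional to `P^n`.
The heat fraction is derived by energy conservation,
`eta_h = 1 - phi * lambda_ex / (n * lambda_em)` (0.952 at defaults): of each
absorbed three-photon quantum, a `phi` chance of emitting one 450 nm photon
returns that energy radiatively, and everything else thermalizes.

**Attenuation-length convention.** The configuration stores the *intensity*
1/e attenuation length `L_I`; an n-photon signal therefore decays with 1/e
length `L_I / n`. The brain preset uses `L_I = 750` um so that the
photoacoustic signal decays with the 250 um 1/e length observed in deep
tissue recordings. The alternative reading — 250 um as the intensity
attenuation length of the 1300 nm beam itself — is supported by setting
`L_I = 250` in a custom medium; the signal-length reading is the default
because it is the one anchored to a measured signal decay. The organoid
preset lengthens `L_I` by 1.5x (engineered neural tissue scatters and
absorbs less than brain); the gel preset is optically transparent. These
preset values are stated assumptions, not measurements, and every one is
overridable per phantom.

## Acoustic chain

Initial pressure is the stress-confined conversion `p0 = Gamma * H` with a
water-like Grueneisen parameter of 0.2. Propagation to the element uses a
far-field spherical-wave superposition: each source voxel contributes
`(a_eff / r) * p0 * s(t - r/c)` with `a_eff` the lateral source radius
(1.1 um at defaults), giving the characteristic ~10^-3 geometric pressure
loss from a micron-scale source over millimeter standoffs. The source
wavelet `s` is a derivative-of-Gaussian whose spectral peak is set to
`c / (w_z / 2)` — inversely proportional to the axial *radius* of the
heated volume — which places the default source spectrum at 100 MHz, inside
the 90-125 MHz band a full-wave simulation of this geometry predicts.
A full finite-difference acoustic solver is deliberately out of scope; the
analytic far-field model is fast, linear, and testable against a brute-force
voxel-sum oracle to round-off.

Frequency-dependent tissue attenuation is the standard amplitude power law
`10^(-a d f^b / 20)` with `a = 4/270` dB/(mm MHz) and `b = 1`, calibrated so
that 2.7 mm of cortex-like tissue at 100 MHz loses exactly 4 dB. (A 4 dB
amplitude loss is a 37% reduction, not 44%; quoting both -4 dB and "44%"
for the same path mixes amplitude and intensity conventions, and this
package consistently uses amplitude dB.)

The transducer model composes a 2.6 us delay line, the unit's passband
(68-197 MHz for the 125 MHz element, 45-122 MHz for the 75 MHz element), a
20-150 MHz receiver, 140 uV/Pa sensitivity and 63 dB (1412x) gain, plus
white output noise. Filters are zero-phase Butterworth sections so that
arrival times (`t_delay + r/c`) survive filtering exactly; transducer
ringing beyond the stated passband is not modeled. The lateral acceptance of
the fixed element is a Gaussian weight with 100 um half-amplitude diameter —
the acceptance is treated as a smooth aperture rather than re-deriving
piston diffraction.

**Absolute scale.** Nothing printed at desk scale pins the absolute voltage
of the chain (the Grueneisen parameter, collection solid angle and pulse
shape factor are individually unknowable here), so the chain carries one
dimensionless coupling constant calibrated once: the reference bench
condition — 10 mM gel standard, 25 mW at the objective, default transducer —
produces a single-trace gated peak-to-peak of 194 mV. With the default
20 mV output noise RMS this fixes the reference SNR at 9.7:1. All other
amplitudes follow from the physics of the chain; the calibration is a single
multiplicative anchor, never re-tuned per experiment.

**SNR convention.** SNR = gated peak-to-peak signal amplitude / output
noise RMS, matching the bench arithmetic 194 mV / 20 mV = 9.7.

## Trace processing

The scalogram is an analytic Morlet CWT (center-frequency parameter
`omega0 = 6`, 32 voices per octave, so the log-frequency grid spacing is
~2.2% — comfortably inside a +/-3 MHz localization requirement at 88 MHz and
2 GHz sampling). Per-scale normalization is flat in amplitude so the ridge
maximum directly identifies the dominant frequency.

Band-limited denoising reconstructs the trace from only those coefficients
whose center frequencies lie in the chosen band. Because summing in-band
Morlet coefficients is a linear time-invariant operation, `band_denoise`
applies its exact frequency-response equivalent, normalized to unit in-band
gain: in-band tones are preserved within a few percent, out-of-band energy
falls off with the Gaussian wavelet spectrum, and the operation is nearly
idempotent. The default band is 50-90 MHz; the analyses this emulates used
50-70, 50-90 and 60-90 MHz variants, so the band is an argument everywhere.

Pixel values use a gated statistic over a window placed at
`t_delay + r/c`; peak-to-peak is the default because the bandpassed pulse is
bipolar, and which scalar statistic the bench pipeline used is not
recoverable from the outputs. Calibration fits are ordinary least squares on
the appropriate transformed axes (log-log for the power law, log-linear for
depth decay), with a non-decaying flag when a fitted 1/e length exceeds
100x the sweep span — a decay shallower than ~1% over the sweep is not
resolvable and should not be reported as a length.

`dff_and_correlation` implements the activity-trace utilities: per-ROI
baseline = mean of the lowest decile of samples, `dF/F = (F - F0)/F0`, and
pairwise Pearson correlation. A linear photobleaching detrend is available
but off by default, since the printed normalization formula is ambiguous
about its exact form.

## Image formation

`simulate_scan` rasters the focus across a square field at fixed depth,
generating `floor(dwell * rep_rate)` pulse traces per pixel;
`assemble_image` averages the gated statistic over those pulses per pixel
(4 pulses/pixel at 20 us dwell and 200 kHz). Frame period is the flyback-free
product `pixels * lines * dwell`, which reproduces the printed 0.76 frame/s
at 256 x 256; scanner turnaround is ignored. Scanning is unidirectional
row-major. The transducer-acceptance vignette across the field of view is
available (`apply_aperture = TRUE`) but off by default so that a uniform
specimen images as a uniform field; with a fixed element and a >100 um
field the acceptance would otherwise dominate the image. Richardson-Lucy
deconvolution (10 iterations by default, boundary-renormalized kernel) with
the lateral heated-profile PSF provides the denoising/resolution step; it
preserves non-negativity and conserves flux to better than 1%.

For scan speed the per-pixel forward model uses the effective-source
approximation: the focal-volume-weighted heat density drives one canonical
far-field wavelet per pixel rather than a per-voxel superposition. The
per-voxel superposition (`farfield_trace`) remains the reference path and
the two are consistent by construction for sources small compared to the
standoff.

## Depth sweeps and the two-channel comparison

Two design choices matter when sweeping focus depth:

* **The acoustic leg is held fixed.** As the focus descends, the tissue path
  to the transducer shortens (less attenuation, shorter 1/r) — corrections
  of order 10^-4/um with opposite signs that partially cancel and that no
  desk-scale number constrains. The penetration model this emulates
  attributes depth decay entirely to optical extinction, so the sweep
  drivers evaluate the acoustic leg once, at the measurement geometry, and
  vary only the optical terms. Consequence: the fitted 1/e length equals
  `L_I / n` exactly in the noiseless model (250 um for the brain preset).
* **Surface-clipped stations are excluded from fits.** At depths shallower
  than about one focal half-length (~1.25 w_z), part of the focal volume
  lies above the specimen surface; the station measures geometry, not
  attenuation. These stations are still simulated and reported, but
  excluded from the exponential fit.

The dual-channel comparison uses the spherical organoid phantom at 10 mM
uniform concentration (the top of the stated 0-12 mM biological range,
matching the gel standard) and 53 mW, the constant power of the deep
recordings. The optical channel decays with both the excitation attenuation
and the 50 um emission extinction; its noise floor is calibrated so the
noiseless channel crosses it at 400 um, the observed optical penetration
limit — the floor is then held fixed, so changing the model (e.g. a 10x
brighter fluorophore) moves the crossing as it should. The photoacoustic
floor is the output noise RMS of the averaged measurement; under these
defaults its crossing lies near 2.7 mm, far beyond the 1.2 mm organoid,
consistent with a channel that shows no decline through the full specimen.

```{r}
dc <- run_dual_channel_depth(depths_um = seq(0, 1100, by = 100))
dc$crossings_um
```

## What the synthetic phantoms do and do not emulate

The phantoms reproduce: uniform gelatin standards in the molded geometry
(3 mm x 1.58 mm), spherical organoids (1.2 mm), random non-overlapping
cell fields over background (cells 5-15 um), and hair-like fiducial fibers
as a second contrast channel. They deliberately omit cytoarchitecture,
vasculature, NADH compartmentalization, chromophore mixtures (FAD,
collagen, tryptophan), time-varying concentration, acoustic heterogeneity,
reflections and shear waves. Passing tests on these phantoms demonstrates
that the *chain* behaves as designed — linearity, power law, spectra,
timing, depth budgets — not that real tissue contrast will match; the noise
model is white and Gaussian at the receiver output, which understates
structured interference a real bench sees.

## Numerical choices

* Focal fields are sampled at `w_xy/6` (kernel integration) or finer; a
  pitch coarser than `w_xy/4` is refused.
* Concentration lookup is nearest-voxel; points outside the grid return 0.
* Trace simulations run at the 2 GHz acquisition rate; delays are rounded
  to the nearest sample (0.5 ns).
* Noise of an n-pulse average is drawn once at RMS `sigma/sqrt(n)`
  (distributionally identical to averaging n draws); `average_pulses`
  operates on explicit trace sets and carries the sqrt(n) law in tests.
* Seeds: every stochastic entry point takes a seed and restores the
  caller's RNG state; multi-stage drivers derive per-stage child seeds
  deterministically.
* Problem sizes in the test-suite simulations (sub-mm phantoms at 8-10 um
  pitch, 6-12 pixel scans, 50-seed Monte-Carlo recoveries) were chosen as
  the smallest sizes at which the asserted properties are
  discretization-stable; all scale up linearly through the same interfaces.

## Known limitations

* The absolute voltage scale rests on one calibration constant; absolute
  pressures/voltages outside the calibrated neighborhood are indicative
  only.
* The far-field wavelet fixes the pulse shape; near-field diffraction,
  piston ringing and heterogeneous sound speed are not modeled, so measured
  spectra (e.g. a 60-90 MHz band where the ideal model predicts ~100 MHz)
  will sit below the model's peak, as the designers themselves observed.
* `L_I` presets for gel and organoid media are stated assumptions flagged
  above, not measurements.
* The CLI covers the analysis and simulation drivers; trace containers are
  plain CSV/JSON (and TIFF for images) rather than a binary format.
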