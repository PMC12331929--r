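# pam3p

Forward simulation and trace processing for label-free multiphoton
photoacoustic microscopy of NAD(P)H.

## The problem

NAD(P)H is an endogenous coenzyme whose concentration tracks cellular
metabolism, making it a label-free biomarker for brain cells. But it is a
poor fluorophore: ~5% quantum yield and ~450 nm emission that brain tissue
extinguishes with a 1/e length of only ~50 µm, limiting all-optical imaging
to one or two hundred micrometers of depth. A multiphoton *photoacoustic*
microscope sidesteps the emission path entirely: three ~1300 nm photons are
absorbed simultaneously in a femtoliter focal volume, most of the absorbed
energy thermalizes, and the stress-confined heating launches an ultrasound
pulse that crosses millimeters of tissue with only dB-scale loss to a
transducer below the specimen.

`pam3p` is a desk-scale digital twin of that instrument for anyone designing,
calibrating or reasoning about such a system: it simulates the whole chain on
synthetic phantoms with known ground truth and implements the accompanying
trace-processing and image-reconstruction pipeline.

## The model in brief

- **Excitation**: normalized focal intensity `Î` with *heated-profile*
  (`Î^n`, n = 3) FWHMs of 2.2 µm × 30 µm at NA 0.4/1300 nm; per-pulse heat
  density `H = C·N_A·σ₃·(I_pk·T(z)·Î)ⁿ·τ_p·η_h·n·E_photon`, with
  `T(z) = exp(−z/L_I)` the excitation depth transmission and
  `η_h = 1 − Φ·λ_ex/(n·λ_em) ≈ 0.952` the non-radiative heat fraction.
- **Acoustics**: initial pressure `p₀ = Γ·H`; far-field superposition
  `p(t) = Σ (a_eff/r)·p₀·s(t − r/c)` with a derivative-of-Gaussian wavelet
  peaking at `c/(w_z/2)` (≈100 MHz); tissue attenuation
  `10^(−a·d·f/20)` with `a = 4/270` dB/(mm·MHz) (−4 dB through 2.7 mm at
  100 MHz); transducer delay line (2.6 µs), passband (68–197 MHz),
  20–150 MHz receiver, 140 µV/Pa, 63 dB gain (×1412).
- **Processing**: analytic Morlet CWT scalograms, band-limited inverse-CWT
  denoising, gated peak-to-peak pixel statistics, power-law/linear/
  exponential calibration fits, ΔF/F + Pearson correlation utilities.
- **Reconstruction**: pulses-per-pixel gating and averaging
  (4 pulses/pixel at 20 µs dwell, 200 kHz), frame averaging, Richardson–Lucy
  deconvolution with the lateral heated-profile PSF.

The vignette (`vignettes/pam3p-methods.Rmd`) documents every assumption,
calibration and numerical choice.

## Worked example

Simulate the reference gel-standard measurement (10 mM, 25 mW) and a
brain-preset depth sweep:

```r
library(pam3p)

ph <- make_gel_cylinder(10, diameter_mm = 0.4, height_mm = 1.58, pitch_um = 8)
m  <- simulate_ascan(ph, pam_config(), focus_um = c(200, 200, 100),
                     noise_rms_mv = 0)
m$trace
#> raw_trace: 7667 samples at 2 GHz (3.83 us), 194 mV pk-pk

scalogram(m$trace, 20, 300)
#> scalogram (morlet, omega0 6): 126 scales 20-300 MHz x 7667 samples
#>   ridge peak: 113 MHz at 2.93 us

run_depth_sweep()
#> pam_experiment: depth_sweep (8 conditions, seed 1)
#>  depth_um pa_amplitude_mv in_fit
#>         0        882.3599  FALSE
#>       100       1217.9727   TRUE
#>       ...
#>       700        110.4920   TRUE
#> fit:
#>   length_um = 250 (se 2.6e-13)
```

Reading this: the gel standard yields a 194 mV gated peak-to-peak A-scan
(9.7:1 against the 20 mV receiver noise), arriving 2.93 µs after the trigger
(2.6 µs delay line + 0.33 µs travel) with its spectral ridge near 113 MHz;
the brain-preset sweep decays with a 250 µm 1/e extinction length (the
surface station is excluded from the fit because the focal volume is
partially above the specimen there).

A thin CLI wraps the same drivers:

```sh
Rscript inst/cli/pam3p.R timing --rep-rate 200 --dwell 20
Rscript inst/cli/pam3p.R depth --preset brain --out out/
Rscript inst/cli/pam3p.R denoise --in trace.csv --f-lo 50 --f-hi 90 --out out/
```

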