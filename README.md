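# zeobench

Fluorescence bioimaging is hard to compare across labs: every microscope,
filter set, staining protocol and analysis pipeline changes what a "signal"
means. A practical answer is a physical benchmark sample — lanthanide(III)-
doped Linde Type A (LTA) zeolites dispersed in a dye-stained polyvinyl-alcohol
(PVA) thin film — imaged with the exact hardware and settings of the real
experiment. The homogeneous stained film provides the fluorophore signal and
background, while the zeolites' sharp Eu(III)/Tb(III) f–f emission lines act
as spectrally unmistakable fiducials.

`zeobench` implements the complete analysis of that model system in R, plus a
seeded synthetic-scene generator that emulates the sample and the
hyperspectral confocal measurement, so the entire pipeline is testable and
reproducible without any instrument:

* **Spectral cubes** — 10 × 10-pixel raster scans over 5 × 5 µm at 1 s/pixel,
  one emission spectrum per pixel, with TIFF + JSON-sidecar and long-format
  TSV readers/writers, and neon-lamp wavelength calibration.
* **Virtual filter channels** — commercial bandpass kits (Edmund FITC
  539–556 / Texas Red 604–644 / Cy5 672–712 nm; Chroma FITC 539–550 /
  mCherry 593–667 / ATTO647N 669–741 nm) emulated by integrating each
  spectrum over the transmission window.
* **Photophysics** — packaged constants for F18, MitoTracker Red, ATTO647N,
  Eu(III) and Tb(III): quantum yields, molar absorptivities at the four laser
  lines (465/488/560/633 nm), emission maxima and excited-state lifetimes.
  Brightness is `B(λ) = QY × ε(λ)`, and the per-molecule photon budget of
  emitter *a* over *b* is `(B_a / B_b) × (τ_b / τ_a)`.
* **Signal statistics** — the model system's two-pixel estimate: the average
  of two background pixels is subtracted from two signal pixels, and the mean
  and sample standard deviation of the two nets are reported.
* **Crosstalk** — cross-excitation spectra and the full emission
  bleed-through matrix over dyes × excitations × channels, with automatic
  flagging of off-target signals that exceed a channel's designated pair.
* **Photobleaching** — single-pixel 100 × 1 s spectral series, band-integrated
  traces, 0–1 normalization, and bi-exponential decay fits
  `a₁e^(−t/τ₁) + a₂e^(−t/τ₂) + b`.

## Worked example

```r
library(zeobench)

# Brightness of F18 at the 488 nm laser line, from the packaged constants
brightness(dye_record("F18"), 488)
#> [1] 69229.87

# Per-molecule photon budget of F18 over directly excited Eu(III)
photon_budget_ratio(dye_record("F18"), dye_record("Eu"), 488, 465)
#> [1] 359822609148

# Simulate the benchmark film (150 uM F18 + doped zeolites), scan it at
# 488 nm, and emulate the Edmund filter kit with background subtraction
scene <- scene_model_system(dyes = "F18", seed = 1)
cube  <- simulate_scan(scene, excitation_nm = 488, seed = 2)
bg    <- simulate_scan(background_scene(scene), excitation_nm = 488, seed = 3)
channel_signal_table(list(F18 = cube), list(bg), filter_set_preset("edmund"))[,
  c("label", "excitation_nm", "channel", "mean", "sd")]
#>   label excitation_nm  channel         mean         sd
#> 1   F18           488     FITC 8.317092e+06 3910.85845
#> 2   F18           488 TexasRed 1.419630e+04   89.97054
#> 3   F18           488      Cy5 4.956095e+01   35.73131

# Single-pixel accelerated bleaching of the same film
series <- simulate_bleach_series(scene, pixel = c(7, 7), excitation_nm = 488,
                                 seed = 4)
trace  <- minmax_normalize(trace_from_series(series))
fraction_lost(trace, 10)
#> [1] 0.7454658
fit_decay(trace, n_components = 2)$taus
#> [1]  3.992062 23.652942
```

The channel table is the crosstalk story in miniature: F18's intended FITC
signal is enormous, but its broad emission tail still leaves a clear signal
in the Texas Red window (≈1.4 × 10⁴ a.u.) — the bleed-through that, at these
staining ratios, outshines MitoTracker Red's own signal and would cause
false positives in co-localization. The bleaching trace loses ~75 % of its
intensity in the first 10 s and the fit recovers the shipped F18 kinetics
(τ ≈ 4 s and 25 s).

`run_pipeline(default_pipeline_config(seed = 1), "out")` executes the whole
chain — simulation, channel signals, crosstalk matrix + flags, bleaching
fits — and writes deterministic TSV/JSON tables plus a cube manifest.

## Documentation

The methods vignette (`vignettes/model-system-benchmarking.Rmd`) describes
the forward model, the noise model, every tunable parameter with its default
and rationale, the zeolite/film pixel classifier, and the known limitations
of the synthetic scenes.
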