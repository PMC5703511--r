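---
title: "A zeolite thin-film model system for benchmarking fluorescence bioimaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A zeolite thin-film model system for benchmarking fluorescence bioimaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeobench)
```

## The model system

The benchmark sample this package analyses consists of two spectrally
complementary components in one thin film:

* a **polyvinyl-alcohol (PVA) film** homogeneously stained with one or more
  organic fluorophores — F18 (a fluorescein membrane stain, 150 µM),
  MitoTracker Red (a rhodamine, 0.1 µM) and ATTO647N (a carborhodamine,
  0.1 µM) — each with a broad emission band tens of nm wide;
* micron-scale **Linde Type A zeolites** whose exchangeable cations are
  replaced by Eu(III) or Tb(III). Lanthanide f–f transitions give sharp
  emission lines (FWHM below ~10 nm) at reproducible positions, with the
  dominant Eu(III) ⁵D₀→⁷F₂ line at 616 nm and the dominant Tb(III) line at
  544 nm.

A scanning confocal microscope with a spectrograph detector records a full
emission spectrum per pixel: a 10 × 10-pixel raster over 5 × 5 µm at 1 s per
pixel, at one of four laser lines (465, 488, 560, 633 nm at 2, 7.2, 1.2 and
2.9 µW). Each laser images its own corner quadrant around one anchor
zeolite, so no area is illuminated twice and bleaching during acquisition is
minimized. Filter-based microscopy is then *emulated*: a commercial bandpass
channel is applied virtually by integrating each pixel spectrum over the
filter's transmission window.

Everything downstream — background subtraction, brightness arithmetic,
crosstalk matrices, bleaching kinetics — is implemented against this data
model, and a seeded generator produces synthetic scenes with known ground
truth so that every stage is testable quantitatively.

## The forward model

The expected spectrum of a pixel at position $p$ under excitation
$\lambda_{ex}$ with power $P$ and dwell time $T$ is

$$ I(\lambda) \;=\; B \;+\; \sum_{s}\; k \, c_s(p)\,
   \varepsilon_s(\lambda_{ex})\, \Phi_s\, P\, T\,
   f_s(t)\, S_s(\lambda), $$

where $B$ is a constant detector/autofluorescence floor (a.u. per nm),
$c_s$ the local concentration of species $s$, $\varepsilon_s$ its molar
absorptivity, $\Phi_s$ its quantum yield, $f_s(t)$ its surviving bleach
fraction, $S_s(\lambda)$ its unit-area emission shape, and $k$ a global gain
mapping these arbitrary units to pseudo-counts. The model is deliberately
linear: pixels are independent (no point-spread function), there is no
saturation, and intensities are arbitrary units — no detector-efficiency
correction of the intensity axis is applied, matching how the instrument
data are treated.

Key parameter choices:

| parameter | default | rationale |
|---|---|---|
| wavelength grid | 400–820 nm, 1 nm | upper bound covers the 817 nm limit used in the red-dye bleach windows; the true detector range is instrument-specific |
| scan geometry | 10 × 10 px, 0.5 µm/px, 1 s/px | the benchmark's standard scan |
| film concentrations | 150 / 0.1 / 0.1 µM | the model system's staining ratios (F18 deliberately 1500× the others) |
| background level $B$ | 20 a.u./nm | a visible but non-dominant floor; ~8 × 10³ integrated counts per pixel |
| gain $k$ | 1 | makes 1 µM × 1 M⁻¹cm⁻¹ × 1 µW × 1 s ↦ 1 pseudo-count/nm |
| zeolite loading | 2 × 10⁵ µM | ~0.2 M local lanthanide from the ion exchange; chosen so zeolite counts are the same order as dye-film counts, which is how the real sample behaves despite the tiny lanthanide brightness |
| zeolite geometry | r = 1.5 µm, bright rim 0.9–1.5 µm, core at 20 % loading | doped zeolites light up at the edges while the center appears dark |
| noise | Poisson, then Gaussian read noise σ = 2 | CCD counting statistics plus readout; clamped at zero counts |

### Emission and excitation shapes

Dye emission bands use the log-normal lineshape routinely fitted to dye
spectra, parameterized by peak, FWHM and a red-tail asymmetry (default 1.3):
F18 517/35 nm, MitoTracker Red 598/45 nm, ATTO647N 664/50 nm. Peaks are the
tabulated emission maxima; widths mimic the published spectra, which exist
only as figures. Lanthanide shapes are sums of narrow Gaussians at the
standard transition positions (Tb 490/544/585/620 nm, Eu 592/616/650/700 nm,
FWHM 8 nm); the relative line intensities inside LTA zeolites are not
published, so the defaults are representative and configurable.

Molar absorptivities at the four laser lines are tabulated constants and
always take precedence; between them, a mirrored log-normal excitation band
anchored at the absorption maximum interpolates $\varepsilon(\lambda) =
\varepsilon_{max} \cdot s(\lambda)$. Outside the band's support the
absorptivity is zero — which is why no emission appears when a dye is
excited beyond the red edge of its absorption band.

### Long-pass edges

The emission path carries a long-pass filter per laser line to reject
scattered excitation light. These are modelled as hard cutoffs on the
*emitted* light: 539 nm for 465/488 nm excitation (the 532 nm long-pass only
becomes transparent around 539 nm — which is also why both green filter
windows start at 539 nm), 566 nm for 560 nm and 652 nm for 633 nm
excitation. The last two are nominal edge positions of the corresponding
long-pass filters plus a small transition margin; only the 532 nm edge is
documented precisely, so these are package choices. The detector floor $B$
is not cut: it models dark counts and stray light on the detector side.

## Band integration

Virtual filters integrate the trapezoid rule on the stored grid, with window
endpoints that fall between samples snapped by linear interpolation of the
integrand. This makes the rule exactly linear in the intensity and exactly
additive over adjacent windows (a partition of the axis reproduces the
full-range integral to rounding error), at the cost of the usual
$O(\mathrm{step}^2)$ truncation against the true continuous integral.
Windows that only partially overlap the axis integrate over the
intersection; an empty intersection yields zero with a warning rather than
an error.

## Classifying zeolite vs film pixels

Zeolite pixels are identified by their uniquely narrow emission peaks
protruding from the broad dye bands. The statistic is the maximum excess of
the spectrum over a 31 nm running-median baseline, divided by the total
integrated intensity. Two design points matter:

* **The statistic has a ceiling.** For a pure 8 nm line of relative weight
  ~0.5 the statistic cannot exceed ≈ 0.06 /nm, because the line's own area
  dominates the denominator. The decision threshold (default 0.015 /nm)
  therefore sits between the smooth-band floor of noisy dye spectra
  (≈ 0.003) and the value of a realistic zeolite rim pixel (≈ 0.02–0.03),
  not near the pure-line ceiling.
* **The long-pass edge must be masked.** The cut-on step the long-pass
  filter imprints on every spectrum looks like a narrow feature to a running
  median. The statistic is therefore evaluated only above the edge for the
  cube's excitation line, where the spectrum is genuinely smooth unless a
  line protrudes.

Default pixel selection for the two-pixel statistic follows the same
classification: the two film pixels farthest from any zeolite-classified
pixel, and the two classified zeolite pixels of maximum intensity, with
raster order breaking ties; both are overridable.

## Bleaching

Photobleaching is modelled empirically as a bi-exponential decay plus a
non-bleaching baseline, $f(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + b$
with $a_1 + a_2 + b = 1$. The shipped per-dye defaults are calibrated to the
observed single-pixel behaviour of the model system:

| dye | $a_1$ | $\tau_1$ | $a_2$ | $\tau_2$ | behaviour encoded |
|---|---|---|---|---|---|
| F18 | 0.7 | 4 s | 0.3 | 25 s | ~70 % of the intensity lost in the first 10 s, then levelling toward background |
| MitoTracker Red | 0.5 | 7 s | 0.5 | 15 s | fast ~50 % loss, essentially gone by 40 s |
| ATTO647N | 0.5 | 7 s | 0.5 | 40 s | fast ~50 % loss, a long-lived tail surviving toward 100 s |

The lanthanide dopants do not bleach. A simulated series samples the decay
instantaneously at frame starts $t = 0, 1, \dots$ s, so noise-free traces
match the closed forms exactly. Within a single raster scan each pixel is a
fresh, previously unilluminated spot, so by default bleaching does not build
up across a scan (`bleach_mode = "fresh"`; prior illumination of the whole
area enters through `t0`). A `"cumulative"` mode that advances the bleach
clock by one dwell per raster pixel is available for emulating stationary
wide-field exposure.

Decay fits are nonlinear least squares (Levenberg–Marquardt) with
nonnegative amplitudes, time constants and baseline. Initialization is fixed
for determinism: equal amplitudes, baseline at the trace minimum, time
constants log-spaced over $(t_{max}/50,\; t_{max}/2)$. Traces are presented
min–max normalized to [0, 1]; the fraction lost by time $t$ is
$1 - I(t)/I(0)$ with $I$ linearly interpolated and $I(0)$ the first recorded
frame (not a fitted amplitude).

## Crosstalk bookkeeping

For each single-dye scene the package tabulates the background-subtracted
two-pixel signal in every (excitation × filter channel) cell, across both
packaged kits (six channels). Each channel has a designated (dye,
excitation) pair — FITC ↔ (F18, 488), Texas Red/mCherry ↔ (MitoTracker Red,
560), Cy5/ATTO647N ↔ (ATTO647N, 633) — and any other cell whose mean signal
exceeds the designated pair's is flagged as bleed-through. Ratios are
reported on background-subtracted means with negative nets clipped to zero
(and marked), to avoid noise-driven nonsense ratios.

With the benchmark's staining ratios, the flags tell the model system's
central story: the 1500-fold concentration advantage of F18 makes its broad
emission tail exceed MitoTracker Red's own signal inside the red channels,
while only ATTO647N at 633 nm holds its designated far-red channels.

## What the synthetic scenes do and do not emulate

The generator reproduces the features the analysis actually relies on:
spectrally distinct broad and line emitters, the quadrant scan geometry with
an anchor zeolite at the image corner, realistic relative signal levels,
counting noise, and per-dye bleaching kinetics. It deliberately omits
optics-level effects — diffraction/PSF blur between pixels, film-thickness
and focal-depth variation, spectral shifts from the local environment,
detector-efficiency wavelength dependence, and pH- or quenching-driven
changes in quantum yield. Tests passing on synthetic scenes therefore
validate the *analysis chain* (integration, subtraction, classification,
crosstalk and kinetics arithmetic), not these instrument- and
sample-dependent effects; absolute intensities in arbitrary units carry no
meaning across instruments.

Problem sizes used throughout the package's own test material — 10 × 10
cubes, 100-frame traces, 10–20 seed replicates, 200 labelled pixels — match
the scale of the benchmark protocol itself, which is intentionally small:
one scan is 100 spectra.

## Numerical and degenerate-input conventions

* Wavelength axes must be strictly increasing; raw spectra must be
  nonnegative, and only background-subtracted spectra (flagged) may carry
  negative samples.
* Pixel indices are 0-based with (0, 0) top-left in all interchange formats;
  1-based inside R, following each language's convention.
* TIFF cube stacks store 32-bit samples with an affine offset/scale recorded
  in the JSON sidecar (TIFF samples live in [0, 1]); the long-format TSV
  route is exact. A frame-count/axis mismatch on reading is an error naming
  both counts.
* All randomness flows from explicit seeds; identical configuration + seed
  gives bit-identical cubes and byte-identical pipeline tables.
* A constant trace cannot be min–max normalized (zero dynamic range, error);
  an all-zero spectrum classifies as film with a warning; a non-positive
  film net makes contrast infinite, flagged rather than thrown.
* Underdetermined wavelength calibrations (fewer lines than degree + 1) are
  errors; decay fits that fail to converge raise an error carrying the last
  parameter iterate.

## Known limitations

* The Eu(III)/Tb(III) line intensity ratios inside LTA zeolites and the
  true spectrometer range/resolution are not published; the defaults are
  reasonable stand-ins and configurable.
* The mapping from laser power to photon flux is absorbed into the single
  gain constant $k$; absolute simulated counts are not calibrated to any
  instrument.
* MitoTracker Red, ATTO647N and Tb(III) excited-state lifetimes default to
  typical class values (1.7 ns, 3.5 ns, 1.8 ms); only the F18 (~5 ns) and
  Eu(III) (~0.5 ms) lifetimes that anchor the photon-budget comparison are
  part of the benchmark's constants.
* The estimated ~300-fold dye-loading advantage of Eu(III) zeolites over the
  film dye is carried as a documented constant (`eu_loading_advantage`), not
  derived.
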