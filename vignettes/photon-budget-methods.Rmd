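---
title: "Methods: absolute photon budgets for microfluidic optical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute photon budgets for microfluidic optical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonbudget)
```

## The model and its assumptions

`photonbudget` computes the output voltage of a microfluidic fluorescence
or absorption analyser as a function of analyte concentration by linking
per-component algebraic factors: every stage either multiplies the photon
rate by a geometric/spectral fraction in [0, 1] or, after detection, by an
electronic gain. The core assumptions are:

* **Perfect alignment.** Focal spot, detector-view region and channel
  centreline are concentric and coaxial; misalignment is out of scope.
* **Flat-disk interception.** A lens (or bare aperture) of radius R at
  distance x intercepts the solid angle πR²/x², capped at the source cone
  Ω_S (excitation side) or at a hemisphere (collection of isotropic
  emission: a single lens on one side of the sample can never collect more
  than half of 4π). The exact spherical-cap form is available via the
  `exact_cap` option; the Monte-Carlo sampler quantifies the difference,
  which grows with the angle the aperture subtends.
* **Single nominal wavelengths.** No spectra; the Stokes shift enters only
  through the separate `emission_wavelength` and the filter's band ratio.
* **Base-e Beer–Lambert.** `exp(-eps*C*l)` with eps in L mol⁻¹ cm⁻¹, as is
  natural for the linked algebra. Decadic (base-10) datasheet coefficients
  are converted by ln(10) at construction (`epsilon_base = "10"`).
* **No secondary optical effects.** Lens Fresnel losses, aberrations,
  vignetting, inner-filter re-absorption of fluorescence, photobleaching,
  quenching, scattering and waveguiding in the liquid channel are all
  neglected. Fibers carry one scalar transmission efficiency.
* **Deterministic thresholds.** The MDL is the concentration where the
  noise-free calibration curve crosses the detector noise floor — a
  threshold-crossing definition, not a statistical (3σ/IUPAC) one. Noise
  is a single floor value; saturation is hard clipping.

## Geometry of the three coupling families

*Perpendicular* systems illuminate the channel or film normally. With a
lens, the spot at the sample is the image of the emitting area; with no
optics, the illuminated footprint at stand-off d is taken as
`A_S + Ω_S·d²` — the near-field source extent plus the far-field cone —
which stays finite as d → 0 and reduces to the bare cone footprint at
long range. The fraction of spot photons landing on channel fluid, and the
fraction of those the detector sees, come from exact circle/strip segment
areas (`circle_strip_area()`); because spot and view circles are
concentric, their triple intersection with the channel strip is again a
circle-strip area of the smaller circle, so no 2-D quadrature is needed in
the engine (the tests verify the segment formulae against quadrature).

*Cross-fiber* systems launch a collimated beam (the fiber core diameter is
comparable to the channel) across the channel width; *coaxial* systems
launch along the channel axis and collect with a second fiber facing the
channel exit. The capture fraction of a fiber at distance d from an
isotropic emitter is `min(πR_F², Ω_F d²)/(4π d²)`: line-of-sight solid
angle, limited by the acceptance cone `Ω_F` computed from NA = n·sin θ_F
with the refractive index of the medium the fiber looks into (1.33 for a
water-filled channel).

## The coaxial integral

Excitation decays as `p(x) = p0·e^(-εCx)` along the channel; each slice
absorbs `p(x)·εC·dx`, emits isotropically with yield QY, and is captured
with the distance-dependent fiber fraction above. The integral is evaluated
as a composite-Simpson sum over slices uniform in the *absorbed fraction*
`s = 1 − e^(-εCx)` rather than in length: `d(fluor) = p0·QY·cap(x)·ds`
exactly, so the quadrature nodes concentrate automatically where photons
are actually absorbed and the rule remains accurate when the absorption
depth `1/(εC)` is far smaller than the channel. With the default
`n_slices = 1000`, doubling the slice count changes the result by less
than 10⁻⁶ relative (asserted in the tests).

The physics of this geometry is instructive: captured fluorescence rises
linearly, flattens near an along-channel absorbance of order one, and then
*declines*, because at high concentration all absorption happens at the
channel entrance — the far end from the collection fiber. The engine
therefore treats coaxial monotonicity as a thin-regime property only, and
the dynamic-range solver reports an open-ended range (with the optical
asymptote voltage attached) when the plateau sits below detector
saturation.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `photons_per_watt_nm` constant | s⁻¹W⁻¹nm⁻¹ | 5.03×10¹⁵ | the standard rounded engineering constant; `exact = TRUE` uses 1/(hc) (0.08% different) for validation |
| `magnification` | — | `"area"` | image area scales with (x₂/x₁)²; a `"linear"` mode scaling by x₂/x₁ is provided for cross-checks — both coincide at 2F–2F imaging, the only condition with a fixed expected value |
| `n_slices` | count | 1000 | coaxial quadrature resolution; ≥ 100 enforced |
| bisection bracket | mol/L | [10⁻¹⁵, 10] | spans sub-fM to paste-like; relative tolerance 10⁻⁶ on concentration, deterministic (no randomness anywhere in the engine) |
| `epsilon_base` | — | `"e"` | the attenuation algebra is natural-log; decadic datasheet values convert by ln 10 |
| Avogadro, electron charge | — | 6.022×10²³, 1.602×10⁻¹⁹ C | fixed conversion constants |

Degenerate inputs are rejected at construction (zero distances, NA > n,
noise floor ≥ saturation, both or neither of power/lumens); configuration
files are schema-checked with *all* violations reported at once, and
unknown keys are errors — silent unit mistakes are the dominant failure
mode in radiometric chains, so config units are fixed (cm, nm, cm²,
mol/L, V, A/W) and spelled out in the key names.

## The example grid: what it emulates, and what it does not

`example_components()` is a synthetic component library representative of
its device classes, not a record of any specific commercial parts: 5 mW
LED dies (0.04 cm², 10°/150° blue at 470 nm, 120° UV at 365 nm), a
1.5 cm focal-length, 1.5 cm diameter lens used at its 2F–2F conjugates
(x₁ = x₂ = 3 cm) with collection at x₃ = 1.5 cm, 100 µm core NA 0.22
fibers, a 100 µm square microchannel (1 cm long; 1000 µm for the coaxial
case), a 100 µm film of 1 cm² extent, a fluorescein-like analyte
(ε = 8×10⁴ L mol⁻¹ cm⁻¹, QY = 0.9, emission 520 nm), a 25 nm FWHM / 90%
filter against a 50 nm emission band, a SiPM (QE 0.2, gain 10⁶, 1 mV
floor, 500 mV saturation) and an amplified photodiode (0.25 A/W, 1 mV
floor, 5 V saturation). The bench layout places bare source and detector
at a 1 cm stand-off when no optics are used (room for substrate and
filter stack) and the collection fiber 500 µm from the channel end (a
substrate wall between channel and ferrule).

With these choices the grid reproduces the qualitative design rules the
methodology exists to expose — lens coupling beats no optics beats coaxial
fiber at fixed concentration; thin films beat microchannels (more
interrogated molecules per concentration); the collimated 10° LED beats
the 150° LED — and the tests assert exactly those orderings. What passing
those tests does *not* show: that the absolute MDLs match any particular
published instrument (real LED fluxes, filter curves, responsivities and
distances differ), or anything about noise-limited detection, since the
noise floor is an input, not a model output.

## Numerical and design choices

* **Capped fractions everywhere.** Every geometric ratio is clamped to its
  physical bound (1, or ½ for one-sided collection of isotropic light)
  so that extrapolated algebra can never create photons.
* **Root finding.** MDL and saturation crossings are bisected on
  log-concentration after a sign check on the bracket ends; a bracket
  without a crossing returns `NA` (MDL) or the open-ended report (dynamic
  range) rather than a fabricated number. The closed form noise/slope is
  recovered to 0.1% on linear trains (tested).
* **Sensitivities** are central finite differences with relative step
  10⁻⁴ on the unclipped signal; normalised sensitivities are exact
  exponents for power-law dependences (1 for multiplicative parameters,
  −2 for the collection distance).
* **Monte-Carlo oracle.** Directions are sampled uniformly over the
  spherical cap (cos θ uniform), positions uniformly over the emitting
  disk; the sampler is seeded, restores the global RNG state, and is a
  first-class exported function so users can audit the flat-disk
  approximation at large angles, where it is knowingly biased.
* **Determinism.** The engine contains no randomness; curve exports round
  to 6 significant digits so identical inputs give identical bytes, and
  every export carries the tool version and an FNV-1a hash of its config.

## Problem sizes

The shipped tests run the full 36-system grid (signals, MDLs, dynamic
ranges), Monte-Carlo checks at 10⁶ samples per geometric factor, and
25-point calibration curves; all targets are algebraic or
one-dimensional quadratures, so the complete suite executes in seconds on
a single CPU.

## Known limitations

Beyond the assumption list above: no spectrometer model (absolute
spectrometer efficiency is rarely specified); pulse-counting electronics
are represented only by the electron rate, without discriminator or
pulse-shape modelling; no mirror-based (e.g. ellipsoidal) collection; the
absorption-mode collection path treats the transmitted beam as refocused
(lens) or geometrically diverging (no optics) without diffraction; and
parameter estimation from measured curves (inverting the model) is not
implemented.
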