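# photonbudget

Absolute photon-budget modelling of microfluidic optical analysis systems.

Fluorescence and absorption readout of analytes in microchannels and thin
films is usually reported on relative scales; designing an instrument,
however, requires knowing the *absolute* chain from molecules to volts.
`photonbudget` traces photon and electron rates stage by stage through an
optical train — light source, coupling optics, sample, spectral filter,
detector, electronics — from datasheet-style component specifications, and
derives absolute calibration curves (detector output vs. concentration or
molecule count), minimum detection limits (MDL) and dynamic ranges. It is
aimed at designers of lab-on-chip fluorometers and absorbance readers who
want to compare sources, coupling schemes, sample geometries and detectors
before building anything.

## The model

Photons per second from the source:

```
P_S = 5.03e15 · P(W) · λ(nm),          P(W) = lumens / (683 · V(λ))
```

with the emission cone 2θ giving the solid angle `Ω_S = 2π(1 − cos θ)`.
Geometric transport between stages is algebraic: a lens of radius R at
distance x intercepts `min(1, πR²/(Ω_S x²))` of a conical source and
`min(½, R²/4x²)` of isotropic sample emission; imaging follows the
thin-lens conjugates `1/F = 1/x₁ + 1/x₂`; a fiber with acceptance
`NA = n sin θ_F` couples `min(1, Ω_F D²/A_S) · πR_F²/(Ω_S D²)` of an
extended source. Overlap of the focal spot, the detector-view region and
the channel is computed from circle/strip geometry. In the sample,
Beer–Lambert attenuation gives

```
P_T = P_c e^(−εCl),   P_abs = P_c (1 − e^(−εCl)),   P_Sa = P_abs · QY
```

and the detection chain applies the filter band ratio
`min(1, FWHM/Δλ_em) · T`, the detector area fraction, `E_D = P_D · QE · G`
(or a responsivity in A/W), a transimpedance and an analog amplification.
Concatenating the stages yields the calibration curve; its crossing of the
detector noise floor is the MDL, its crossing of saturation sets the
dynamic range. Coaxial fiber-in-channel coupling needs one integral along
the channel and is genuinely non-linear at high concentration. A seeded
Monte-Carlo photon sampler (`estimate_fraction()`) provides brute-force
verification of every algebraic geometric factor.

## Worked example

A 5 mW, 10° blue LED imaged by a 1.5 cm lens onto a 100 µm square
microchannel of fluorescein-like dye (ε = 8×10⁴ L mol⁻¹ cm⁻¹, QY = 0.9),
collected by a second lens onto a SiPM (1 mV noise floor, 500 mV
saturation):

```r
library(photonbudget)
tr <- example_train("lens", "microchannel", "led_blue_10", "sipm")
signal_at_concentration(tr, 1e-7)$trace
#>       source      into_sample      transmitted         absorbed
#>    1.182e+16        6.667e+14        6.666e+14        5.333e+10
#>      emitted after_collection     after_filter      at_detector
#>    4.800e+10        3.000e+09        1.350e+09        1.350e+09
#>    electrons         output_V
#>    2.700e+14        2.163e-03
```

Of 1.18×10¹⁶ photons/s emitted, 5.6% land on channel fluid; at 100 nM
only 8×10⁻⁵ of those are absorbed; the collection lens captures 6.25% of
the isotropic fluorescence and the filter passes 45%, leaving 1.35×10⁹
photons/s at the detector — 2.16 mV of output. The performance extraction:

```r
find_mdl(tr) * 1e9        # 46.24  (nM at the 1 mV floor)
dynamic_range(tr)         # 504.7  (> 500: Beer-Lambert curve flattening)
sensitivity(tr, "collection.x3", 1e-8)   # -2 (inverse-square collection)
```

`example_system_grid()` builds the full 36-system comparison grid
(3 sources × {lens, no optics, cross fiber, coaxial fiber} × {microchannel,
thin film} × 2 detectors) and `design_sweep()` tabulates MDL and dynamic
range for all of them; `generate_fixtures()` writes the same grid as
editable YAML configs. A command-line interface wraps these verbs:

```sh
Rscript inst/cli/photonbudget.R fixtures --out-dir fixtures
Rscript inst/cli/photonbudget.R simulate --config fixtures/lens_microchannel_led_blue_10_sipm.yaml --out curve.csv
Rscript inst/cli/photonbudget.R oracle --seed 1 --case source-lens
```

Component values in the examples are representative, synthetic datasheet
numbers for their device classes; see the methods vignette
(`vignettes/photon-budget-methods.Rmd`) for every default and its
rationale.

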