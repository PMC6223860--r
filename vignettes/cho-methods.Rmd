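---
title: "Task-based CT image quality with a channelised Hotelling observer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based CT image quality with a channelised Hotelling observer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choiq)
```

## The problem

Diagnostic reference levels benchmark CT *dose*, but say nothing about
whether the images answer the clinical question. Task-based image-quality
assessment closes that gap: a model observer is given a well-defined
detection task — here, finding a 5-mm low-contrast lesion (nominal 20 HU
contrast at 120 kVp) in an abdominal phantom — and its ROC performance (AUC)
becomes the image-quality figure of merit, to be read alongside the
displayed CTDIvol. Repeating this across phantom sizes and scanners shows
how detectability behaves as dose-modulation systems react to patient
habitus.

`choiq` implements that analysis chain end to end: a channelised Hotelling
observer (CHO) with dense difference-of-Gaussian (DDoG) channels, a
nonparametric bootstrap ROC analysis, reading of classic CT DICOM series
with ROI extraction, study-level aggregation statistics, and a synthetic
ROI generator that stands in for scanner acquisitions in all testing.

## The observer model

Each square ROI `g` (in HU) is reduced to a J-vector `v = t(U) g` by a bank
of J = 10 radially symmetric bandpass channels. Channel `j` has the
frequency response

    C_j(rho) = exp(-0.5 (rho / (Q sigma_j))^2) - exp(-0.5 (rho / sigma_j)^2),
    sigma_j = sigma0 * alpha^(j-1)

with defaults `sigma0 = 0.005`, `alpha = 1.4`, `Q = 1.67` — the standard
dense-DDoG setting, chosen in the literature to mimic the spatial-frequency
selectivity of early human vision, which makes the observer anthropomorphic
without an internal-noise term. The decision variable of image `i` is the
dot product `lambda_i = t(w) v_i`, with the Hotelling template

    w = solve(K, v_theo)

where `K` is the channel covariance estimated from the signal-absent images
only and `v_theo` is the channelised *theoretical* signal: a centred 2-D
Gaussian with FWHM 5 mm. Using the theoretical rather than the empirical
mean signal avoids overfitting the small signal-present sample (40 images);
the empirical-mean alternative remains available via
`fit_cho(signal_mode = "mean")` for comparison. No internal noise is added
anywhere in the score path.

Scores from the two classes feed a Mann-Whitney AUC (pair counting, ties
half-credited — identical to the trapezoidal ROC area). The bootstrap
resamples each class independently with replacement at its own size
(90 / 40 by default) for 500 replicates, reporting the replicate mean and
SD. Whether the original procedure resampled one or both classes is not
specified anywhere; both-class resampling is the documented choice here.

## Parameters that matter

| parameter | default | unit | notes |
|---|---|---|---|
| `sigma0`, `alpha`, `Q`, J | 0.005, 1.4, 1.67, 10 | cycles/pixel | channel bank; see below on units |
| lesion FWHM | 5 | mm | the 5-mm sphere is the binding task |
| lesion contrast | 20 | HU | nominal contrast at 120 kVp |
| design | 90 absent / 40 present | images | 10 scans x (9 background + 4 lesion ROIs) |
| `n_boot` | 500 | replicates | bootstrap ROC experiments |
| ROI size | 64 | px | not stated by any protocol; see below |
| pixel spacing | FOV/512 | mm | 320/370/420 mm FOV presets on an assumed 512 matrix |
| noise SD | 10 | HU | synthetic generator only |

**Frequency units.** `sigma_j` is interpreted in cycles/pixel: the published
`sigma0 = 0.005` matches the dense-DDoG literature in those units, and no
units are stated alongside the value. The interpretation matters: it couples
the channel bank to the pixel grid rather than to millimetres, which is also
why the same bank works across the three FOV presets.

**ROI size.** 64 x 64 px covers more than ten times the 5-mm lesion at all
three pixel spacings and keeps FFTs cheap. There is a hard lower bound
worth knowing: on an N-px grid the lowest non-DC frequency is 1/N
cycles/pixel, and for N much below ~64 the narrowest default channels have
essentially no response at any sampled bin, making the channel covariance
numerically singular. `build_template()` detects this (condition number
above 1e12) and tells the user to add a ridge or more images; tests that use
16-px ROIs deliberately widen `sigma0` instead.

**Template conditioning.** The template is obtained by a symmetric Cholesky
solve, never an explicit inverse; ridge regularisation is off by default
because 90 samples estimate a 10 x 10 covariance comfortably. `v_theo` uses
unit amplitude by default — AUC is invariant to template scale, so the
nominal 20 HU amplitude is cosmetic.

**No background subtraction.** The channels have exactly zero DC response
(the DC bin is forced to 0 when the bank is sampled on the DFT grid), so
constant-HU offsets cannot reach the scores and no mean-background
subtraction step exists.

## The synthetic generator: what it emulates, what it does not

`generate_dataset()` realises the stated experimental world: 90 noise-only
and 40 signal-bearing square ROIs in HU, lesion centred at pixel
`floor(N/2)` (0-based), at the pixel spacing of the chosen phantom preset.
Noise is stationary Gaussian — white by default (SD 10 HU, a typical
abdominal-protocol noise magnitude), or optionally shaped in the frequency
domain by a radial `f^(exponent/2)` filter (DC exactly zero, cosine taper
from 60% of Nyquist) as a crude stand-in for filtered-backprojection
texture. The whole dataset is a deterministic function of its configuration,
including the seed.

It does **not** emulate: reconstruction-kernel or iterative-reconstruction
noise correlations, beam hardening, partial-volume effects through slice
thickness, tube-current modulation, off-centre lesions, or multi-slice
structure (generation is single-slice 2-D, matching the 2-D observer). A
green test on synthetic data therefore establishes the *statistical
machinery* — channelisation, covariance, template, ROC, bootstrap,
aggregation — not scanner-specific image physics. On real data the
stationary-Gaussian assumption holds only approximately, which is exactly
why the observer estimates `K` from measured signal-absent images.

**DICOM round trip.** The export path quantises pixels to integer HU
(signed 16-bit, rescale slope 1 / intercept -1024), so write-then-read is
exact for integer-valued images; continuous synthetic images round-trip to
within 0.5 HU by construction. The bundled reader covers classic
uncompressed little-endian single-frame CT only.

## Aggregation statistics

Per phantom size, CTDIvol and AUC distributions are summarised by median,
quartiles and 5th/95th percentiles using linear interpolation between order
statistics (R's type-7 rule — the single documented convention; no source
states a rule, and the worked example 1..10 giving q1 = 3.25, q3 = 7.75
pins it down). "Outliers" are the values outside the 5th-95th percentile
band, mirroring the box-figure convention, not a Tukey fence.

Cross-size correlations of AUC use the Pearson coefficient on
pairwise-complete centres, stratified by the two ATCM families
(target-noise-level vs reference-mAs). Strength labels follow the Evans
scale on |r| with half-open intervals ([0, 0.20) very weak ... [0.80, 1]
very strong); the printed scale abuts at two decimals, so the upper edge of
each band is taken exclusive except the last. A cell with fewer than three
complete pairs is undefined; `pearson_r()` raises the undefined-correlation
error directly, while `correlation_matrix()` returns `NA` for that cell so
the rest of the matrix survives — a deliberate reading of the per-cell
error contract.

**Cohort simulator calibration.** `simulate_study_records()` validates the
aggregation stack against a known ground truth. AUC values live in (0, 1),
so they are generated through a probit link from a latent Gaussian — but a
nonlinear link attenuates Pearson correlation, so the latent correlations
are pre-compensated (a NORTA construction: the latent pairwise correlation
is solved from a closed 1-D integral so that the *AUC-scale* Pearson
correlation equals the requested `latent_r` in expectation). Without this,
a requested 0.5 came out around 0.42-0.47 depending on the size pair's mean
level.

## Numerical choices and degenerate inputs

- DFT-grid sampling of the channel responses (no continuous quadrature);
  the inverse DFT of the real, even response is real and radially symmetric
  to machine precision, and is stored as real.
- Covariance uses the unbiased (n - 1) denominator and is symmetrised
  exactly before the solve.
- `rcond()` guards the template solve; condition numbers above 1e12 are
  treated as singular with an actionable error.
- Ties in the AUC are half-credited; this matters only for degenerate
  (e.g. quantised) score sets and makes `auc(a, p) + auc(p, a) = 1` exact.
- All bootstrap and generator randomness flows through a private RNG stream
  seeded from the configuration; the caller's RNG state is restored
  afterwards.
- `noise_sd_hu = 0` degenerates to a deterministic dataset; a zero-amplitude
  lesion makes the two classes exchangeable by construction, which the null
  calibration test exploits.

## Known limitations

- The DICOM layer is deliberately minimal (no sequences, compressed
  syntaxes, or enhanced multi-frame objects) and exists because no DICOM
  package is available in the target environment.
- The correlated-noise option is a texture stand-in, not a reconstruction
  model; conclusions about correlated-noise performance transfer to real
  scanners only qualitatively.
- The per-scan split of the 130-image design (4 signal + 9 background ROIs
  per scan, 10 scans) is a documented convention; only the 40/90 totals are
  fixed by the protocol.
- Background ROI placement on real phantoms is user-configured; no automatic
  sphere detection or registration is attempted.
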