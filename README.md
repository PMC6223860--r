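# choiq — task-based CT image quality with a channelised Hotelling observer

`choiq` is an R package for physicists and imaging scientists who benchmark
CT protocols by what the images let you *detect*, not just by dose. It
implements the complete analysis chain used in multicentre low-contrast
detectability (LCD) surveys of abdominal phantoms:

- a **channelised Hotelling observer (CHO)** with ten dense
  difference-of-Gaussian (DDoG) channels
  (`C_j(ρ) = exp(-½(ρ/Qσ_j)²) − exp(-½(ρ/σ_j)²)`, `σ_j = σ₀ α^{j−1}`,
  defaults `σ₀ = 0.005`, `α = 1.4`, `Q = 1.67`),
- the Hotelling template `w = K⁻¹ v_theo` built from the signal-absent
  channel covariance `K` and the channelised theoretical 5-mm FWHM Gaussian
  lesion `v_theo`, producing decision variables `λ = wᵀv`,
- a nonparametric **Mann–Whitney AUC** with a 500-replicate class-wise
  **bootstrap** (mean ± SD) as the image-quality figure of merit,
- **DICOM** reading of classic CT series plus ROI extraction at configured
  lesion/background positions (90 signal-absent / 40 signal-present design),
- a **synthetic phantom-image generator** (Gaussian lesion on white or
  radially correlated stationary Gaussian noise) that stands in for scanner
  acquisitions in all testing, and
- **study aggregation**: per-phantom-size distribution summaries (median,
  quartiles, 5th/95th percentiles, outliers), Pearson correlation matrices
  of AUC across phantom sizes stratified by ATCM type, with Evans-scale
  strength labels.

## Worked example

A full synthetic assessment at the medium-phantom pixel spacing (370 mm FOV
on a 512 matrix), with a deliberately hard 6 HU lesion:

```r
library(choiq)

cfg  <- phantom_preset("medium", lesion_amplitude_hu = 6, seed = 42)
rois <- generate_dataset(cfg)        # 90 signal-absent + 40 signal-present
run_cho_study(rois, seed = 42)
#> AUC 0.7881 (bootstrap mean 0.7893, SD 0.0428; 500 replicates, 90/40 scores)
```

The point AUC (0.79) is the probability that a random signal-present ROI
outscores a random signal-absent one; the bootstrap SD (0.043) is the
statistical uncertainty from the 90/40 design at this difficulty. At the
nominal 20 HU contrast the same pipeline saturates near AUC 1.

Study-level aggregation over a simulated 68-centre cohort whose AUC values
carry a known cross-size correlation of 0.5:

```r
rec <- simulate_study_records(n_centres = 68, latent_r = 0.5, seed = 42)
rep <- build_report(rec)
round(rep$correlations$overall, 2)
#>      S    M    L
#> S 1.00 0.58 0.62
#> M 0.58 1.00 0.56
#> L 0.62 0.56 1.00
subset(rep$evans, stratum == "overall")
#>   stratum size_a size_b         r    label
#> 1 overall      S      M 0.5758129 moderate
#> 2 overall      S      L 0.6174092   strong
#> 3 overall      M      L 0.5597247 moderate
```

With only 68 centres the sample correlations scatter around the implanted
0.5 (sampling SE ≈ 0.09); at 500 centres they recover it within ±0.08
(an acceptance criterion). `rep$auc` and `rep$dose` hold the per-size
distribution summaries that correspond to the survey's box-style figures.

## Command line

```sh
inst/cli/choiq simulate  --preset medium --amplitude-hu 20 --noise white --seed 1 --out data/
inst/cli/choiq assess    --scores scores.csv --n-boot 500 --seed 1
inst/cli/choiq aggregate --records records.csv --out report/
```

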