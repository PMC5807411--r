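# ramanECM

Quantifying the depth-dependent composition of cartilage — glycosaminoglycan
(GAG), collagen and water — from confocal Raman hyperspectral images.

Raman microspectroscopy records, at every ~10 µm tissue pixel, a spectrum
whose intensity is linear in the local constituent concentrations. The
difficulty is that the constituent signals overlap heavily (collagen
dominates, GAG is buried). `ramanECM` resolves them with multivariate curve
resolution by alternating least squares (MCR-ALS): the baseline-corrected
pixel-by-wavenumber matrix is factorized as

    D = C · S + E,      C ≥ 0, S ≥ 0

with `S` the pure component spectra (unit-norm rows) and `C` the per-pixel
abundances, fitted on the 800–1800 cm⁻¹ fingerprint range by exactly solved
non-negative least squares in each half-step. Water is mapped separately by
integrating the broad OH-stretching band (3100–3600 cm⁻¹). Downstream the
package produces laterally averaged depth profiles (normalized to peak /
surface / mean anchors, convertible to absolute % wet weight via a bulk
assay mean), localized heterogeneity scores (coefficient of variation over
250 × 250 µm regions), and a validation layer against sectioned biochemical
assays: squared Pearson correlation, RMSEP as a percent of the mean
observed value, and two-way (technique × depth) ANOVA.

A synthetic phantom generator reproduces the three canonical tissue models
— native cartilage (GAG/collagen increasing with depth, water decreasing
12.5 % between 0.1 and 2.5 mm), engineered constructs (GAG/collagen
decreasing from the media-exposed surface) and trypsin-digested explants
(GAG increasing, collagen uniform) — with full ground truth (spectra,
concentration fields, baseline, seeded noise) plus simulated sectioned
assays, so the entire pipeline is testable without any measured data.

Intended users: tissue-engineering and cartilage-biology groups running
Raman imaging, and chemometricians who want a fully testable, scriptable
MCR-ALS reference pipeline.

## Worked example

```r
library(ramanECM)

cfg <- pipeline_config("native", n_rows = 60L, n_cols = 20L,
                       wavenumber = list(lo = 600, hi = 3600, step = 8),
                       seed = 1L)
res <- run_pipeline(cfg, "native_out")

res$fit
#> <mcr_fit: 4 components, 200 iterations (not converged), explained variance 99.89%>
res$fit$S
#> <component_spectra: 4 components [collagen, water, cell, GAG], 126 channels>
res$validation$GAG
#> <validation: GAG, R2 = 0.963, RMSEP = 13.9%, technique p = 0.579>
res$validation$collagen
#> <validation: collagen, R2 = 0.901, RMSEP = 14.3%, technique p = 0.886>
res$cov
#>   tissue region constituent cov_percent n_pixels
#> 1 native   deep         GAG   14.541745       16
#> 2 native   deep    collagen    8.185111       16
```

Reading: the four-component resolution explains 99.9 % of the spectral
variance (the "not converged" flag only records that the relative residual
change had not yet fallen below 1e-6 at the 200-iteration cap). The
Raman-derived GAG depth profile agrees with the simulated sectioned assay
at R² = 0.96 with an RMSEP of 13.9 % of the mean section value, and the
technique factor is non-significant (p = 0.58): the two measurement
routes are statistically indistinguishable. The CoV rows quantify local
tissue heterogeneity in a deep-zone region of interest.

The joint multi-tissue design — all images pooled into one matrix and
resolved with a shared `S` — is run with `run_study()`;
on phantoms it is what makes the digested model's uniform-collagen
signature come out reliably:

```r
st <- run_study(list(
  native     = pipeline_config("native", seed = 1L),
  engineered = pipeline_config("engineered", seed = 101L),
  digested   = pipeline_config("digested", seed = 201L)), "study_out")
st$digested$profiles$collagen$uniform
#> [1] TRUE
```

Each run writes `profiles.csv`, `resolved_spectra.csv`, `assay.csv`,
`validation.csv`/`.json`, `cov.csv`, `config.json` and a stage log to the
output directory; runs are byte-deterministic given the config and seed.
A thin command-line wrapper with subcommands (`phantom`, `preprocess`,
`fit`, `quantify`, `validate`, `run`, `study`) ships in
`inst/cli/raman-pipeline.R`. The methods vignette
(`vignettes/raman-cartilage-unmixing.Rmd`) documents the model,
parameters, phantom design and numerical choices.

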