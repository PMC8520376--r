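# echometrics

Edge-preserving denoising for 2-D grayscale ultrasound images, plus the
derived cardiology metrics and summary-statistics layer needed to run a
left-ventricular diastolic-function analysis end-to-end on synthetic data —
no patient images or records required.

The package is aimed at researchers who work with echocardiographic image
processing pipelines and need (a) a carefully tested bilateral filter with a
brute-force reference implementation, (b) speckle phantoms and quality
metrics to evaluate it, and (c) the standard clinical derived quantities
(LVEF, Simpson biplane volume, diastolic filling rate, E/A, E/E′, QT
dispersion, P-wave terminal force) together with the SPSS-era statistical
toolkit (t-test, one-way ANOVA + LSD, chi-square, Pearson r) that clinical
papers report — including variants that operate directly on printed
mean ± SD (n) triples.

## The core algorithm

Ultrasound images carry multiplicative speckle. A plain Gaussian filter
replaces each pixel by a spatially weighted neighborhood average,

    h(m) = Σ_{ξ∈Ω} f(ξ) c(ξ, m) / K_d(m),      c(ξ, m) = exp(−‖ξ−m‖² / 2σ_d²),

with K_d(m) = Σ c(ξ, m) the unitization factor that leaves flat regions
unchanged — but it blurs edges. The bilateral filter multiplies the spatial
weight by an intensity-similarity weight,

    h(m) = Σ_{ξ∈Ω} f(ξ) c(ξ, m) s(f(ξ), f(m)) / k(m),
    s(f(ξ), f(m)) = exp(−(f(ξ) − f(m))² / 2σ_r²),
    k(m) = Σ_{ξ∈Ω} c(ξ, m) s(f(ξ), f(m)),

so averaging stops at strong edges: each output pixel is a convex
combination of its (2r+1)×(2r+1) neighborhood Ω, and as σ_r → ∞ the filter
degenerates to the Gaussian one. Two numerically equivalent implementations
ship: a per-pixel `reference` double loop and an `accelerated`
shift-and-accumulate sweep.

Downstream, the package computes LVEF = 100·(LVEDV − LVESV)/LVEDV, the
biplane Simpson method-of-discs volume V = (π/4)(L/n) Σ aᵢbᵢ, the mean
filling rate as the average slope of the volume–time curve over the
diastolic filling segment, QTd = max(QT) − min(QT) across leads, and
PTFV1 = amplitude × duration (mm·s, negative). A Gaussian-copula cohort
simulator generates three-group cohorts (control / myocardial infarction /
angina pectoris) with prescribed marginals and a target correlation
structure over (MFR, PTFV1, QTd).

## Worked example

```r
library(echometrics)

# a synthetic four-chamber phantom, speckled, then denoised
clean <- make_phantom(phantom_preset("fourchamber", 96, 96))
noisy <- add_speckle(clean, noise_spec("multiplicative_gamma", looks = 16, seed = 1))
den   <- bilateral_filter(noisy, kernel_spec(sigma_spatial = 2, sigma_range = 40))

quality_report(clean, noisy)
#>     mse  psnr edge_preservation_index
#> 1  561.  20.6                   0.555
quality_report(clean, den)
#>     mse  psnr edge_preservation_index
#> 1  245.  24.2                   0.706
```

Denoising raises PSNR by 3.6 dB while the edge-preservation index (the
correlation between the Laplacians of truth and result) improves from 0.56
to 0.71 — smoothing happened inside regions, not across boundaries.

```r
# diastolic filling rate from a sinusoidal volume-time curve
t <- seq(0, 1, length.out = 64)
vtc <- data.frame(time_s = t, volume_ml = 70 - 30 * cos(2 * pi * t))
mean_filling_rate(vtc)
#> [1] 118.4915    # analytic mean slope is 120 mL/s

lvef(120, 40)
#> [1] 66.66667

# one-way ANOVA straight from printed mean±SD (n) rows
glance(one_way_anova(data.frame(
  label = c("CG", "MIG", "APG"), n = c(20, 19, 21),
  mean = c(55.3, 55.9, 53.6), sd = c(9.8, 10.4, 8.5))))
#>   statistic    df   df2 p.value
#> 1     0.315     2    57   0.731

# copula-simulated cohort: the MFR-PTFV1 correlation is recovered
cohort <- simulate_cohort(default_cohort_spec(), n_total = 10000, seed = 1)
tidy(pearson_correlation(cohort, "mfr_ml_s", "ptfv1_mm_s"))
#>   method                             statistic    df p.value estimate
#> 1 Pearson product-moment correlation      202.  9998       0    0.896
```

The age ANOVA above illustrates the homogeneity check on a baseline
("Table 1") cohort description: p = 0.73 ≫ 0.05, so the groups are
age-compatible. The simulated cohort's empirical r = 0.896 matches the
copula target 0.895 to within sampling error.

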