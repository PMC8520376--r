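---
title: "Methods: filters, phantoms, cardiac metrics and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filters, phantoms, cardiac metrics and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echometrics)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and how they were settled.

## 1. The neighborhood filters

Both filters act on a 2-D grayscale intensity grid `f` held in an
`echo_image`. The Gaussian filter is

$$h(m) = \frac{\sum_{\xi \in \Omega} f(\xi)\, c(\xi, m)}{K_d(m)}, \qquad
  c(\xi, m) = \exp\!\left(-\frac{\|\xi - m\|^2}{2\sigma_d^2}\right),$$

with $K_d(m) = \sum_{\xi \in \Omega} c(\xi, m)$ normalizing the weights so
that a flat region passes through unchanged. The bilateral filter
multiplies in the intensity-similarity weight

$$s(f(\xi), f(m)) = \exp\!\left(-\frac{(f(\xi) - f(m))^2}{2\sigma_r^2}\right)$$

and renormalizes by $k(m) = \sum c \cdot s$. Because the center pixel
always contributes $c \cdot s = 1$, $k(m) > 0$ and the output is a convex
combination of neighborhood intensities — the source of the
range-contraction invariant the tests assert.

**Open choices and how they were settled.**

* *Kernel forms.* Gaussian kernels for both the closeness and similarity
  weights — the canonical bilateral-filter choice, and the only smooth
  family consistent with separate "spatial position" and "pixel
  similarity" bandwidths.
* *Window.* $\Omega$ is a square $(2r+1)\times(2r+1)$ window with default
  $r = \lceil 3\sigma_d \rceil$ (≥ 99.7% of the spatial Gaussian mass),
  capped at `min(height, width) − 1` so tiny images stay well defined.
* *Boundaries.* Default reflect padding (mirror without repeating the edge
  pixel); edge-replicate and zero padding are selectable. Zero padding
  darkens borders (the normalizer still counts the out-of-canvas weight),
  which is why it is not the default.
* *Arithmetic.* Intensities are processed in double precision and clipped
  to the declared range only at construction and on image export, never
  inside the normalized sums, avoiding quantization bias.
* *`reference` vs `accelerated`.* The reference implementation is a
  per-pixel neighborhood sum; the accelerated one precomputes the spatial
  kernel and sweeps the window by whole-image shifts. They are constrained
  to be numerically equivalent (tests demand per-pixel agreement below
  1e-9; the only difference is floating-point summation order). No
  approximate speed-up is offered: an "optimized" variant that changed the
  numbers would change the science.
* *Defaults.* `sigma_spatial = 2` px and `sigma_range = 0.1 × span` on the
  command line — a conventional speckle-smoothing regime; every value is a
  flag away.

## 2. Speckle phantoms

`make_phantom()` rasterizes piecewise-constant scenes (ellipses, annuli,
rectangles over a background); the `fourchamber` preset sketches an apical
four-chamber view as a bright myocardial ellipse containing four dark
chambers, `step` is a 50/200 vertical edge, `impulse` a single bright
pixel. A pixel belongs to a shape when its integer center satisfies the
shape's inequality, so the rasterization is deterministic and exactly
reproducible.

`add_speckle()` defaults to *multiplicative Gamma* noise: each pixel is
multiplied by an i.i.d. $\mathrm{Gamma}(L, L)$ variate with unit mean and
variance $1/L$ — the standard fully-developed-speckle intensity model,
with $L$ the number of looks. Additive Gaussian noise is available as a
control condition. After corruption the image is clipped to its declared
range (display saturation), not wrapped.

What the phantoms do **not** emulate: beamforming point-spread functions,
log compression, depth-dependent attenuation, or spatially correlated
speckle. Tests passing on these phantoms show the filters implement their
equations correctly and preserve synthetic edges; they do not certify
clinical image quality.

**A caveat worth stating explicitly.** At heavy speckle the bilateral
filter's advantage disappears: with $L = 4$ the noise coefficient of
variation is $1/\sqrt{L} = 0.5$, so on a 200-intensity region the noise SD
(≈ 100 gray levels) exceeds any reasonable range bandwidth, the similarity
kernel mistakes noise excursions for edges, and the Gaussian filter wins
on both PSNR and edge preservation; as $\sigma_r$ grows the bilateral
result approaches the Gaussian one from below but never beats it. The
edge-preservation superiority that motivates the bilateral filter is real
but conditional — it requires the within-region noise SD to sit below the
range bandwidth, which is the regime the quality-module property test
exercises (additive $\sigma = 15$, or Gamma $L = 64$).

## 3. Image quality metrics

`quality_report()` is full-reference: MSE, PSNR with the declared
intensity-range span as peak (format convention, not the observed
maximum), and an edge preservation index defined as the Pearson
correlation between the 3×3 discrete Laplacians (4-neighbor stencil,
reflect padding) of reference and test. The Laplacian-correlation index
was chosen over Pratt's figure of merit because it needs no edge-detection
threshold; it is 1 for perfect preservation and −1 for contrast inversion,
and undefined (flagged `NA` with a warning) when either Laplacian has zero
variance, i.e. on constant images.

## 4. Cardiac derived quantities

* **LVEF** `= 100 (LVEDV − LVESV)/LVEDV`; scale-invariant; demands
  `LVEDV > LVESV > 0`.
* **Simpson biplane volume** `V = (π/4)(L/n) Σ aᵢbᵢ` from paired disc
  diameters measured in the four- and two-chamber views. Diameters are
  taken at mid-disc stations `(i − ½)L/n` (midpoint rule), so on an
  ellipsoid the error decays as $O(1/n^2)$; at $n = 20$ discs the volume
  is within 1% of the closed form $(\pi/6)D_1D_2L$.
* **Mean filling rate.** "Slope of each point" on the volume–time curve is
  made precise as: central finite differences in the interior of the
  diastolic filling segment, one-sided differences at its two ends
  (second-order accuracy where possible), averaged arithmetically;
  multiple cycles average their per-cycle means. The filling segment runs
  from an end-systolic minimum to the next end-diastolic maximum — the
  word *filling* fixes the segment, which resolves the ambiguity of
  averaging over the whole cycle (whose mean slope is ≈ 0). Detection is
  automatic (each local minimum paired with the next local maximum, curve
  endpoints counting as extrema) and overridable via explicit
  `es_index`/`ed_index` annotations. A known discretization effect: when
  a sampled extremum falls exactly on a grid point the one-sided endpoint
  slopes (≈ 0 there) bias the mean low at coarse sampling; at 64 samples
  per cycle the sinusoidal benchmark is recovered within 2%.
* **QTd** `= max(QT) − min(QT)` across 2–12 leads; translation- and
  permutation-invariant. The 200–700 ms plausibility window is a
  validation guard that warns rather than fails — it is data hygiene, not
  physiology.
* **PTFV1** `= amplitude × duration` with the amplitude of the terminal
  (negative) P-wave phase in V1 stored as a nonpositive number in mm at
  10 mm/mV, so the product is ≤ 0 and "more abnormal" means "more
  negative"; a positive amplitude is rejected because it is not a terminal
  negative phase.

The early/late diastolic volume ratio sometimes reported alongside these
quantities is **not** implemented: its defining interval and
numerator/denominator are not specified precisely enough to compute
without guessing.

## 5. The statistical layer

All tests operate on *sufficient statistics* — per-group `(n, mean, sd)` —
so they accept either raw sample vectors or the triples printed in a
paper's baseline table, and the two input paths agree to machine precision
(asserted at 1e-9 in the tests, with base R's `t.test`/`aov`/
`chisq.test`/`cor.test` as independent oracles on the raw path).

Choices: Student (pooled) t-test by default with Welch selectable — pooled
is what classic clinical software reported; two-sided p-values throughout
with the conventional 0.05 threshold; LSD pairwise comparisons use the
ANOVA's pooled within-group mean square on `N − k` degrees of freedom and
are deliberately unadjusted (that is the LSD design, not an oversight);
the chi-square test of independence uses no continuity correction.
Degenerate inputs follow explicit conventions: identical constant groups
give `t = 0, p = 1`; zero within-variance with unequal means is flagged
and yields `p = 0`; an all-constant ANOVA is `0/0`, returned as `NaN` with
a warning. Distribution tails come from R's `pt`, `pf`, `pchisq`.

## 6. The cohort simulator

`simulate_cohort()` draws, per subject, a latent trivariate standard
normal with the target correlation matrix (Gaussian copula via the
Cholesky factor) and maps it linearly to the (MFR, PTFV1, QTd) means and
SDs; clinical variables are independent normals with per-group marginals;
sex is Bernoulli with the per-group male proportion. Linear maps of
jointly normal variables preserve Pearson correlation exactly in
expectation, which is why the empirical r at n = 10,000 lands within
±0.01 of the target (SE ≈ (1 − r²)/√n ≈ 0.002 at r = 0.9).

Design decisions:

* **Marginal shapes.** Only means, SDs and Pearson correlations are
  prescribed, so normal marginals are the minimal assumption; nothing in
  the downstream tests depends on higher moments.
* **The unreported correlation pair.** The target structure prescribes
  r(MFR, PTFV1) = 0.895 and r(MFR, QTd) = −0.912 but is silent on
  r(PTFV1, QTd). Completing the matrix by eigenvalue clipping from a zero
  entry would perturb the two prescribed coefficients; instead the default
  uses the conditional-independence completion
  r(PTFV1, QTd) = 0.895 × (−0.912) ≈ −0.816, which keeps the prescribed
  pairs exact and is always positive semi-definite. `nearest_psd()`
  (eigenvalue clipping + unit-diagonal rescale) is provided to repair
  user-supplied matrices, and an invalid target is rejected with the
  offending eigenvalue named.
* **Derived-triple marginals.** No per-group numbers are prescribed for
  MFR, QTd or PTFV1, and the reported correlations are pooled over
  subjects, so the default spec gives the triple common population
  marginals across the three groups — MFR 180 ± 45 mL/s, QTd 50 ± 15 ms,
  PTFV1 −0.030 ± 0.012 mm·s, clinically plausible scales — which makes
  the pooled empirical correlation estimate the copula target directly.
  Per-group overrides (a `label` column in `derived`) are supported; note
  that group-mean separation then shifts the pooled correlation away from
  the within-group target, which is a property of pooling, not a bug.
* **Group sizes.** The default is 20/19/21 (control / myocardial
  infarction / angina pectoris); `n_total` rescales proportionally with
  largest-remainder rounding, which is how the n = 10,000
  parameter-recovery runs are produced.

What the simulator does not model: any mechanistic link between filling
rate and ECG physiology, non-normal tails, measurement error structure, or
missing data. It exists to exercise the statistical layer end-to-end with
known ground truth.

## 7. Problem sizes and determinism

The shipped tests run the brute-force filter oracle on 16×16 and smaller
images with radii ≤ 4, quality comparisons on 96–128 px phantoms,
speckle-moment checks at 256×256, and copula recovery at n = 10,000 —
sizes chosen so the whole suite completes in well under a minute while
keeping Monte-Carlo tolerances honest (the 15% variance band on the
Gamma-moment check, for instance, is ≈ 6 SDs of the empirical variance at
65,536 pixels). Every stochastic path (noise fields, cohorts, CLI
subcommands) is reproducible bit-for-bit under a fixed seed, and both
`add_speckle()` and `simulate_cohort()` restore the caller's RNG state.

## 8. Known limitations

* Filters are 2-D only; no cine (3-D/4-D) filtering, no GPU path, and no
  approximate bilateral grids — the accelerated variant is exact.
* The four-chamber phantom is a geometric sketch, not an anatomical model.
* QT/P-wave delineation from raw waveforms is out of scope; the ECG
  metrics consume annotated intervals.
* The statistical layer covers the two-group/k-group normal-theory tests
  and Pearson correlation only — no nonparametrics, regression or
  survival methods.
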