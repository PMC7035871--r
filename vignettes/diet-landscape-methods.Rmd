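---
title: "Methods: testing diet–landscape tracking with remote sensing and stable isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing diet–landscape tracking with remote sensing and stable isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazescape)
```

## The question and the measurement chain

Large savanna herbivores such as the African elephant eat both browse
(C3 trees and shrubs) and grass (C4). Whether their diets simply track the
availability of grass around them, or reflect active selection, is hard to
answer in the field because diet and habitat must be observed at matching
spatial and temporal scales. `grazescape` implements a chain of five
measurements that makes the question testable from two remote data sources:

1. **Land cover.** A supervised classification of a dual-date multispectral
   composite maps the woody-cover gradient in four 25% intervals — closed
   deciduous woodland (CDW, 75–100% woody), open deciduous woodland (ODW,
   50–75%), discontinuous grassland (DG, 25–50%) and continuous grassland
   (CG, 0–25%) — plus anthropogenic, bare and water classes.
2. **Buffers.** Around each faecal sample site, land-cover composition is
   extracted inside concentric circular buffers of 2, 4, 8 and 12 km radius,
   bracketing a reported mean minimum daily movement of about 4 km.
3. **Grassiness.** Buffer composition is reduced to a single a-priori index:
   each gradient-class percentage is multiplied by an integer modifier
   (CDW ×1, ODW ×2, DG ×3, CG ×4) and summed, giving a value between 0 and
   400 on fully-gradient buffers.
4. **Diet.** Faecal δ¹³C is converted to %C4 intake with a two-endmember
   linear mixing model after removing a diet–faeces discrimination offset ε:
   %C4 = 100·((δ − ε) − δ_C3)/(δ_C4 − δ_C3), clamped to [0, 100].
5. **Inference.** %C4 is regressed on grassiness within a locality-blocked
   permutation framework (below), separately for dry-season, wet-season and
   combined data, at every buffer radius.

## The permutation regression framework

Faecal collections are clustered: most localities contribute several
specimens per sampling interval (month), and a naive OLS over all specimens
lets heavily collected localities dominate the fit. Each permutation
iteration therefore draws exactly **one specimen per locality × interval
unit** uniformly at random and fits the simple linear regression of %C4 on
grassiness. Over the iterations (default 10³) the framework reports:

* permuted means of r², intercept *a* and slope *b*, with 95% confidence
  limits computed as mean ± 1.96·sd/√iterations (the standard error of the
  permuted mean; percentile limits of the iteration distribution are
  available via `cl = "percentile"`);
* Monte Carlo significance p̂ = 1 − (number of iterations with model
  p < 0.05)/iterations, with α fixed at 0.05;
* one-tailed dry-vs-wet comparisons of r² and *b* (null: dry ≤ wet),
  formed by pairing iterations across the two season subsets, taking the
  empirical two-sided p of the per-iteration differences and halving it.

Two constructions here were genuinely open and are package decisions:

* *Resampling scheme.* "Randomising the data for each locality and sampling
  interval" is read as one-specimen-per-unit resampling — the only reading
  that is unbiased with respect to repeated collections at a locality and
  that makes *n* equal the number of distinct locality × interval units. A
  within-unit label-shuffle alternative is available as
  `scheme = "shuffle"` for sensitivity analysis.
* *Season-comparison p before halving.* The paired-iteration empirical
  two-sided p uses the add-one convention
  p = 2·min{(#d ≤ 0)+1, (#d ≥ 0)+1}/(iterations+1), capped at 1. Identical
  draw streams then give p = 0.5 exactly, and complete separation gives
  p = 1/(iterations+1), below the 1/iterations Monte Carlo resolution —
  a Monte Carlo p is never reported as exactly zero.

With one specimen in every unit, every iteration draws the same data and the
permutation collapses to the single OLS fit; `p̂` degenerates to an indicator
of that fit's significance. This equivalence is tested exactly.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| buffer radii | 2, 4, 8, 12 km | m | daily-range scale (≈4 km) bracketed both ways |
| buffer membership | pixel centre in radius | — | at ≥2 km radii on 30–100 m cells, partial-pixel error is negligible |
| min valid fraction | 0.5 | — | buffers truncated by the grid edge keep ≥ half their area or are excluded |
| grassiness modifiers | 1,2,3,4 | — | linear integer interpolation between the stated ×1 (closed woodland) and ×4 (continuous grassland) endpoints |
| grassiness denominator | total valid buffer area | — | water/bare dilute the index; `renormalise = TRUE` rescales over gradient classes only |
| δ_C3, δ_C4, ε | −27.0, −12.5, −0.9 | ‰ VPDB | generic savanna defaults; they are configuration, not constants, and per-season/region overrides are supported — calibrated endmembers should be supplied for real systems |
| forest size | 500 trees | — | standard random-forest default; seed recorded in the classifier object |
| iterations | 10³ | — | matches the reported analysis; Monte Carlo SE of p̂ ≈ 0.007 at p̂ = 0.05 |

Accuracy percentages are rounded half-up to 2 decimals for printing
(`round_half_up()`); all computations keep full precision.

## What the synthetic generator emulates

`generate_landscape()` thresholds a smoothed Gaussian random field at the
mixture's rank quantiles: class proportions are exact to one cell and
patch size grows with the autocorrelation length. Threshold bins are ordered
water, CDW, ODW, DG, CG, bare, so water abuts closed woodland (a loose
riparian analogy). The default mixture is the observed composition of a
southern-savanna study landscape (CG 40.7%, DG 32.6%, ODW 21.6%, CDW 4.1%,
traces of bare and water). No quantitative patchiness estimate was available
for the study area, so the default autocorrelation length (2 km) is
illustrative.

`generate_samples()` places localities uniformly on non-water cells, assigns
1–8 specimens per locality × month (uniform), and draws each specimen's true
%C4 as a_season + b_season·G + N(0, sd), clamped to [0, 100], where G is the
locality's grassiness at the 4 km reference radius. Defaults are the study
conditions: dry slope 0.10 and wet slope 0.04 %C4 per grassiness unit,
residual sd 10 %C4, intercepts −2.3 (dry) and 36.8 (wet), 100 localities ×
6 monthly intervals. Months May–October are dry, November–April wet.
δ¹³C is back-computed through the inverse mixing model, so the isotope
module recovers the generating %C4 exactly (to 1e−9) — the round trip is an
identity by construction, which tests plumbing, not chemistry.

What the generator does **not** emulate: radiometry and phenology (the
classifier fixture draws class-conditional band means, nothing more),
non-Gaussian residuals, spatial correlation of diet residuals beyond the
locality blocks, seasonal movement of localities, and observation error in
sample coordinates. Passing tests on synthetic data therefore demonstrate
that the estimators recover known generating parameters under the model's
own assumptions — not that the assumptions hold in any real landscape.

## Numerical choices and degenerate inputs

* Buffer membership is decided on pixel centres; the valid fraction uses the
  untruncated disc's cell count as denominator, so edge truncation is
  reported rather than hidden. A buffer with zero valid cells yields `NA`
  percentages and is an error downstream in the grassiness index — never a
  silent zero.
* OLS inside the permutation loop is the closed-form normal-equations fit
  (it runs ~10⁴–10⁵ times per report); it is verified against `stats::lm`
  including the slope-test p-value. Exact fits (zero residual variance)
  report p = 0 for a nonzero slope and p = 1 otherwise.
* A constant predictor (grassiness does not vary across units) and subsets
  with fewer than 3 units are errors, not NaNs.
* Every seeded operation restores the caller's RNG state; reports record
  their seed, scheme and iteration count, and re-running a pipeline config
  reproduces outputs byte-for-byte apart from the isotope round-trip's
  ~1e−15 floating-point noise when stages are skipped against re-read CSVs.
* Classes absent from a confusion matrix's rows or columns give undefined
  (NA) user's/producer's accuracies, not zeros.

## Problem sizes

Synthetic analyses in the tests and the acceptance script use 250×250-cell
landscapes at 100 m resolution (25 km × 25 km). The generating relationship
operates on the grassiness value itself, so coarser-than-Landsat cells leave
the diet model unchanged while keeping buffer extraction cheap; the buffer
oracle tests cover 30 m cells separately. Parameter-recovery checks use the
full study conditions (100 localities × 6 intervals, ~2,500 specimens,
10³ iterations); type-I checks repeat 50 sampling campaigns on one fixed
landscape — one landscape is also what any real study has.

## Known limitations

* The land-cover module assumes analysis-ready, co-registered, cloud-masked
  reflectance inputs; there is no atmospheric correction or cloud detection.
* Published class-area fractions of a real classification are not
  reproducible from this package alone — they require the original imagery
  and training polygons; only the confusion-matrix arithmetic is
  reproducible from printed counts, and the package verifies exactly that.
* The mixing-model defaults are deliberately generic. Analyses of deposited
  %C4 values should bypass the isotope module (supply `pct_c4` directly;
  the pipeline then skips the stage and records the skip).
* Buffers are isotropic and ignore movement barriers (rivers, fences).
* The permutation framework conditions on the observed localities; it does
  not model spatial autocorrelation between localities.
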