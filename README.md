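# grazescape

Do large savanna herbivores eat grass in proportion to how much grass
surrounds them? `grazescape` couples two remote measurements to answer that
question for faecal-sampled populations: a land-cover classification of the
woody-cover gradient from dual-date multispectral imagery, and faecal
stable-carbon-isotope diet estimates. It is aimed at ecologists who have
(a) a categorical land-cover map (or reflectance stacks plus labelled
reference points) and (b) a table of georeferenced faecal δ¹³C values or
pre-computed %C4 diet fractions.

## The method

1. **Classification.** A random forest is trained on a 12-band composite of
   a senescent-season and a flushed-season acquisition (bands 1–5, 7 of
   each), mapping four woody-cover classes — closed deciduous woodland
   (CDW, 75–100% woody), open deciduous woodland (ODW, 50–75%),
   discontinuous grassland (DG, 25–50%), continuous grassland (CG, 0–25%) —
   plus agriculture, built-up, coniferous plantation, bare and water.
   Accuracy assessment reports the confusion matrix with user's/producer's
   accuracies.
2. **Buffers.** Class composition is extracted in concentric circular
   buffers (default radii 2, 4, 8, 12 km) around each sample site, by
   pixel-centre membership, with truncation reported as a valid fraction.
3. **Grassiness index.** G = Σ (class % × modifier), modifiers ×1 (CDW) to
   ×4 (CG); G ∈ [0, 400] on fully-gradient buffers.
4. **Mixing model.** %C4 = 100·((δ¹³C − ε) − δ_C3)/(δ_C4 − δ_C3), clamped
   to [0, 100], with per-season/per-region endmember overrides.
5. **Permutation regression.** %C4 is regressed on G; each of 10³
   iterations draws one specimen per locality × interval unit, removing
   pseudo-replication from repeated collections. Reported: permuted means
   and 95% confidence limits of r², intercept and slope, Monte Carlo
   significance p̂ = 1 − #(model p < 0.05)/10³, and one-tailed dry-vs-wet
   comparisons (null: dry ≤ wet).

A synthetic-data generator (autocorrelated class landscapes, clustered
localities, season-dependent diet model) makes the whole chain testable
without imagery; see the methods vignette
(`vignettes/diet-landscape-methods.Rmd`).

## Worked example

```r
library(grazescape)

# accuracy arithmetic on the bundled published validation matrix
acc <- accuracy_summary(savanna_validation_matrix())
round_half_up(acc$overall)   # 90.73 (%; n = 410 validation points)

# synthetic end-to-end run at study conditions
land    <- generate_landscape(landscape_spec(seed = 1))
samples <- generate_samples(land, diet = diet_model_spec(seed = 11))
profiles <- extract_all(land, samples, radii = c(2000, 4000))
grass    <- grassiness_table(profiles)
diet     <- estimate_diet(samples)               # delta13C -> %C4
records  <- build_analysis_table(samples, grass, diet, profiles)
permutation_report(records, radii_km = c(2, 4), iterations = 1000, seed = 2)
```

which prints:

```
<perm_report> 1000 iterations, seed 2, scheme one_per_unit
 radius_km season   n r2_mean   r2_lo   r2_hi intercept_mean intercept_lo
         2   both 588 0.04854 0.04793 0.04915         23.361       23.256
         2    dry 294 0.17436 0.17252 0.17620          6.325        6.192
         2    wet 294 0.03252 0.03148 0.03356         40.591       40.436
         4   both 588 0.05677 0.05612 0.05742         15.900       15.763
         4    dry 294 0.20390 0.20184 0.20596         -4.415       -4.608
         4    wet 294 0.03922 0.03807 0.04037         36.211       35.996
 intercept_hi slope_mean slope_lo slope_hi p_hat
       23.466    0.04901  0.04869  0.04932 0.000
        6.458    0.07041  0.07000  0.07082 0.000
       40.746    0.02704  0.02658  0.02751 0.112
       16.038    0.07339  0.07296  0.07382 0.000
       -4.222    0.10550  0.10489  0.10610 0.000
       36.426    0.04141  0.04075  0.04207 0.059

Season comparisons (one-tailed, null dry <= wet):
 radius_km parameter p_one_tailed       null
         2        r2     0.000999 dry <= wet
         2         b     0.000999 dry <= wet
         4        r2     0.000999 dry <= wet
         4         b     0.000999 dry <= wet
```

Reading it: `n` counts distinct locality × interval units (294 dry + 294
wet). At the 4 km radius — the scale the diet model generates at — the
permuted mean dry-season slope is 0.1055 (generating value 0.10) and the
wet-season slope 0.0414 (generating 0.04); the dry-season models are
uniformly significant (p̂ = 0) while wet-season ones are mostly not
(p̂ = 0.059), and the one-tailed tests reject dry ≤ wet at every radius
(p ≈ 0.001, the Monte Carlo floor at 10³ iterations). At 2 km, away from
the generating scale, both slopes attenuate — the multi-scale contrast the
buffer radii are designed to expose.

Full pipelines run from a YAML config: `run_pipeline("run.yaml")` or
`grazescape run --config run.yaml` (see `?run_pipeline` for the artefact
list and `?read_run_config` for the schema).

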