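# winterniche

Thermal-niche statistics for wintering birds from upper-quantile abundance
models.

## What it does

For endotherms wintering at temperate latitudes, minimum winter temperature
is expected to cap the abundance a species can attain in a grid cell, while
habitat, food and other unmeasured factors hold most cells below that cap.
Abundance–temperature scatterplots are then *wedge-shaped*: a sharp upper
edge (the temperature-limited potential abundance) over a solid cloud.
`winterniche` estimates that edge and what follows from it.

Given a per-cell temperature table and per-species detection counts
(transects with detection out of transects surveyed, nominally 60 per
cell), the package:

1. fits quadratic **quantile regressions** of relative abundance `A` on
   standardized temperature,
   `Q_A(τ | T) = a + b·z(T) + c·z(T²)` at τ = 0.50, 0.75, 0.90, 0.95,
   by exact linear programming (interior point + vertex polish) of the
   pinball loss;
2. screens each model against the intercept-only null by the
   Koenker–Machado **pseudo-R²** `1 − V_full/V_null` and the
   asymmetric-Laplace **ΔAIC** `= 4 + 2n·ln(V_full/V_null)`, calling a
   temperature model supported when `ΔAIC ≤ −2·ln(1000) = −13.816`
   (evidence ratio ≥ 1,000);
3. derives per-species niche statistics from the τ = 0.95 fit and the raw
   survey: preferred temperature `T_PREF` (vertex of the fitted ceiling,
   clipped to the thermal span with a boundary flag), mean distribution
   temperature `T_MEAN` (abundance-weighted mean of occupied-cell
   temperatures) and thermal breadth `T_BREADTH` (area under the ceiling
   over [−2, 10] °C, normalized to (0, 1]);
4. runs the across-species meta-analysis: t tests on `b` and `c`, paired
   `|b|` vs `|c|`, the repeated-measures linear contrast of pseudo-R²
   across quantile levels, `T_PREF` vs `T_MEAN` correlation and paired
   test, per-species tests of occupied-cell temperatures against the
   regional mean with Holm (sequential Bonferroni) correction,
   specialist/generalist and cold/warm classification, and the parameter
   summary table.

A synthetic-data module simulates whole communities with known ground truth
(`detections ~ Binomial(60, U · clip(a₀ + b₀T + c₀T², 0, 1))`,
`U ~ Uniform(0,1)`), so every stage is testable without field data.

## Worked example

```r
library(winterniche)

cfg  <- community_config(n_cells = 1689, n_species = 6, seed = 42)
comm <- generate_community(cfg)                  # field + surveys + truth
out  <- run_pipeline(comm$surveys, comm$field, pipeline_config())

out$params[, c("species_id", "pseudo_r2", "delta_aic",
               "t_pref", "t_mean", "t_breadth", "class_thermal")]
```

```
  species_id pseudo_r2 delta_aic t_pref t_mean t_breadth class_thermal
1      sp001  6.05e-01  -3134.28  -2.00  0.371     0.307    specialist
2      sp002  3.47e-01  -1433.59   9.06  5.797     0.688  intermediate
3      sp003  0.00e+00      4.00   4.00  3.880     1.000    generalist
4      sp004  3.97e-01  -1705.42  -2.00  1.426     0.523  intermediate
5      sp005  3.75e-01  -1584.84   9.28  5.682     0.682  intermediate
6      sp006  7.23e-05      3.76  -2.00  3.808     0.982    generalist
```

Species 3 and 6 are the simulated temperature-independent archetypes: their
ΔAIC is near +4 (the pure parameter penalty), so the screen correctly drops
them, and their breadth is ≈ 1. The cold-preferring specialist (sp001) has
`T_PREF` pinned at the −2 °C edge of the span; the warm-preferring species
peak above 9 °C yet occupy cells averaging ~5.7 °C — `T_MEAN` sits below
`T_PREF` because suppression spreads occupancy over the whole span.

```r
print(out$report)
```

```
Across-species meta-analysis
  regional mean temperature: 3.854 C; delta-AIC cutoff -13.816
Counts:
    n_species n_significant   n_pref_cold   n_pref_warm  n_specialist  n_generalist
            6             4             2             2             1             2
Tests:
|b| vs |c|: statistic = 6.139, df = 3, p = 0.008691 (n = 4)
r(t_pref, t_mean): statistic = 8.999, df = 2, p = 0.01213 (n = 4)
linear contrast (repeated measures): statistic = 5.889, df = 1,5, p = 0.05962 (n = 6)
...
```

The same stages run from a shell over CSV files:

```sh
Rscript inst/cli/winterniche.R all --out-dir runs/demo --n-cells 1689 --n-species 12 --seed 7
# or stage by stage: simulate / fit / niche / meta
```

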