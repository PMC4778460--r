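# aerohab

Project the thermal habitat of competing fish species from their aerobic
physiology.

`aerohab` is an R package for the full chain from laboratory respirometry to
basin-scale habitat maps. It was built around a concrete question in
Mediterranean invasion ecology — how warming shifts the balance between the
native salema (*Sarpa salpa*) and the invasive marbled spinefoot
(*Siganus rivulatus*), two competing herbivores — but every stage is generic:

1. **Respirometry processing** — turn intermittent-flow oxygen traces
   (15-min closed / 15-min flush cycles, samples every 15 s) into per-fish
   maximal metabolic rate (MMR), standard metabolic rate (SMR) and aerobic
   metabolic scope (MS).
2. **Thermal performance curves** — fit species-specific models of SMR and
   MMR against temperature and summarise them as the optimal temperature
   T_opt, the maximal scope MS_max and the critical temperature T_crit.
3. **Habitat projection** — convert gridded daily temperature fields into
   thermal habitat suitability (THS) maps, binary suitability masks (QMS), a
   two-species coexistence factor (CF), and area statistics, for a
   present-day decade and a delta-method warming scenario.
4. **Synthetic data** — generate every input above (traces, acclimation
   experiments, decade-long daily temperature fields, occurrence points)
   with known ground truth, so the whole pipeline is testable end to end.

## The model

Standard metabolic rate rises exponentially with temperature T while maximal
metabolic rate follows a skewed unimodal curve that peaks at T_act and
vanishes at T_m:

```
SMR(T) = a · exp(b · T)
MMR(T) = δ · x^ω · exp(−ω x),   x = (T_m − T) / (T_m − T_act)   (T ≤ T_m)
MS(T)  = MMR(T) − SMR(T)
```

Aerobic scope MS is the budget available for swimming, digestion and growth;
its normalised form NMS(T) = max(0, MS(T)) / MS_max maps any temperature to a
[0, 1] performance index. Over a scenario of N days, each grid element i gets

```
THS_i = Σ_t max(0, MS(T_{i,t})) / (N · MS_max)
```

a decadal suitability index in [0, 1]. Thresholding THS at T_MS (the isoline
containing 95% of current occurrences; 0.62 for the packaged physiology)
gives the binary mask QMS per species, and the coexistence factor

```
CF_i = QMS_i(salema) − QMS_i(spinefoot)   ∈ {−1, 0, +1}
```

marks areas thermally favouring only the native (+1), only the invader (−1),
or both/neither (0).

## Worked example

```r
library(aerohab)

# canonical physiology shipped with the package
salema    <- species_params("salema")
spinefoot <- species_params("spinefoot")
curve_summary(salema)
#> # A tibble: 1 × 4
#>   species t_opt ms_max t_crit
#>   <chr>   <dbl>  <dbl>  <dbl>
#> 1 salema   22.1   806.   28.6
curve_summary(spinefoot)
#> # A tibble: 1 × 4
#>   species   t_opt ms_max t_crit
#>   <chr>     <dbl>  <dbl>  <dbl>
#> 1 spinefoot  29.9  1005.   38.5
```

The salema's scope peaks near 22 °C and collapses at ~28.6 °C; the spinefoot
peaks near 30 °C and tolerates almost ten degrees more — the physiological
asymmetry that drives the projections.

```r
# two-scenario projection over a synthetic decade (40 x 40 cells x 10 years)
cfg <- pipeline_config(outdir = "demo_run", seed = 1)
run_pipeline(cfg)
#> # A tibble: 2 × 5
#>   scenario cf_lt0_pct cf_eq0_pct cf_gt0_pct  t_ms
#>   <chr>         <dbl>      <dbl>      <dbl> <dbl>
#> 1 present        18.0       47.1       34.8  0.62
#> 2 future         26.4       51.4       22.2  0.62
```

Under the warming delta the area thermally exclusive to the invader
(CF < 0) grows from 18% to 26% of the basin while the native-only area
(CF > 0) shrinks from 35% to 22% — warming hands the warm southern half of
the domain to the spinefoot. `autoplot()` methods draw the performance
curves, THS maps and CF maps.

Individual stages are plain functions over tibbles and can be piped:

```r
trace_spec(true_smr = 150, true_mmr = 600, seed = 42) |>
  generate_trace() |>
  process_trace()
#> # A tibble: 1 × 7
#>   fish_id species acclim_temp_c   mmr   smr    ms mass_kg
#>   <chr>   <chr>           <dbl> <dbl> <dbl> <dbl>   <dbl>
#> 1 fish_1  salema             20  568.  143.  425.   0.005
```

## Documentation

The methods vignette (`vignettes/metabolic-scope-habitat.Rmd`) documents the
models, the numerical conventions (quantile definition, trimming windows,
clamping rules, search resolutions), what the synthetic generators emulate
and what they deliberately leave out, and the package's known limitations.
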