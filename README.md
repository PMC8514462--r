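# cropdiv

National-scale analysis of change in crop diversity from harvested-area
records.

`cropdiv` is for agroecologists and biodiversity analysts who want to ask,
country by country: *when* did the portfolio of cultivated crops start to
change, *how long* did the change last, and *how fast* was it? It ingests
long-format area-harvested tables in the FAOSTAT bulk-download dialect
(country x crop item x year, hectares), computes per-country-per-year
diversity, fits breakpoint models to the resulting time series, and carries
the analysis through to multivariate composition change, latitudinal
gradients and socio-economic (HDI) mixed models. A synthetic data generator
with known ground truth backs every stage with end-to-end recovery tests.

## The models at the core

**Diversity per country-year.** With `p_i` the share of total harvested
area in crop group `i`:

- richness `S` = number of crop groups with positive area;
- Shannon index `H' = -Σ p_i ln p_i` (nats);
- Pielou evenness `J' = H' / ln S` in [0, 1] (undefined at `S = 1`).

**Two-breakpoint segmented regression.** For each country the `S`-vs-year
(and `J'`-vs-year) series is fitted with the continuous piecewise-linear
model

```
y = a + b·year + c·(year − ψ1)·I(year > ψ1) + d·(year − ψ2)·I(year > ψ2)
```

so the slope is `b` before ψ1, `b + c` between the breakpoints, and
`b + c + d` after ψ2. Estimation is Muggeo-style iterative relinearization
(gap-term updates of ψ), safeguarded by step-halving, a best-SSE tracker and
a deterministic local polish; an exhaustive integer-grid search
(`grid_oracle()`) is shipped as an independent reference. Three change
indicators are read off each converged fit: **onset** = ψ1, **duration** =
ψ2 − ψ1, **rate** = b + c.

**Composition.** Country-by-year samples with areas as abundances are
compared by Bray–Curtis dissimilarity
`BC_jk = Σ|x_ij − x_ik| / Σ(x_ij + x_ik)`, embedded by NMDS (Kruskal
stress-1), and decomposed by a sequential permutational MANOVA
(year as a 1-df numeric covariate, then country, then their interaction),
with significance by free label permutation.

**Gradients and predictors.** Quadratic regressions of `S` on absolute
latitude give the peak-richness latitude `−β1/(2β2)`; linear mixed models
(`indicator ~ HDI`, random intercepts for continent and region nested in
continent, REML) partition indicator variance into fixed, continent, region
and unexplained shares.

## Worked example

```r
library(cropdiv)

cfg <- synthetic_config(n_countries = 30, richness_sd = 0.5, seed = 11)
sim <- generate_dataset(cfg)          # records + metadata + truth tables
div <- diversity_table(sim$records)
head(div, 3)
#>       country year  S        H         J J_defined total_area
#> 1 Country_001 1961 19 2.623857 0.8911228      TRUE   575715.3
#> 2 Country_001 1962 21 2.668289 0.8764230      TRUE   575715.3
#> 3 Country_001 1963 20 2.647467 0.8837461      TRUE   575715.3

d1 <- div[div$country == "Country_001", ]
fit_segmented(d1$year, d1$S)
#> Two-breakpoint segmented fit (S ~ year), n = 57
#>   psi1 = 1979.84, psi2 = 1994.94
#>   slopes: 0.0193 | 0.9679 | 0.0109 (b, b+c, b+c+d)
#>   r2 = 0.9947, p = 1.07e-56

fits <- fit_country_trends(div, "S")
summarize_indicators(indicator_table(fits))
#>   metric indicator      center     spread center_kind distribution  n
#> 1      S         1 1980.041657 0.40797459     mean±sd       normal 30
#> 2      S         2   14.976044 0.76861453     mean±sd       normal 30
#> 3      S         3    1.001535 0.03895029     mean±sd       normal 30
```

The generator's truth here was onset 1980, duration 15, rate 1.0 crop
groups per year: the cross-country summaries recover it to within a
fraction of a year.

The full pipeline (ingest → diversity → fits → indicators → composition →
gradients → HDI models) runs from one configuration:

```r
cfg <- pipeline_config(synthetic = synthetic_config(n_countries = 30, seed = 1),
                       n_perm = 99, seed = 1)
run_pipeline(cfg, "out/")   # stage CSVs + manifest.json
```

or from the command line (`exec/cropdiv`): `cropdiv simulate`,
`cropdiv run --config cfg.json --outdir out`, `cropdiv fit-country`,
`cropdiv permanova`, `cropdiv report`.

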