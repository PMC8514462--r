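---
title: "Methods: quantifying national crop-diversity change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying national crop-diversity change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropdiv)
```

## Scope and data model

`cropdiv` treats a national agricultural census as a community-ecology
dataset: each country-year is a "community" whose "species" are FAO crop
commodity groups and whose abundances are harvested areas in hectares. The
atomic record is `(country, year, crop_group, area_ha)`. Ingest applies a
fixed label-harmonization (merging the cotton fractions into `Seedcotton`
with areas summed, renaming `Palmkernels` to `Oilpalmfruit`, and removing
five labels that are not single plant crops) and an optional whitelist
filter that excludes dissolved states. Zero-area rows are treated as
absences rather than zero-abundance presences: counting them as presences
would inflate richness with administrative placeholders.

## Diversity metrics

Richness `S` counts crop groups with positive area. Shannon diversity uses
the natural logarithm throughout, on area proportions formed within the
country-year (never across years). Pielou evenness `J' = H'/ln S` is
undefined at `S = 1`; such country-years carry an explicit `J_defined`
flag and are excluded from evenness modelling. This exclusion is a package
decision — the alternative (imputing `J' = 1` or 0) would manufacture
trend signal out of monoculture years.

## The segmented trend model

Each country's diversity series is fitted with a continuous two-breakpoint
piecewise-linear model. The number of breakpoints is fixed at two by
design: the scientific object is a single "period of change" with an onset
(ψ1), an end (ψ2), and a within-period rate (`b + c`). No model selection
over breakpoint counts is attempted.

Estimation follows the iterative relinearization idea: at the current
(ψ1, ψ2) the design is augmented with gap indicators `−I(year > ψk)`, and
each breakpoint is moved by the ratio of its gap coefficient to its
slope-difference coefficient. Numerical choices:

- tolerance `1e-6` on the breakpoint update norm, at most 100 iterations;
- step-halving (down to 1/64) keeps proposals ordered and inside the data
  range; failure to do so is reported as non-convergence, not clamped;
- the plain iteration can cycle between near-optimal breakpoint pairs, so
  the best-SSE pair seen is tracked and accepted once the SSE stalls for
  three iterations;
- a deterministic Nelder–Mead polish on (ψ1, ψ2) then minimizes the exact
  piecewise SSE locally. There are no random restarts — determinism is
  preferred, and the exhaustive integer-grid oracle (`grid_oracle()`, with
  earliest-pair tie-breaking) is the safeguard used by the test suite to
  confirm that the iterative path reaches the global basin;
- minimum segment support is 2 observations; exactly linear data makes the
  gap coefficients degenerate and is reported as "no identifiable
  breakpoint" rather than returning an arbitrary ψ;
- default initials are 1975 and 2000, sensible for 1961–2017 national
  series; per-country overrides are configuration data
  (`fit_country_trends(..., overrides = )`), mirroring the practice of
  hand-tuning starting values for countries with shortened records;
- the model p-value is the overall F of the fit against intercept-only
  with 5 model degrees of freedom, counting both breakpoints as estimated
  parameters.

Non-converged countries are never dropped silently: they appear as
explicit rows with `converged = FALSE` and a reason string.

## Indicators and their summaries

Onset, duration and rate are pure functions of a converged fit: ψ1,
ψ2 − ψ1 and `b + c`. Cross-country summaries are distribution-aware: a
normal and a log-normal candidate are fitted by maximum likelihood and
compared by AIC, reporting mean ± s.d. under the normal and
median ± m.a.d. under the log-normal. Two conventions deserve note:

- the log-normal is selected only when it beats the normal by more than 2
  AIC units. For tightly clustered onset years (coefficient of variation
  below 1%) the two candidates are practically indistinguishable and a
  strict lower-AIC rule flips by sampling noise; the ΔAIC ≥ 2 rule is the
  standard "substantial support" threshold and resolves ties toward the
  conventional mean ± s.d. summary;
- the m.a.d. is the raw median absolute deviation, without the 1.4826
  consistency factor;
- indicators that can be negative (rates) are shifted by a configured
  offset (default +10) before log candidacy, and the applied transform is
  recorded verbatim (e.g. `log(x+10)`).

## Composition analysis

Bray–Curtis dissimilarities are computed exactly as the Manhattan distance
scaled by summed abundances; columns absent from a sub-sample stay as
zeros. NMDS minimizes Kruskal stress-1; optimization is delegated to
`vegan::monoMDS` (monotone regression plus coordinate updates) started
from the classical metric-MDS configuration plus seeded random starts
(default 4 starts total), the best stress winning. An independent stress-1
implementation based on pooled-adjacent-violators (`stress1()`) lets the
tests verify the optimizer without trusting it.

The permutational MANOVA is implemented from first principles
(Gower-centered inner-product matrix; term SS as increases in explained
trace along the cumulative design). Two conventions are deliberate:

- **sequential (Type-I) SS in entry order year → country → interaction**,
  the default of the Adonis-style tools this mirrors; the order is
  configurable but fixed by default;
- **year is a numeric single-df covariate**, country a factor, so the df
  pattern matches the national-scale analysis this reproduces.

Significance uses free permutation of sample labels with the count
estimator `(b + 1)/(n_perm + 1)` (99 permutations by default, so p is a
multiple of 0.01), and an epsilon tie guard so permutations equivalent to
the observed labelling are counted as exceedances rather than lost to
floating-point drift. `vegan::adonis2` serves as an independent oracle in
the tests; the two agree to machine precision on the SS decomposition.
The shrinking-dispersion pattern over time is exposed numerically as a
per-year mean distance-to-centroid table (`year_dispersion()`), not as
ordination graphics.

## Latitudinal gradients and HDI models

The latitude model is OLS of `S` on |lat| and |lat|² in the raw
(non-orthogonal) basis, so coefficients are directly interpretable, with
the peak at `−β1/(2β2)` defined only for concave fits. Latitude is
consumed as supplied metadata (absolute centroid degrees); its provenance
is the caller's responsibility.

The six HDI models (three indicators × two metrics) are linear mixed
models with fixed `intercept + HDI` and nested random intercepts
(continent, region within continent), fitted by REML with `lme4`. Variance
partitioning uses the marginal-R²-style convention: the fixed share is the
variance of the fixed-effect predictions; continent and region shares are
their REML variance components; the total is the sum of all four, so the
proportions always sum to 1. An alternative convention (partitioning only
the random side) exists in the literature; the one implemented is stated
here and used consistently. Boundary (zero) variance components are valid
results and flagged `singular`. Countries missing HDI are dropped from
these models only.

## The synthetic world

The generator is first-class, tested code, and its defaults are a stated
world, not tuning knobs:

- 57 years (1961–2017), baseline richness `S0 = 20`, breakpoints 1980 and
  1995, segment slopes (0, 1, 0) crop groups/year — a flat–rise–flat
  trajectory whose onset/duration/rate truth is (1980, 15, 1.0);
- richness is realized by actually introducing and retiring crops from a
  per-country preference ordering over a 120-crop pool, so presence counts
  — not just latent means — follow the piecewise mean (rounded, floored at
  1), with Gaussian noise on the latent scale;
- harvested areas follow a geometric rank-abundance series with decay
  parameter θ ∈ (0, 1]; θ = 1 gives perfectly even areas (J′ = 1) and the
  θ → J′ link is monotone with a closed form (`geometric_evenness()`),
  giving controllable monotone or flat evenness trajectories;
- country totals are log-normal around 10⁶ ha and constant over years;
  proportions, and hence diversity, are scale-invariant to this choice;
- latitude is uniform on [0°, 70°]; when a gradient is configured,
  baseline richness follows `β0 + β1·L + β2·L²` (default recovery target
  β = (20, 1.5, −0.02), peak 37.5°);
- the nested socio-economic structure (default 4 continents × 3 regions)
  can shift each country's onset by continent, region and residual
  Gaussian effects and an HDI slope; all default to zero (shared truth);
- every draw flows from the single mandatory config seed.

What the generator does **not** emulate: real FAO crop frequencies, trade
structure, reporting gaps, correlated noise, or countries appearing and
disappearing. A green end-to-end test therefore establishes that the
estimators recover a world obeying the model's assumptions — it does not
validate the models against real-world violations of those assumptions.

## Known limitations

- Breakpoint uncertainty is not quantified (no confidence intervals on ψ).
- The integer-grid oracle is exact only over integer breakpoint pairs; the
  iterative fitter can legitimately do slightly better off-grid.
- PERMANOVA stores the full distance matrix in memory; at the full
  national scale (~10⁴ samples) that is ~1 GB and the pipeline exposes a
  year-step thinning control (`composition_year_step`) instead of a
  streaming implementation.
- The distribution dichotomy is normal-vs-log-normal only, by design.
- Reproducing published full-scale results requires the external FAO
  download and HDI tables; the package's acceptance surface is the
  synthetic desk-scale world.
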