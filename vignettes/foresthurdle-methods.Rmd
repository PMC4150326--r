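---
title: "Methods: hurdle mixed models of land-use impacts on tropical forest species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hurdle mixed models of land-use impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Compilations of site-level species abundance records from many independent
field studies are the main evidence base for quantifying how land use
affects biodiversity. Such data are awkward in three ways: most records are
zeros (a species sampled in a study is absent from most of its sites);
measurement units and effort differ across studies; and records are
clustered — by study, by site within study, and by species.

`foresthurdle` implements a two-stage ("hurdle") mixed-model analysis of
such data against four anthropogenic pressures — land-use class, forest
cover, human population density (HPD) and vegetation offtake (iNDVI) —
together with a ground-truthed synthetic data generator, so that every
stage of the analysis can be exercised and validated without access to any
proprietary compilation.

**Occurrence stage.** Presence/absence of taxon *t* at site *s* of study
*j* is modelled by a binomial-logit GLMM,

    logit P(y > 0) = Xβ + u_study(j) + u_site(s|j) + u_taxon(t),

with independent random intercepts for study, site nested in study, and
taxon, fitted by Laplace-approximated maximum likelihood (`lme4::glmer`).
A taxon is present where its record value is positive; it is inferred
absent at the other sites of any study that recorded it somewhere (absence
is never inferred across studies). Taxa never recorded positive within a
study drop out of that study's occurrence table.

**Abundance stage.** Conditional on presence, the natural log of the
effort-corrected record value is modelled by a Gaussian LMM with the same
random-intercept structure, by ML rather than REML so that
likelihood-ratio tests and AIC are comparable across fixed-effect
structures. Count-family GLMMs are not offered: effort correction and the
mixture of measure types make the values non-integer.

**Fixed effects.** The candidate set is land use (six classes: primary
forest, secondary vegetation, wood plantation, cropland, pasture, urban),
taxonomic group (invertebrates, herptiles, mammals, birds), their
interaction, the three continuous pressures, pairwise interactions among
continuous pressures, their interactions with group, and the three-way
(continuous pair × group) terms — `full_term_set()`. Continuous pressures
enter linearly on the link scale after centring and scaling to unit SD
(HPD as log(x+1); both are package choices — standardization conditions
the optimizer and makes coefficients comparable; curvature is left to
interactions, with a cubic side-model available where one group's response
is genuinely non-monotone, `fit_cubic_submodel()`).

**Backward selection.** `backward_select()` tests only currently
*droppable* terms — those contained in no retained higher-order term — by
likelihood-ratio tests, drops the least significant term with p ≥ α
(ties broken towards the smaller χ²/df), and repeats until all droppable
terms are significant. Main effects are therefore tested only after every
interaction containing them has been removed, and the trace has the shape
of a term-test table with "n.a." (NA) entries for terms that were never
exposed to a test.

**Model fit.** `r2_glmm()` reports the marginal and conditional R² for
mixed models: σ²_fixed over the total of fixed, random, residual and
distribution-specific variance (π²/3 for the binomial logit).

# The synthetic data generator

The generator (`generator_config()`, `generate_dataset()`) emulates the
structure the analysis assumes, with every true parameter stored:

* ~20 studies of 20–40 spatially clustered sites each (~600 sites), each
  study sampling a single taxonomic group — so absences are inferable
  exactly as the preprocessing assumes — with group frequencies
  (0.577, 0.080, 0.056, 0.287) and land-use frequencies
  (348, 94, 319, 7, 20, 7)/795 taken from the kind of compilation the
  analysis targets.
* Occurrence intercept calibrated at generation time (1-D root solve on
  the realized linear predictors) so the overall non-zero fraction is
  0.26 exactly in expectation.
* Random-intercept SDs default to study > taxon > site (occurrence: 1.2,
  0.8, 0.4; abundance: 0.8, 0.5, 0.3; residual 0.8), the ordering such
  compilations show.
* Taxon intercepts are drawn on the taxonomy tree (class/order/family/
  genus/species, Grafen branch lengths) under a Pagel-λ covariance with
  λ = 0.1, so residual phylogenetic-signal diagnostics have a known
  target.
* Each site carries a 3-year, 16-day MODIS-like NDVI series: baseline
  0.75, seasonal dip amplitude 0.05 scaled by a land-use-dependent
  offtake multiplier, Gaussian noise (SD 0.02), flagged cloud
  contamination (10% of composites), and rare *unflagged* cloud spikes
  (0.5% of composites, depth 0.35). The true iNDVI is integrated from the
  latent clean series by the same integrator the pressure module uses, so
  recovery error isolates contamination handling. Amplitude ≪ spike depth
  reflects moist-forest NDVI: seasonality is modest, cloud artefacts are
  deep.
* Pressure–land-use coupling is configurable (`pressure_means`); setting
  the means equal across classes decouples a pressure from land use,
  which is how the "only land use × group active" selection scenarios are
  constructed.
* Effort is uniform per site on a configurable range; only the
  effort-sensitive measure types (abundance, group abundance) are
  recorded as abundance × effort. All randomness descends from one root
  seed through fixed per-stage offsets.

What the generator does **not** emulate: detection error (presence is
taken at face value), species interactions, biogeographic realism, or
habitat-patch effects. Passing tests therefore validate the estimator and
pipeline logic, not the ecological fidelity of any particular published
effect size.

# The iNDVI pressure

`compute_indvi()` integrates, by the trapezoid rule on the composite grid
with true calendar day gaps, the excess of NDVI over its minimum within
the 3-calendar-year window ending 31 December of the study's final
sampling year (floored at 2002, the first year with complete composite
coverage). Units are NDVI·days. The integral is exact for the piecewise
linear interpolant, which is why the grid is not resampled daily.
Quality-flagged composites are dropped and re-interpolated linearly;
leading/trailing gaps are extended from the nearest retained value rather
than inventing a trend.

Because the integral is measured **from the window minimum**, a single
missed low outlier shifts the whole integral by roughly its depth times
the window length — the characteristic failure mode of unflagged cloud
contamination. `screen_influential()` flags composite *i* when
median − vᵢ > k·MAD (scaled MAD, default k = 5) **and** both neighbours
lie within 1 MAD of the median, so sustained ecological depressions are
never flagged. Screened composites are treated as flagged and
re-interpolated by default; `drop_site = TRUE` discards the site instead,
the more conservative response. The quiet-neighbour condition makes the
screen deliberately specific rather than sensitive (roughly half of
injected spikes survive under noise); the tests assert only that
screening never increases iNDVI and always moves it towards the latent
truth on average.

# Preprocessing decisions

* Effort correction rescales effort-sensitive values to the study's
  maximal effort (`corrected = value/(effort/max effort)`); any study-level
  rescaling constant is absorbed by the study random intercept on the log
  scale, so the reference choice is cosmetic but standardized.
* Area of occupancy sums spherical areas of distinct half-degree cells
  (R = 6371 km), cells aligned to integer/half-integer boundaries and
  half-open so boundary points belong to the north-east cell. The
  range-size split is strict at the group median ("exceeds" → wide; ties
  → narrow).
* Specialists: birds are forest specialists iff forest habitat is of
  "major" importance; mammals iff habitat breadth is 1; other groups are
  "unknown" and stay unsplit in trait-refined models.

# Diagnostics

* `build_tree()` constructs the taxonomy tree from ranked paths (one node
  per distinct rank/name pair, conflicting parentage is an error,
  singleton chains collapsed); `grafen_lengths()` sets node heights to
  (descendant leaves − 1)/(total leaves − 1), giving an ultrametric tree
  of depth 1.
* `pagel_lambda()` profiles the Gaussian likelihood analytically (GLS
  mean, ML scale) and maximizes over λ ∈ [0, 1] with a bounded search
  (tol 1e-6); a 1e-10 ridge handles λ → 1 singularities from effectively
  duplicated tips. The reference model is λ = 0 (all taxa equally
  related), and the LRT p-value uses the χ²₁ upper tail, which is
  conservative at the boundary; a 50:50 mixture option exists but is off
  by default. Residuals feeding λ are deviance residuals (occurrence) or
  response residuals (abundance) averaged per taxon — the record-level
  weighting is a package choice.
* `morans_i()` uses inverse great-circle-distance weights, row
  standardized, with a 1 m floor for coincident sites (k-nearest weights
  available); the variance is the standard randomization formula, which
  requires n ≥ 4 (n = 3 yields the statistic with p = NA). The meta-test
  is a one-sided exact binomial test of the number of studies significant
  at α against Binomial(n, α). Because the exact binomial p is discrete
  and conservative, calibration checks use its standard uniformized
  version.
* `refit_excluding()` refits the minimum adequate model without the
  flagged studies and tabulates coefficients side by side; lost factor
  levels become NA contrasts, not errors.

# Community-abundance index

`community_index()` multiplies the relative probability of occurrence and
the relative abundance of persisting species:
value = invlogit(b₀ + Δocc)/invlogit(b₀) × exp(Δab), with b₀ the
occurrence model's fixed intercept (random effects at zero, covariates at
reference). It is exactly 1 in primary forest. The back-transformation
convention (fixed intercept, reference covariates) is a package choice;
the index is deliberately crude and carries no SE.

# Problem sizes used by the tests

The validation suite runs entirely on generated data, at sizes chosen to
make each property measurable with reasonable Monte-Carlo precision:

* CI coverage of land-use × group contrasts: 25 generator-default
  replicates (~600 sites each), coverage pooled over the 20 non-baseline
  contrasts; recovery fits use the generator's true site pressures, since
  contaminated-iNDVI attenuation is a property of the pressure module
  (tested there), not of the estimator.
* Variance-component recovery: 12 replicates of a 50 × 20 × 20
  crossed-design LMM with σ = (1, 0.5, 0.5, 1).
* Selection consistency: 100 replicates of a 42-study scenario with a
  strong land-use × group interaction (offsets ±0.8/±0.5), zero
  continuous slopes and pressure means decoupled from land use, on the
  abundance stage; null-term discard is asserted per term — with several
  null terms at α = 0.05, the probability of discarding *all* of them is
  bounded near (1 − α)^k and is not a calibration property of the
  selector. LRT type-I: 1000 small-LMM replicates.
* Pagel's λ: 500-tip recovery (100 Brownian and 100 independent
  replicates), 1001-point grid cross-checks on 50-tip trees.
* Determinism: the full pipeline twice at a reduced configuration
  (8 studies, 8–14 sites, 5–8 taxa); determinism does not depend on size.

# Known limitations

* The GLMM uses the Laplace approximation; adaptive quadrature is not
  available for crossed random effects. Boundary variance estimates are
  reported as zeros, not errors.
* ML likelihood-ratio tests for group-level terms are mildly
  anticonservative when the number of studies is small; the selection
  tests run at 42 studies where the effect is negligible.
* Wald CIs ignore variance-component uncertainty; coverage is validated
  empirically rather than assumed.
* The spike screen favours specificity over sensitivity by design; deep
  contamination adjacent to flagged composites can survive and inflate
  iNDVI. The `drop_site` option is the recourse when a site's series is
  suspect.
* No detection modelling, no spatial random fields, no phylogenetic
  covariance inside the GLMM (λ is a residual diagnostic only).
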