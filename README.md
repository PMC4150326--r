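# foresthurdle

Hurdle mixed models of how land use and other human pressures shape the
occurrence and abundance of individual species in tropical and
sub-tropical forests — built as a fully synthetic, ground-truthed
analysis workflow.

## The problem

Site-level abundance compilations pool records from many independent
field studies: most records are zeros, measurement units and sampling
effort differ between studies, and records are clustered by study, site
and species. The package implements the standard two-stage ("hurdle")
treatment of such data against four pressures — land-use class, forest
cover, human population density (HPD) and vegetation offtake (iNDVI) —
for four taxonomic groups (invertebrates, herptiles, mammals, birds):

* **Occurrence**: binomial-logit GLMM,
  `logit P(present) = Xβ + u_study + u_site(study) + u_taxon`,
  fitted by Laplace ML; absence is inferred only within studies that
  recorded the taxon somewhere.
* **Abundance given presence**: Gaussian LMM on natural-log
  effort-corrected values, same random intercepts, ML (not REML) so
  LRTs and AIC are comparable across fixed structures.
* **iNDVI**: the trapezoidal integral of an NDVI composite series above
  its minimum over the 3 years up to the study's final sampling year
  (NDVI·days), after quality filtering, linear gap interpolation and
  screening of isolated unflagged cloud spikes.
* Backward stepwise selection with marginality-respecting LRTs over the
  candidate set `land_use × group + continuous pressures + their pairwise,
  ×group and three-way interactions`; marginal/conditional R² for mixed
  models; Pagel's λ of per-taxon residuals on a Grafen-calibrated
  taxonomy tree; per-study Moran's I with an exact binomial meta-test;
  relative land-use effects and the occurrence × abundance
  community-abundance index.

Because no real compilation ships with the package, a first-class
synthetic generator (`generator_config()`, `generate_dataset()`)
produces multi-study datasets with known true parameters — including a
calibrated ~26% non-zero record fraction, study > taxon > site random
variation, λ-structured taxon effects and MODIS-like contaminated NDVI
series — so every stage is testable against ground truth.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `06_summaries.R`, writing under `results/`). Run it
with `Rscript analysis/01_simulate.R` and so on, or drive everything at
once:

```r
library(foresthurdle)
res <- run_pipeline(generator_config(seed = 1))
```

On the default configuration (20 studies, 584 sites, 7 001 records,
25.2% non-zero) the workflow prints:

```
occurrence: kept {land_use, group, hpd, forest_cover, forest_cover:group} after 38 fits
  marginal R2 0.183, conditional R2 0.408
abundance: kept {land_use, group, land_use:group, forest_cover} after 38 fits
  marginal R2 0.059, conditional R2 0.563
occurrence: lambda = 0.105 (LRT p = 0.019); 2/20 studies autocorrelated (10.0%), meta-p 0.26
abundance: lambda = 0.000 (LRT p = 1); 2/20 studies autocorrelated (10.0%), meta-p 0.26
refit without 2 flagged studies: 12/12 coefficients within 2 SE
community index ranges from 3.0% (invertebrates in pasture) to 62.8% (herptiles in secondary vegetation) of primary forest
occurrence variance ordering: study > taxon > site
abundance variance ordering: study > taxon > site
```

Reading this: the selector keeps land use and the pressures that were
truly active; the pressures explain a modest fraction of variance once
study and taxon differences are absorbed (marginal vs conditional R²);
the residual phylogenetic signal recovers the λ = 0.1 the generator
planted in the occurrence taxon effects; few studies show residual
spatial autocorrelation, and dropping them leaves every coefficient
within 2 SE; and the community-abundance index — relative probability of
occurrence × relative abundance of persisting species — falls below 1
in every human-modified land use.

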