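# dispersalshare

Inferring bacterial dispersal potential in the human living environment
from **shared amplicon sequence variants (ASVs)** between paired human and
doormat microbiome samples.

## The problem

Direct measurement of microbial dispersal at household-to-landscape scales
is effectively impossible, so dispersal must be inferred from patterns.
One such pattern: an indoor entrance mat accumulates soil, dust and the
bacteria carried in from outdoors (plus bacteria shed by the residents).
If dispersal between a person and their living environment is high, the
person's microbiota and the mat's microbiota should share more taxa. For a
human sample (saliva, skin swab or feces) paired with the same subject's
doormat sample at the same season, the dispersal-potential statistic is

```
proportion shared = k / n
```

where `n` is the number of ASVs observed in the human sample and `k` is
the number of those ASVs also present on the paired mat. The denominator
is always the *human* richness, because total richness drives the raw
shared count. The proportion is then modeled as a binomial response
(`k` successes out of `n` trials, logit link) in a generalized linear
mixed model with season (timepoint) as a fixed effect, a per-subject
random intercept, and household/lifestyle covariates (percent built
environment around the home, outdoor recreation, gardening, pets,
handwashing, number of persons, days the mat was in use) entering through
a two-phase forward selection: the first variable must have the lowest
p value below 0.05 (after screening each candidate for a timepoint
interaction by likelihood-ratio test), later variables enter one at a
time only if they lower AIC by at least 3.

The package implements the whole path from raw ASV count tables to those
models:

- **I/O** for plain-TSV and mothur-`shared` count tables, taxonomy with
  bootstrap-suffix stripping, and sample/subject metadata
  (`read_count_table()`, `read_taxonomy()`, `read_metadata()`).
- **Filtering** in a fixed order — lineage blacklist (chloroplast,
  mitochondria, unknown, Archaea, Eukaryota), whole-dataset singleton
  removal, strict removal of every ASV seen in any negative control,
  replicate merging — followed by **rarefaction** (a single exact
  multivariate-hypergeometric draw per sample, per-type automatic depth)
  (`filter_pipeline()` and the individual steps).
- **Shared-taxa statistics**: pairing, per-pair `(k, n)` records, Venn
  partitions across sample types (`shared_table()`, `venn_by_type()`).
- **Community structure** from first principles: Bray-Curtis, Sørensen
  (= Bray-Curtis on presence/absence) and Hellinger distances, classical
  PCoA, one-way PERMANOVA with free label permutation, pairwise contrasts
  with BH/Bonferroni adjustment, and PERMDISP on distances to group
  spatial medians with the negative-eigenvalue correction
  (`distance_matrix()`, `pcoa()`, `permanova()`, `permdisp()`).
- **Dispersal models**: binomial random-intercept GLMMs (lme4 Laplace fit
  with bobyqa retry), the forward-selection protocol with its phase-wise
  missing-data rules, per-timepoint reruns, and simulation-based scaled
  quantile residual diagnostics (`fit_glmm()`, `forward_select()`,
  `per_timepoint_models()`, `simulate_residuals()`).
- A **synthetic-study generator** with known ground truth — regional
  urban/rural taxon pools, subject-specific core microbiota,
  covariate-driven dispersal acting on community composition, mats mixing
  environmental and human-shed reads, contamination shared with negative
  controls (`simulation_config()`, `generate_study()`).
- **Orchestration**: `run_pipeline()` and a CLI at
  `inst/cli/dispersalshare.R` produce rarefied tables, shared-taxa and
  data-characteristics tables, dispersion-test tables, model coefficient
  tables and a JSON manifest with every seed.

## Worked example

```r
library(dispersalshare)

cfg <- simulation_config(n_subjects = 20, seed = 42,
                         n_env_taxa = 250,
                         n_core_taxa = c(saliva = 70, skin = 110, feces = 70),
                         library_size_human = c(700, 1200),
                         library_size_mat = c(1500, 2500),
                         n_mat_replicates = 2, n_negative_controls = 6)
study <- generate_study(cfg)
filt  <- filter_pipeline(study$table, study$taxonomy,
                         study$metadata$samples, seed = 1)
shared <- shared_table(filt$table, filt$records)
shared_summaries(shared)[, c("human_type", "timepoint", "n_pairs", "pct_shared")]
#>  human_type timepoint n_pairs      pct_shared
#>       feces         S      20 11.8 (1.8-29.6)
#>       feces         A      20 12.9 (3.3-24.3)
#>       feces         W      20 19.3 (5.5-37.5)
#>      saliva         S      20 11.3 (1.8-19.4)
#>      saliva         A      20 12.0 (2.0-27.3)
#>      saliva         W      20 19.1 (5.9-39.4)
#>        skin         S      20  9.4 (1.3-19.8)
#>        skin         A      20  8.6 (1.1-20.4)
```

`pct_shared` is the mean (min–max) percent of each human sample's ASVs
also found on the paired mat — the response the models explain. Winter
(`W`) is highest because the generator's default seasonal offset raises
the dispersal logit by +1.07 in winter; skin has no winter sampling by
design. Fitting the models:

```r
dat <- prepare_model_data(shared, study$metadata$subjects, "saliva")
sel <- forward_select(dat, c("built", "outdoor", "gardening", "pets",
                             "handwashing", "number_of_persons",
                             "real_mat_days"))
sel$selected
#> [1] "built"     "outdoor"   "gardening"
sel$model$coefficients[, c("term", "estimate", "se", "p")]
#>                       term estimate      se        p
#>                (Intercept)  -1.7621 0.21695 4.58e-16
#>                 timepointA   0.0126 0.13662 9.27e-01
#>                 timepointW   0.6122 0.12078 4.00e-07
#>                      built   0.0130 0.00163 1.71e-15
#>                    outdoor  -0.6204 0.17294 3.34e-04
#>  gardeningat_least_monthly  -0.4085 0.11466 3.67e-04
```

`built` is recovered with a positive sign and `outdoor` with a negative
sign — the generator's true nonzero coefficients (+0.02 per percent
built, −1.2 per outdoor unit on the dispersal logit; the estimates are
attenuated because observed sharing is a noisy, thresholded readout of
the latent dispersal probability). `gardening` is a false inclusion of
the AIC gate on this particular draw — a useful reminder that forward
selection controls neither its phase-2 error rate nor selective
inference. The timepoint-W contrast (+0.61) reflects the winter offset.

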