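# traitstab

Tools for asking whether a repeatedly surveyed multitrophic community is
more stable through a **functional-trait** lens than through a **species**
lens.

Surveys of the same sites over years (here: coastal pond fish sampled by
seine at fixed stations, monthly, across years) can be summarized either
as a species-abundance matrix or, after imputing traits to every surveyed
individual, as a community-weighted-mean (CWM) trait matrix. When trait
values overlap among species (functional redundancy) and species within a
trophic group fluctuate compensatorily, species composition can turn over
while trait composition barely moves. `traitstab` implements the full
comparison and a synthetic-data generator with exactly those knobs.

## What's inside

| Stage | Functions |
|---|---|
| Synthetic surveys | `synth_config()`, `generate_species_pool()`, `simulate_survey()`, `simulate_trait_measurements()`, `make_fixture()` |
| Trait imputation | `fit_trait_model()` / `fit_trait_models()` (`trait ~ taxon + s(length)`, thin-plate spline, REML via mgcv), `impute_survey_traits()` |
| Community matrices | `build_abundance_matrix()` (stations-then-months averaging), `build_trait_matrix()` (CWM), `aggregate_by_feeding_mode()` |
| Multivariate core | `bray_curtis()`, `pcoa()`, `nmds()` — from-scratch, oracle-tested against vegan |
| Stability | `year_to_centroid()` (betadisper-style PCoA dispersion or raw-to-mean), `year_to_year()`, `relative_stability()`, `stability_anova()` |
| Inference | `permanova()` (pond + numeric year + interaction), `simper_year_to_centroid()`, `simper_year_to_year()`, `envfit()` |
| Dimensionality control | `mock_config()`, `resample_mock_pair()`, `run_mock_experiment()` |
| Orchestration | `pipeline_config()`, `run_full_pipeline()`, CLI at `inst/scripts/traitstab-cli.R` |

The stability statistic: per pond, the distance of each yearly community
from the pond centroid (year-to-centroid) or between consecutive years
(year-to-year), in Bray–Curtis space; distances are max-normalized within
composition type and compared with a crossed two-way ANOVA
(`relative_distance ~ pond * composition_type`). Smaller distance =
greater stability.

## Worked example

Six ponds, six years, 27 species in four feeding modes, high redundancy
(0.9) and high within-mode compensation (0.9):

```r
library(traitstab)

cfg <- synth_config(n_ponds = 6, n_years = 6, n_months = 3, n_stations = 2,
                    n_species = 27, redundancy = 0.9, compensation = 0.9,
                    seed = 42)
sv     <- simulate_survey(cfg)
tm     <- simulate_trait_measurements(cfg, n_per_species = 20, noise_sd = 0.05)
models <- fit_trait_models(tm)
pred   <- impute_survey_traits(models, sv, species_lookup(cfg$species_pool))

A  <- build_abundance_matrix(sv)   # 36 pond-years x 27 species
T_ <- build_trait_matrix(pred)     # 36 pond-years x 13 CWM traits

stab <- rbind(
  relative_stability(year_to_centroid(bray_curtis(A)),  "species"),
  relative_stability(year_to_centroid(bray_curtis(T_)), "trait"))
tapply(stab$relative_distance, stab$composition_type, mean)
#>   species     trait
#> 0.7406835 0.4294661

stability_anova(stab)
#>                    term df     sumsq     meansq          F            p
#> 1                  pond  5 0.3207384 0.06414769  1.8458613 1.175338e-01
#> 2      composition_type  1 1.7434126 1.74341262 50.1670158 1.806516e-09
#> 3 pond:composition_type  5 0.1606961 0.03213921  0.9248117 4.713465e-01
#> 4             Residuals 60 2.0851301 0.03475217         NA           NA
```

Trait composition is markedly more stable than species composition (mean
relative distance 0.43 vs 0.74; composition-type F on 1 and 60 df ≈ 50),
with no pond-by-type interaction — the redundancy/compensation mechanism
working as designed. PERMANOVA on the trait matrix shows the companion
spatial pattern: traits differ among ponds but are conserved through time:

```r
permanova(bray_curtis(T_), n_perm = 999, seed = 42)
#>        term df           SS          F     p
#> 1      pond  5 0.0020693334 10.0339879 0.001
#> 2      year  1 0.0000246973  0.5987736 0.511
#> 3 pond:year  5 0.0001403822  0.6806990 0.678
#> 4 Residuals 24 0.0009899155         NA    NA
#> 5     Total 35 0.0032243284         NA    NA
```

Whether that trait-vs-species gap is an artifact of 27 species versus 13
traits is checked with equal-dimension mock communities:

```r
mock <- run_mock_experiment(A, T_, mock_config(n_dims = 13, n_reps = 100, seed = 1))
mock$summary$frac_trait_more_stable   # fraction of replicates with gap <= 0
```

## Command line

```sh
Rscript inst/scripts/traitstab-cli.R simulate --preset paper_shape --seed 1 --dir fixture
Rscript inst/scripts/traitstab-cli.R all --survey fixture/survey.csv \
    --traits fixture/traits.csv --lookup fixture/lookup.csv --out results
```

Subcommands: `simulate`, `impute`, `matrices`, `stability`, `permanova`,
`simper`, `envfit`, `mocksim`, `all`. Every run writes a `manifest.json`
that fully determines the outputs.

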