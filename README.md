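# squamataxa

Return-on-investment (ROI) prioritization of taxonomic research for
conservation.

Most undescribed ("candidate") species are invisible to conservation
assessment: a Red List can only protect what taxonomy has named. When expert
panels assess a diverse group — the motivating case is the Australian
squamate reptiles, more than 1,000 species of lizards and snakes — they can
state, species by species, how likely a taxonomic revision is, what research
is still needed to complete it, and how much conservation benefit a
completed revision would unlock. `squamataxa` turns such structured
expert-elicitation tables into a reproducible prioritization pipeline for
conservation scientists, taxonomists and museum/agency analysts:

1. **Ingest & validate** assessment tables (CSV): one row per species (or
   per species × assessor), a four-level taxonomic-revision confidence
   (`none` / `probably_not` / `highly_probable` / `definite`), a mutually
   exclusive predicted outcome (`increase` / `decrease` /
   `species_complex`), four binary outstanding-research flags and four
   binary conservation-benefit flags. Blank conservation cells are scored
   conservatively as 0; blank confidence is an error.
2. **Resolve multi-assessor conflicts** deterministically via the
   three-category rule (morphology-vs-genetics and already-described
   conflicts → no revision; isolated populations lacking genetic data →
   highly probable revision).
3. **Score ROI** per species and rank the cohort:

   `ROI = (c1 + c2 + c3 + c4) × tax / (r1 + r2 + r3 + r4)`

   where `c1..c4` are the conservation benefits (description enables
   assessment; highly localized, i.e. extent of occurrence < 20,000 km²;
   species-level threatening process; high probability of a VU/EN/CR
   listing), `r1..r4` the outstanding research steps (fieldwork, genetics,
   morphology, analysis & manuscript) and `tax ∈ {0, 0.2, 0.8, 1.0}` the
   revision-confidence weight. Species with `ROI ≥ 1` are priorities.
4. **Map** species richness and per-cell weighted-mean scores (and their
   square-root transform) by overlaying range polygons on a 25 km
   equal-area grid (1 km subgrids for islands), without any heavyweight GIS
   dependency.
5. **Summarize**: censuses of taxonomic uncertainty, family-level tables
   with high-revision/low-coverage flags, research-needs profiles
   (including the description backlog), and conservation summaries.
6. **Simulate**: a seeded generator emulates both the assessment tables and
   heavy-tailed range polygons, so the entire pipeline is testable offline;
   `synthetic_supplement()` is a deterministic synthetic benchmark table
   whose aggregate composition mirrors the published Australian squamate
   assessment.

## Worked example

```r
library(squamataxa)

supp <- synthetic_supplement()                     # synthetic benchmark table
res  <- resolve_conflicts(supp$raw, supp$conflict_labels)
census(res$resolved, supp$n_total_species)
#> Assessed 870 of 1034 species (84.1%)
#> Needing revision (highly probable/definite): 282 (32.4% of assessed)
#>   increase 216 | decrease 11 | species complex 43
#> Unrecognized diversity: 24.8% of assessed (29.8% incl. complexes)

cohort <- filter_revision_cohort(res$resolved)     # 216 increase species
conservation_summary(cohort)
#> Increase cohort: 216 species
#> Highly localized (< 20,000 km2 EOO): 52 (24.1%)
#> Conservation concern [any_threat]: 38 (17.6%)

summary(score_cohort(cohort))
#> 216 species scored; 24 priority (ROI >= 1)
#> ROI quantiles:
#>   0%  25%  50%  75% 100%
#> 0.20 0.25 0.25 0.40 3.00
```

The counts read directly: of 870 assessed species, 282 probably or
definitely need revision; the 216 whose revision would add species form the
ROI cohort; 52 of them harbour highly localized candidates, 38 are of
conservation concern, and 24 clear the `ROI ≥ 1` priority bar.

The gridding reproduces the textbook weighted-mean cell: six co-occurring
species with ROI scores (1, 1, 1, 1, 3, 4) give a cell mean of
11/6 ≈ 1.83:

```r
fx <- make_worked_example_fixture()
m  <- mean_score_map(fx$scores, fx$ranges, fx$grid)
as.matrix(m)[2, 2]
#> [1] 1.833333
```

## Package tour

| Area | Functions |
|---|---|
| I/O & validation | `read_assessments`, `write_assessments`, `validate_assessments`, `assessment_schema` |
| Conflicts & cohorts | `resolve_conflicts`, `filter_revision_cohort`, `conflict_categories` |
| ROI | `tax_weights`, `roi_score`, `score_cohort`, `roi_prioritize`, `priority_count` |
| Spatial | `build_grid`, `range_map`, `read_ranges`/`write_ranges`, `albers_project`, `cells_occupied`, `richness_map`, `mean_score_map`, `sum_score_map`, `sqrt_transform`, `island_subgrid_analysis`, `write_raster_csv`/`write_raster_asc` |
| Summaries | `census`, `family_summary`, `research_profile`, `conservation_summary` |
| Synthetic data | `synthetic_config`, `generate_assessments`, `generate_ranges`, `make_worked_example_fixture`, `synthetic_supplement` |

See the methods vignette (`vignettes/roi-prioritization.Rmd`) for the model,
its assumptions, parameter choices and limitations.
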