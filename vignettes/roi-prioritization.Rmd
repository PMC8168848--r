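---
title: "Prioritizing taxonomic research for conservation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing taxonomic research for conservation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squamataxa)
```

## The problem

Species that have not been formally described cannot be listed, assessed or
managed. In diverse groups — Australian lizards and snakes being the
motivating case — expert panels can nevertheless say, per currently
recognized species, whether a taxonomic revision is likely to reveal
additional ("candidate") species, what research remains before those
species can be described, and how much conservation benefit a completed
description would unlock. `squamataxa` operationalizes that structured
elicitation as a scoring and mapping pipeline.

## The elicitation model

Each species carries:

* **Confidence** that revision is needed, on an ordered four-level scale
  (`none`, `probably_not`, `highly_probable`, `definite`), weighted
  `tax = 0, 0.2, 0.8, 1.0`. Analyses deliberately use only the top two
  levels, a conservative guard against overinflating the estimate of
  taxonomic uncertainty.
* **Outcome**: whether revision would `increase` diversity, `decrease` it
  (synonymy), or the group is a `species_complex` too tangled to call. The
  coding is binary per species — a species containing five candidate
  species still counts as one — which again biases the census downward.
* **Research steps** still outstanding (`r1` fieldwork/sampling, `r2`
  genetics/genomics, `r3` morphology/phenotype, `r4` analysis & manuscript),
  each 0/1. A species needing revision with all four complete is a
  contradiction and is rejected.
* **Conservation benefits** (`c1` description enables assessment, `c2`
  highly localized — extent of occurrence below the 20,000 km² threshold at
  which the IUCN range criterion admits a Vulnerable listing, `c3` exposure
  to a species-level threatening process, `c4` high probability of a
  VU/EN/CR listing), each 0/1. Where experts could not judge conservation
  concern the cells default to 0 — "no concern" is the conservative reading
  of silence — whereas a blank confidence is a data error: silence about
  the core question cannot be defaulted.

### Multi-assessor conflicts

Independent research groups sometimes return discordant assessments.
Observed disagreements fall into three categories, resolved
deterministically: (1) morphology suggests a candidate but unpublished
genetics shows within-species variation, and (3) the candidate is already
described — both coded as *no revision needed*; (2) morphology suggests an
isolated short-range endemic with no genetic data available — coded as
*highly probable*, retaining the asserting assessor's outcome and flags.
For concordant duplicates, and for the asserting records in category 2,
binary flags merge by field-wise maximum: if any assessor flags a research
need or a benefit, it stays flagged. For categories 1 and 3 we zero all
flags: a species resolved as not needing revision has no outstanding
revision research by definition. Resolution is deterministic and
idempotent, which the test suite asserts directly.

## The ROI statistic

$$\mathrm{ROI} = \frac{(c_1 + c_2 + c_3 + c_4)\,\times\, tax}{r_1 + r_2 + r_3 + r_4}$$

Benefits over costs, discounted by the confidence that the work is needed
at all. The statistic is bounded: `0 ≤ ROI ≤ 4`, with 4 attained only at
full benefit, `tax = 1` and a single outstanding step. It is monotone
non-decreasing in every benefit flag and in `tax`, non-increasing in every
cost flag, and scale-equivariant in the weight table — all verified
exhaustively (every one of the 2⁴ × 2⁴ flag combinations × 3 weights)
against an independently coded brute-force formula.

Choices worth making explicit:

* **Zero cost is an error, not `ROI = ∞`.** At minimum, analysis and
  manuscript preparation are always outstanding for an undescribed species;
  a zero cost row is a coding mistake.
* **Priority rule `ROI ≥ 1`** (inclusive), configurable via `threshold`
  and `strict`. An inclusive and an exclusive reading of the bar are both
  defensible; we default to inclusive and expose the switch.
* **Cohort**: confidence in the top two levels *and* outcome `increase`
  (the default); a permissive mode admits any species with `tax > 0`. Only
  increase species have a defined conservation payoff, so complexes and
  synonymies are censused but not scored.
* **Ties** in the ranking break lexicographically by species id, so runs
  are reproducible; equal scores have no substantive order.
* `c1` is 1 by construction for every increase species — describing the
  candidate is precisely what enables its conservation assessment — and
  remains overridable in the data.

## Spatial aggregation

Range polygons are overlaid on a square equal-area grid (default 25 km
cells; 1 km subgrids for island groups such as Lord Howe and Norfolk, where
a continental cell swallows the whole archipelago). Per cell the package
computes species **richness**, the **sum** of scores, the **weighted
mean** (score sum / species count — the richness-adjusted score; six
species scoring 1, 1, 1, 1, 3, 4 give 11/6 ≈ 1.83) and its **square-root
transform**, which damps the handful of extreme cells that otherwise
dominate a mean-ROI map. Cells with no species are nodata in the mean
layers, never 0: zero is a meaningful score.

Numerical/design choices:

* **CRS**: default EPSG:3577 (Australian Albers, GRS80, meters), an
  equal-area projection, with a hand-coded forward Snyder ellipsoidal
  transform for lon/lat input. Any metric equal-area CRS is accepted;
  geographic (degree) CRSs are rejected for gridding. The projection's
  equal-area property is verified in the tests against independently
  computed ellipsoidal areas (`geosphere`), agreeing to ~2×10⁻⁵ relative.
* **Occupancy rule**: a cell is occupied iff the polygon intersects its
  interior with positive area (computed by Sutherland–Hodgman rectangle
  clipping + shoelace area, tolerance 1 m² per 625 km² cell scale), so a
  range merely touching a cell edge does not occupy it. A `centroid` rule
  is available since the overlay convention is a genuine free choice.
* **Grid alignment**: origins snap down to integer multiples of the cell
  size from the CRS origin, so grids built from different extents align
  cell-for-cell. Cells are half-open, so a shared edge belongs to exactly
  one cell.
* **Geometry layer**: the package implements the few planar primitives the
  overlay needs (areas, rectangle clipping, centroids) directly in R and
  keeps them small and testable; the test suite cross-checks richness and
  mean layers cell-for-cell against an independent triple-loop oracle
  (species × cell × intersection) computed with `shapely`, and against an
  exact interval-arithmetic oracle for rectangular ranges.

## Summaries

`census()` counts assessed species, the revision cohort (top two confidence
levels regardless of outcome) and the outcome split; note the cohort may
exceed the sum of the three outcomes when assessors assert revision without
predicting a direction. `family_summary()` flags families with ≥ 30 % of
assessed species in the increase cohort and families with < 75 % coverage.
`research_profile()` tabulates the 16 step combinations by higher group and
the **backlog** — species with fieldwork and genetics complete (`r1 = r2 =
0`) but work remaining — and the **data-ready** pattern `(0,0,0,1)`.
`conservation_summary()` counts highly localized species and species of
concern, where *concern* defaults to `c3 = 1 OR c4 = 1` ("any threat
signal"); a stricter `c4`-only rule is available because the boundary of
"conservatively identified concern" is itself a judgement. Percentages are
stored exact and rendered half-up to one decimal; half-up is chosen over
banker's rounding to match how such tables are conventionally reported.

## Synthetic data

The generator emulates the statistical structure the pipeline assumes —
it is the package's test bed, not a model of squamate biogeography.

* `generate_assessments()` draws per-species confidence, outcome, research
  and conservation flags from configurable marginal rates; the defaults are
  calibrated to the Australian squamate study conditions (assessment rate
  870/1034; revision rate 282/870; outcome split (216, 11, 43, 12)/282;
  research-step probabilities (0.48, 0.48, 0.60, 0.95), implying a
  backlog rate of (1−0.48)²(1−0.4·0.05) ≈ 26.5 %; localized rate 52/216;
  threat rates 0.12 and 0.0635, giving P(concern) = 17.6 %). A guard forces
  `r4 = 1` when all four research draws are 0, so every generated
  revision-needed species is scoreable. Conflicted species are emitted as
  discordant assessor-A/B row pairs with category labels (21:5:1 mix), built
  so that resolution recovers the originally drawn record. All randomness
  derives from one root seed through named substreams, so adding a
  component never perturbs the others' draws, and identical seed + config
  give byte-identical CSV/GeoJSON output.
* `generate_ranges()` draws lognormal range areas (defaults meanlog 10,
  sdlog 1.5 in km² — median ≈ 22,000 km² with a heavy right tail and
  substantial mass below the 20,000 km² localization threshold; the real
  area distribution is not published, so these were fixed once as a
  plausible heavy-tailed shape) and places convex 48-gon "blobs" uniformly
  in the extent, clipped to it. Species flagged highly localized are forced
  below the threshold by truncated resampling. Blobs are deliberately
  unrealistic as range *shapes*; they are sufficient to exercise the
  overlay logic, which is what the tests need.
* `synthetic_supplement()` is different in kind: a fully deterministic
  synthetic benchmark table (1,034 species, 13 families, 27 injected
  conflicts) whose aggregate composition — 870 assessed, 282 revision, 216
  increase, 52 localized, 38 concern, 24 priority, 57/216 backlog, 49
  snake increase with 9 data-ready, four families at ≥ 30 % — realizes the
  published headline structure of the Australian squamate assessment. The
  acceptance tests run the *entire pipeline* on its raw form and check that
  every aggregate is recovered by computation; this validates the pipeline
  arithmetic end-to-end. It does not validate the expert data itself, which
  is not redistributable with the package.

### What passing tests do and do not show

The generator reproduces marginal rates and conflict structure, not
assessor correlation, phylogenetic clustering of revision need, spatial
autocorrelation of richness, or realistic range shapes. Tests passing on
synthetic data therefore demonstrate correctness of the coding rules,
filters, arithmetic and overlay — not that the method's conservative
defaults are well calibrated for any particular real fauna.

## Problem sizes and determinism

The shipped tests run the parameter-recovery check at n = 5,000 species
(exact binomial 99 % intervals), the spatial oracle on a 16 × 20 cell grid
with 50 ranges, and the exhaustive ROI check over all 768 flag/weight
combinations; the acceptance script regenerates a 5,000-species dataset and
grids 120 scored ranges at 25 km. These sizes give stable statistics while
keeping a full run in tens of seconds. All stochastic steps are seeded;
reruns are bit-identical.

## Known limitations

* One resolved record per species: assessor reliability is not modelled,
  and elicitation weighting beyond the published three-category rule is out
  of scope.
* Costs are categorical counts; no monetary costing of research steps.
* No taxonomic name reconciliation against external registries; species
  identity is exact string match after whitespace/case normalization.
* The spatial layer assumes already-clipped, valid polygons in (or
  projectable to) an equal-area CRS; there is no coastline clipping and no
  invalid-geometry repair — zero-area geometries are rejected outright.
* Published per-cell map values of the original study are not reproducible
  in principle (its projection, grid origin and polygon set are not
  published at cell level); spatial correctness is therefore established
  oracle-wise, not against the published maps.
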