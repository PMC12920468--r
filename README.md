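# mifcontext

Compartment-resolved analysis of multiplex immunofluorescence (mIF) cell
detections in solid tumors, modelled on colorectal cancer (CRC).

Cell-level mIF panels resolve where immune populations sit relative to the
tumor–stroma interface, and that geography carries the signal: PD-L1⁺
myeloid cells, B cells, Tregs and NK cells concentrate in the **invasive
margin (IM)** — the 1 mm band spanning the interface — rather than the
**tumor center (TC)**. `mifcontext` implements the quantitative machinery
for this kind of study as a tested, seeded R pipeline:

- **Compartment delineation** — builds the IM as the flat-capped band of
  total perpendicular width *w* (default 1 mm) around the interface
  polyline, and the TC as the tumor region beyond it; assigns each cell by
  its distance to the interface (a cell at exactly *w*/2 is IM).
- **Density quantification** — up to 5 representative 1 mm² analysis
  fields per compartment (greedy maximal region overlap, seeded
  tie-breaks); densities are pooled counts over pooled analysed area, in
  cells/mm².
- **Spatial proximity** — CD8⁺↔PD-L1⁺ pairing within a closed 20 µm
  radius via grid-bucketed neighbour search; the scored statistic is the
  *engaged-cell density* (CD8⁺ cells with ≥ 1 PD-L1⁺ neighbour, per mm²).
- **Composite scores** — cohort-relative median dichotomization of each
  (metric, region) column:

  | scheme | components | total | high |
  |---|---|---|---|
  | Immunoscore | CD3⁺, CD8⁺ density × {TC, IM} | 0–4 | 3–4 |
  | CD8/PD-L1 composite | CD8⁺ density, PD-L1⁺ density, proximity × {IM, TC} | 0–6 | 5–6 |

- **Statistics** — Wilcoxon matched-pairs signed-rank (exact,
  tie-tolerant null distribution for n ≤ 25), Mann–Whitney U, Pearson
  correlation/linear regression, and the association-panel table
  (high-vs-low p, correlation with CD8⁺, correlation with PD-L1⁺, starred
  at ns / * p ≤ 0.05 / ** p < 0.01 / *** p < 0.001), optionally stratified
  by region and MSI status.
- **Synthetic cohorts** — marked-point-pattern simulator (Poisson and
  Thomas cluster processes, cross-phenotype co-clustering, lognormal
  between-sample heterogeneity, planted high/low infiltration groups,
  latent-factor-controlled density correlations) so every stage is
  testable against known ground truth.

## Worked example

Simulate a small cohort with planted high/low CD8/PD-L1 groups, run the
compartment pipeline, and score it:

```r
library(mifcontext)

spec <- cohort_spec(
  n_samples = 8, groups = default_groups(8),
  intensities = dplyr::bind_rows(
    phenotype_intensity("CD8+",   "P2", 250, 450),   # lambda_tc, lambda_im (cells/mm2)
    phenotype_intensity("PD-L1+", "P2",  80, 220),
    phenotype_intensity("CD3+",   "P3", 400, 700)
  ),
  interface = interface_spec(4, "sinusoidal", amplitude_mm = 0.3,
                             tissue_extent_mm = c(4, 3)),
  seed = 42
)
cohort <- simulate_cohort(spec)
#> <mif_cohort> 8 samples, 105595 cells, 2 panels; seed 42

cells  <- gate_phenotypes(cohort$cells)
fields <- purrr::map_dfr(names(cohort$geometries), function(sid) {
  g <- cohort$geometries[[sid]]
  dplyr::bind_rows(select_fields(g, "IM", seed = 1),
                   select_fields(g, "TC", seed = 1)) |>
    dplyr::mutate(sample_id = sid, .before = 1)
})
cells <- purrr::map_dfr(names(cohort$geometries), function(sid) {
  assign_regions(cells[cells$sample_id == sid, ], cohort$geometries[[sid]])
})

dens <- compute_densities(cells, fields)
prox <- proximity_table(cells, fields, "CD8+", "PD-L1+", radius_um = 20)
scores <- cd8_pdl1_score(cd8_pdl1_matrix(dens, prox))
scores
#> <mif_scores> scheme: cd8_pdl1  n = 8  high: 3
#> # A tibble: 8 × 5
#>   sample_id scheme   bits      total category
#>   <chr>     <chr>    <list>    <int> <fct>
#> 1 S01       cd8_pdl1 <int [6]>     6 high
#> 2 S02       cd8_pdl1 <int [6]>     6 high
#> 3 S03       cd8_pdl1 <int [6]>     6 high
#> 4 S04       cd8_pdl1 <int [6]>     2 low
#> 5 S05       cd8_pdl1 <int [6]>     0 low
#> 6 S06       cd8_pdl1 <int [6]>     0 low
#> 7 S07       cd8_pdl1 <int [6]>     1 low
#> 8 S08       cd8_pdl1 <int [6]>     3 low
```

The three samples simulated with 3× CD8/PD-L1 intensities score 6/6 and are
called `high`; the five baseline samples score 0–3 and are called `low`.
Each sample's `bits` vector records which of the six dichotomized
components (CD8-IM, PD-L1-IM, proximity-IM, CD8-TC, PD-L1-TC, proximity-TC)
exceeded the cohort median; `tidy(scores)` unpacks them and
`attr(scores, "cutoffs")` audits the cutoffs used.

A paired IM-vs-TC comparison of PD-L1⁺ density (the classic
margin-enrichment test) on the same cohort:

```r
paired_region_compare(dens, "PD-L1+")
#> # A tibble: 1 × 10
#>   test                 statistic p_value     n estimate ...
#> 1 wilcoxon_signed_rank        34  0.0234     8     120.
```

p = 0.023 with a median IM−TC difference of +120 cells/mm² — the simulated
IM enrichment (220 vs 80 cells/mm²) is detected at n = 8.

The whole flow — simulate (or read CSV/GeoJSON inputs), gate, delineate,
quantify, score, test, write outputs plus a checksummed JSON manifest — is
also packaged as `run_pipeline(pipeline_config(...))`, with a command-line
wrapper in `inst/scripts/run_pipeline.R`. Plot helpers:
`autoplot(geometry)`, `plot_cells()`, `plot_paired_density()`,
`autoplot(scores)`, `plot_association_panel()`.

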