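---
title: "Methods: compartment-resolved immune contexture from mIF cell tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-resolved immune contexture from mIF cell tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifcontext)
```

## The measurement model

The package analyses per-cell detection tables from multiplex
immunofluorescence (mIF) of tumor sections: one row per segmented cell
with centroid coordinates in micrometres (image convention, y downward)
and 0/1 positivity flags for a 14-marker vocabulary split over three
staining panels (P1: CK, CD20, CD11c, CD15, CD3, CD163; P2: CK, PD-1,
CD8, PD-L1, Ki67, GrzB; P3: CK, CD3, CD4, Foxp3, CD56, CD8). Positivity
thresholds are upstream image-analysis decisions and are taken as given;
the package starts where a QuPath-style export ends.

Phenotypes are derived from the flags by explicit gating rules
(`default_gating_rules()`): each cell receives every label whose required
markers it satisfies on its own panel, so a CD8⁺PD-1⁺ cell is
simultaneously `CD8+`, `PD-1+` and `CD8+PD-1+`. Gating is deterministic,
order-independent and idempotent, which the tests verify by property.
NK cells are gated permissively as CD56⁺, matching how such populations
are usually reported; a stricter CD56⁺CD3⁻ gate is available
(`strict_nk = TRUE`) for users who want T cells excluded. PD-L1⁺ cells
can additionally be split into epithelial (`PD-L1+CK+`) and
stromal/immune (`PD-L1+CK-`) compartments, the distinction that matters
in CRC where PD-L1 is predominantly myeloid-derived.

## Compartment geometry

The tumor–stroma interface is an input polyline; the supported geometry
model is an x-monotone interface spanning the tissue, which is what the
synthetic generator produces and what the GeoJSON dialect stores. Two
derived regions drive everything downstream:

- the **invasive margin (IM)**: the band of total perpendicular width
  `im_width_um` (default 1000 µm) spanning the interface. We read the
  "1 mm-wide zone spanning the interface" literally as 1 mm *total* —
  0.5 mm on each side — rather than 1 mm per side; the width parameter is
  free, so the per-side reading is `im_width_um = 2000`.
- the **tumor center (TC)**: the tumor polygon beyond the band.

The band polygon is built by mitred normal offsetting of the polyline at
±w/2 with flat (butt) end caps: the margin does not extend beyond the
delineated interface, and for a straight interface the band is exactly a
rectangle of area length × width, which the tests assert to machine
precision. For curved interfaces the offset construction gives area equal
to arc length × width whenever the curvature radius exceeds w/2; the
sinusoidal test geometries keep the minimum curvature radius above
1.2 mm, and a fine-grid membership oracle confirms the polygon area to
within 1%.

Cell assignment is predicate-based rather than polygon-based: a cell is
IM iff its perpendicular distance to the interface is ≤ w/2 (closed band
— a cell at exactly w/2 is IM; IM takes precedence over TC), TC iff it
is otherwise inside the tumor polygon, else outside. This makes the
boundary rule exact and independent of polygon discretisation; agreement
with an independent winding-number/dense-resampling oracle is part of
the acceptance suite. Analysis fields are 1 mm² squares ("1000 mm"
field sizes in print are a unit typo no slide could hold; 1 mm² is the
physically possible reading). "Representative" manual field choice is
not reproducible, so it is formalised as greedy maximal region-overlap
on a half-field candidate grid with seeded tie-breaking — deterministic
given the seed. Densities are pooled counts over pooled field∩region
area (cells/mm²), so `density × area` always returns the integer count;
per-field averaging was the alternative reading, and pooling was chosen
because it weighs fields by the area actually analysed.

## Proximity

Proximity between phenotypes A and B (default CD8⁺ and PD-L1⁺ on panel
P2) counts pairs within a closed Euclidean ball of `radius_um`
(default 20 µm — "within 20 µm" read inclusively; the boundary case is
unit-tested). The search is grid-bucketed (radius-sized bins, 3×3
neighbourhood scan), equal by test to the O(n²) distance-matrix oracle
on every instance up to 2000 cells. The scored statistic is the
**engaged-cell density**: A cells with ≥ 1 B neighbour per mm² of
analysed area. The source literature does not pin down the statistic
beyond the pairing rule; per-cell engagement was chosen as the default
because it is bounded by the A-cell density, interpretable per cell and
robust to local B multiplicity, with the raw pair count per mm²
(`pair_density`) available behind the same records. B cells are taken
from the analysis fields dilated by the radius, so a neighbour just
outside a field edge still counts; no further edge correction is applied
— the bias is bounded by the perimeter-to-area ratio of a 1 mm² field at
20 µm (≈ 8%) and affects all samples alike, so cohort-relative
dichotomization is insensitive to it.

## Scores

Both composite scores dichotomize each (metric, region) column at the
cohort 50th percentile, computed with the linear-interpolation
order-statistic convention (the k-th order statistic at probability
(k−1)/(n−1)). A component bit is 1 iff the sample's value is *strictly*
greater than the cutoff: ties at the cutoff score 0, which guarantees at
most half the cohort is "above the median" per column and makes the rule
deterministic; no tie rule is stated in the source conventions, so the
conservative one was chosen. Cutoffs are computed per (metric, region)
column over the scored cohort (samples with both regions present) and
are attached to the result for audit.

- **Immunoscore**: CD3⁺ and CD8⁺ densities in TC and IM → total 0–4,
  low 0–2, high 3–4. CD3 is read from the T-cell panel P3 and CD8 from
  the cytotoxic panel P2 by default (both are arguments).
- **CD8/PD-L1 composite**: CD8⁺ density, PD-L1⁺ density and engaged
  proximity density in *both* IM and TC → total 0–6, low 0–4, high 5–6.
  The TC-only three-component variant of the original tumor-center
  classifier is available via `tc_only = TRUE` (total 0–3, high = 3).

Exhaustive enumeration of all dichotomized component patterns (2⁴ and
2⁶) verifies the attainable totals and the category boundaries; the
score is monotone in every metric and invariant to common rescaling of
the cohort, both checked by property tests.

## Statistics

The battery mirrors standard immune-contexture reporting: paired IM-vs-TC
Wilcoxon matched-pairs signed-rank tests per phenotype; Mann–Whitney U
for high-vs-low group comparisons; Pearson correlation with the
regression slope and its 95% CI. For the signed-rank test with n ≤ 25
non-zero differences the two-sided p comes from the exact null
distribution built by convolution over midranks (valid under ties —
`wilcox.test` declines exact computation there); above that, the
tie-corrected normal approximation. Mann–Whitney uses the exact
distribution for untied samples up to n₁+n₂ = 20 and the tie-corrected
approximation otherwise. Both are checked against brute-force
enumeration oracles (2ⁿ sign patterns; all C(n₁+n₂, n₁) assignments) and
calibrated under null simulation: with 15 pairs and 8-vs-8 groups the
attainable exact sizes are 0.048 and 0.050, so empirical rejection at
α = 0.05 over 1000 replicates falls in [0.03, 0.07] — those simulation
sizes were chosen analytically, from the exact null distributions, to sit
near the nominal level. All-zero paired differences return p = 1 with a
degeneracy flag. Significance stars follow the reporting convention
ns / * (p ≤ 0.05) / ** (p < 0.01) / *** (p < 0.001), and no
multiple-testing correction is applied by default, matching the
descriptive, exploratory use of such panels (`p.adjust` can be applied
to any returned column). The association panel tests each immune subset's
whole-tissue density (pooled counts over pooled IM+TC areas) against the
high/low grouping and against CD8⁺ and PD-L1⁺ densities; region- and
MSI-stratified panels filter to the stratum first and suppress strata
with fewer than 3 samples. Pearson is the default correlation per the
stated analysis plan; `method = "spearman"` reproduces the
rank-correlation variant some tables report.

## The synthetic cohort generator

Real patient tables are not redistributable, so the generator emulates
the study conditions as marked spatial point patterns with known ground
truth:

- **Counts**: per phenotype and region, homogeneous Poisson with mean
  λ·area (λ in cells/mm², separate λ_TC and λ_IM), or a Thomas cluster
  process (Poisson parents, Gaussian-dispersed Poisson offspring) for
  clustered populations. Co-clustering — e.g. PD-L1⁺ cells seeded at
  CD163⁺ macrophage cluster parents — re-uses another phenotype's
  parents, which is coherent across staining panels because serial
  sections share tissue geography.
- **Heterogeneity**: per-sample intensities are mean-preserving lognormal
  draws around group means (σ = 0.35 on the log scale) — the simplest
  positive-valued spread that makes cohort medians non-degenerate.
- **Planted groups**: a default 15-sample cohort with 6 high-infiltration
  samples (5 MSI-H, 1 MSS) and 9 low (3 MSI-H, 6 MSS); the high group
  receives 3× CD8⁺/PD-L1⁺ intensities (and milder enrichments of the
  populations that co-travel with them).
- **Correlation targets**: a shared standard-normal latent factor
  z_a = √r·z₀ + √(1−r)·ε induces Pearson correlation r between two
  phenotypes' log intensities in a chosen region, giving closed-form
  control of the target.
- **Seeding**: one integer seed determines the whole cohort
  bit-for-bit, including each sample's interface phase.

Default intensities (e.g. CD3⁺ 400/700, CD8⁺ 250/450, PD-L1⁺ 80/220,
CD163⁺ 150/400 cells/mm² in TC/IM, epithelium 2500/1200) are free
parameters chosen once as plausible magnitudes for colorectal sections
— no published per-phenotype densities exist for them to estimate — with
the IM-enriched pattern for PD-L1⁺/CD163⁺ and effector populations built
in. What the generator deliberately does *not* model: segmentation error,
marker spillover (flags beyond a phenotype's defining markers are
negative, so gating tests have unambiguous truth), staining-intensity
variation, holes/necrosis in tissue, or anisotropic margins. Passing
tests therefore demonstrate the correctness and calibration of the
measurement machinery, not robustness to those real-data artefacts.

## Numerical choices and degenerate inputs

- Geometry uses exact polygon arithmetic (shoelace areas,
  Sutherland–Hodgman clipping against convex clippers) on 50 µm
  discretised curves; the discretisation error on the test sinusoids is
  below 2·10⁻⁴ relative.
- Zero-area tissue, non-positive band widths, coupling to an unsimulated
  phenotype, cohorts of fewer than 2 samples, constant vectors in
  correlations and single-group comparisons are rejected with explicit
  errors; constant metric columns dichotomize to all-zero bits with a
  warning; zero analysed area suppresses the density record with a
  warning; an empty TC after band subtraction warns but proceeds.
- Problem sizes in the tests and acceptance script (200 replicates for
  Poisson calibration, 1000 for null rejection, 50 cohorts for planted
  recovery, n = 50 for correlation recovery) are the package's chosen
  compromise between Monte-Carlo resolution and a default test run that
  completes in minutes on one CPU.

## Known limitations

The geometry model assumes a single x-monotone interface per sample;
multifocal tumors or closed tumor islands need one geometry per
interface. Proximity is measured within panels (CD8⁺ and PD-L1⁺ share
panel P2); cross-panel proximity would require section registration,
which is out of scope. Scores are cohort-relative by construction —
cutoffs from a 15-sample cohort are not portable reference
distributions, and no survival or treatment-response modelling is
attempted.
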