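# The immune-contexture statistical battery: paired IM-vs-TC comparisons
# (Wilcoxon matched-pairs signed-rank), high-vs-low group comparisons
# (Mann-Whitney U), Pearson correlation / linear regression, and the
# association-panel table with its significance-star mapping.
#
# Rank tests use the exact small-sample null distribution (no ties,
# n <= 25) and the tie-corrected normal approximation otherwise; no
# multiple-testing correction is applied by default.

new_test_result <- function(test, statistic, p_value, n, estimate,
                            ci_lo = NA_real_, ci_hi = NA_real_,
                            degenerate = FALSE, ...) {
  tibble::tibble(test = test, statistic = statistic, p_value = p_value,
                 n = n, estimate = estimate, ci_lo = ci_lo, ci_hi = ci_hi,
                 degenerate = degenerate, ...)
}

#' Significance stars for a p-value
#'
#' `ns` for p > 0.05, `*` for p <= 0.05, `**` for p < 0.01, `***` for
#' p < 0.001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Paired IM-vs-TC comparison of a phenotype's densities
#'
#' Wilcoxon matched-pairs signed-rank test on per-sample density pairs.
#' Samples missing either region are dropped pairwise; if every paired
#' difference is zero the result is flagged degenerate with p = 1.
#'
#' @param densities Density tibble ([compute_densities()]).
#' @param phenotype Phenotype label to test.
#' @param panel Panel to read the phenotype from (default: first panel
#'   carrying it).
#' @param regions Length-2 region pair, default `c("IM", "TC")`; the
#'   estimate is the median of region1 - region2 differences.
#' @return One-row test-result tibble.
#' @export
paired_region_compare <- function(densities, phenotype, panel = NULL,
                                  regions = c("IM", "TC")) {
  d <- densities[densities$phenotype == phenotype, , drop = FALSE]
  if (is.null(panel)) panel <- sort(unique(d$panel))[1]
  d <- d[d$panel == panel, , drop = FALSE]
  wide <- tidyr::pivot_wider(d[, c("sample_id", "region", "density")],
                             names_from = "region", values_from = "density")
  for (r in regions) if (!r %in% names(wide)) wide[[r]] <- NA_real_
  ok <- stats::complete.cases(wide[, regions])
  wide <- wide[ok, , drop = FALSE]
  n <- nrow(wide)
  if (n < 3) stop("need at least 3 samples with both regions", call. = FALSE)
  diffs <- wide[[regions[1]]] - wide[[regions[2]]]
  if (all(diffs == 0)) {
    return(new_test_result("wilcoxon_signed_rank", NA_real_, 1, n, 0,
                           degenerate = TRUE, phenotype = phenotype, panel = panel))
  }
  nz <- diffs[diffs != 0]
  if (length(nz) <= 25) {
    sr <- signed_rank_exact(nz)
    stat <- sr$statistic; p <- sr$p_value
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(wide[[regions[1]]], wide[[regions[2]]],
                         paired = TRUE, exact = FALSE, correct = TRUE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  new_test_result("wilcoxon_signed_rank", stat, p, n, stats::median(diffs),
                  phenotype = phenotype, panel = panel)
}

# Exact two-sided signed-rank p for n <= 25 non-zero differences, valid
# under ties: midranks are doubled to integers and the null distribution of
# the positive-rank sum is built by convolution over the 2^n equally likely
# sign patterns.
signed_rank_exact <- function(d) {
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  f <- numeric(tot + 1)
  f[1] <- 1
  for (s in r2) {
    f <- (f + c(numeric(s), f[seq_len(tot + 1 - s)])) / 2
  }
  v2 <- as.integer(round(2 * v))
  p_le <- sum(f[seq_len(v2 + 1)])
  p_ge <- sum(f[(v2 + 1):(tot + 1)])
  list(statistic = v, p_value = min(1, 2 * min(p_le, p_ge)))
}

#' High-vs-low group comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test of a per-sample value between two groups,
#' exact for small untied samples, tie-corrected normal approximation
#' otherwise. The estimate is the rank-biserial correlation
#' 2U/(n1 n2) - 1.
#'
#' @param values Data frame with columns `value` and `group` (two levels),
#'   or a numeric vector with `group` supplied separately.
#' @param group Optional grouping vector when `values` is numeric.
#' @return One-row test-result tibble.
#' @export
group_compare <- function(values, group = NULL) {
  if (is.data.frame(values)) {
    group <- values$group
    values <- values$value
  }
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("group comparison needs exactly two non-empty groups", call. = FALSE)
  }
  g <- levels(droplevels(group))
  x <- values[group == g[1]]; y <- values[group == g[2]]
  exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)
  )
  u <- unname(wt$statistic)
  rb <- 2 * u / (length(x) * length(y)) - 1
  new_test_result("mann_whitney_u", u, wt$p.value, length(x) + length(y), rb,
                  group_a = g[1], group_b = g[2],
                  n_a = length(x), n_b = length(y))
}

#' Pearson correlation and linear regression of two density vectors
#'
#' @param x,y Numeric vectors (pairwise-complete, n >= 3, non-constant).
#' @param method `"pearson"` (default) or `"spearman"` (no regression CI
#'   for the latter).
#' @return One-row tibble: `test`, `statistic` (r), `p_value`, `n`,
#'   `estimate` (r), `slope`, `intercept`, `ci_lo`/`ci_hi` (95% CI on the
#'   slope).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("correlation is undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  if (method == "pearson") {
    fit <- stats::lm(y ~ x)
    ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
    new_test_result("pearson", unname(ct$estimate), ct$p.value, n,
                    unname(ct$estimate), ci_lo = ci[1], ci_hi = ci[2],
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]))
  } else {
    new_test_result("spearman", unname(ct$estimate), ct$p.value, n,
                    unname(ct$estimate),
                    slope = NA_real_, intercept = NA_real_)
  }
}

# Whole-tissue density: pooled counts over pooled areas across IM and TC.
pooled_density <- function(densities) {
  densities |>
    dplyr::group_by(.data$sample_id, .data$panel, .data$phenotype) |>
    dplyr::summarise(n_cells = sum(.data$n_cells), area_mm2 = sum(.data$area_mm2),
                     .groups = "drop") |>
    dplyr::mutate(density = .data$n_cells / .data$area_mm2)
}

# The association-panel row set (grouped by staining panel).
panel_rows <- function() {
  tibble::tribble(
    ~panel, ~phenotype,
    "P1", "CD20+", "P1", "CD11c+", "P1", "CD15+", "P1", "CD3+", "P1", "CD163+",
    "P2", "PD-1+", "P2", "CD8+PD-1+", "P2", "Ki67+", "P2", "GrzB+",
    "P3", "CD3+", "P3", "CD4+", "P3", "CD4+Foxp3+", "P3", "CD56+"
  )
}

#' Association panel of immune subsets vs CD8/PD-L1 status
#'
#' For each immune-subset row (grouped by staining panel): a Mann-Whitney
#' comparison of whole-tissue density between high and low CD8/PD-L1
#' samples, and correlations of the subset's density with CD8+ and with
#' PD-L1+ density. Stars follow [signif_stars()]. Rows whose phenotype is
#' absent (or everywhere zero) are marked not evaluable.
#'
#' @param densities Density tibble ([compute_densities()]).
#' @param scores `mif_scores` from [cd8_pdl1_score()] (supplies the
#'   high/low grouping).
#' @param rows Tibble (`panel`, `phenotype`) of rows to evaluate; default
#'   the reported immune-subset battery.
#' @param method Correlation method (default Pearson).
#' @return Tibble: `panel`, `phenotype`, `evaluable`, `p_group`,
#'   `stars_group`, `p_cor_cd8`, `stars_cor_cd8`, `p_cor_pdl1`,
#'   `stars_cor_pdl1`.
#' @export
association_panel <- function(densities, scores, rows = panel_rows(),
                              method = "pearson") {
  pooled <- pooled_density(densities)
  ref <- function(ph) {
    v <- pooled[pooled$phenotype == ph & pooled$panel == "P2", c("sample_id", "density")]
    stats::setNames(v$density, v$sample_id)
  }
  cd8 <- ref("CD8+"); pdl1 <- ref("PD-L1+")
  grp <- stats::setNames(as.character(scores$category), scores$sample_id)
  purrr::pmap_dfr(rows, function(panel, phenotype) {
    v <- pooled[pooled$phenotype == phenotype & pooled$panel == panel,
                c("sample_id", "density")]
    vals <- stats::setNames(v$density, v$sample_id)
    ids <- intersect(names(vals), names(grp))
    evaluable <- length(ids) >= 3 && length(unique(vals[ids])) > 1
    if (!evaluable) {
      return(tibble::tibble(panel = panel, phenotype = phenotype,
                            evaluable = FALSE,
                            p_group = NA_real_, stars_group = NA_character_,
                            p_cor_cd8 = NA_real_, stars_cor_cd8 = NA_character_,
                            p_cor_pdl1 = NA_real_, stars_cor_pdl1 = NA_character_))
    }
    pg <- tryCatch(
      group_compare(vals[ids], factor(grp[ids], levels = c("low", "high")))$p_value,
      error = function(e) NA_real_)
    idc <- intersect(ids, names(cd8))
    pc <- tryCatch(correlate(vals[idc], cd8[idc], method = method)$p_value,
                   error = function(e) NA_real_)
    idp <- intersect(ids, names(pdl1))
    pp <- tryCatch(correlate(vals[idp], pdl1[idp], method = method)$p_value,
                   error = function(e) NA_real_)
    tibble::tibble(panel = panel, phenotype = phenotype, evaluable = TRUE,
                   p_group = pg, stars_group = signif_stars(pg),
                   p_cor_cd8 = pc, stars_cor_cd8 = signif_stars(pc),
                   p_cor_pdl1 = pp, stars_cor_pdl1 = signif_stars(pp))
  })
}

#' Region- and MSI-stratified association panels
#'
#' Runs [association_panel()] separately per stratum: region (IM or TC,
#' using region-specific rather than pooled densities) crossed with MSI
#' status when `metadata` is given. Strata with fewer than 3 samples are
#' suppressed with a warning.
#'
#' @param densities Density tibble.
#' @param scores `mif_scores` (high/low grouping).
#' @param metadata Optional tibble `sample_id`, `msi` for MSI stratification.
#' @param rows Row set as in [association_panel()].
#' @param method Correlation method.
#' @return Tibble of per-stratum panels with `region` (and `msi`) columns.
#' @export
region_stratified_panel <- function(densities, scores, metadata = NULL,
                                    rows = panel_rows(), method = "pearson") {
  strata <- tibble::tibble(region = c("IM", "TC"))
  if (!is.null(metadata)) {
    strata <- tidyr::crossing(strata, msi = unique(metadata$msi))
  }
  purrr::pmap_dfr(strata, function(region, msi = NULL) {
    d <- densities[densities$region == region, , drop = FALSE]
    sc <- scores
    if (!is.null(msi)) {
      ids <- metadata$sample_id[metadata$msi == msi]
      d <- d[d$sample_id %in% ids, , drop = FALSE]
      sc <- scores[scores$sample_id %in% ids, , drop = FALSE]
    }
    if (length(unique(d$sample_id)) < 3) {
      warning("stratum ", region, if (!is.null(msi)) paste0("/", msi),
              " has fewer than 3 samples; panel suppressed", call. = FALSE)
      return(NULL)
    }
    out <- association_panel(d, sc, rows = rows, method = method)
    out <- dplyr::mutate(out, region = region, .before = 1)
    if (!is.null(msi)) out <- dplyr::mutate(out, msi = msi, .before = 2)
    out
  })
}

#' Contingency-table association test for categorical covariates
#'
#' Chi-square test of independence, falling back to Fisher's exact test
#' when any expected cell count is below 5.
#'
#' @param a,b Two categorical vectors of equal length (or `a` a 2-way
#'   table).
#' @return One-row test-result tibble.
#' @export
contingency_test <- function(a, b = NULL) {
  tab <- if (is.table(a) || is.matrix(a)) as.table(a) else table(a, b)
  expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    new_test_result("fisher_exact", NA_real_, ft$p.value, sum(tab),
                    if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_)
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    new_test_result("chi_square", unname(ct$statistic), ct$p.value, sum(tab),
                    NA_real_)
  }
}

#' Format an association panel as a markdown table
#'
#' @param panel Output of [association_panel()].
#' @return Character vector of markdown lines.
#' @export
format_panel_md <- function(panel) {
  hdr <- c("| Cell types | High vs low CD8/PD-L1 | Correlation with CD8 | Correlation with PD-L1 |",
           "|---|---|---|---|")
  rows <- character(0)
  for (pan in unique(panel$panel)) {
    rows <- c(rows, paste0("| **Panel ", sub("^P", "", pan), "** | | | |"))
    sub <- panel[panel$panel == pan, , drop = FALSE]
    star <- function(s) ifelse(is.na(s), "n.e.", s)
    rows <- c(rows, sprintf("| %s | %s | %s | %s |", sub$phenotype,
                            star(sub$stars_group), star(sub$stars_cor_cd8),
                            star(sub$stars_cor_pdl1)))
  }
  c(hdr, rows)
}
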