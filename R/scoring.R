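# Cohort-relative composite scores.
#
# Both schemes dichotomize each (metric, region) column at a cohort
# percentile cutoff (default the 50th) and sum the resulting bits:
#   Immunoscore:        CD3 and CD8 densities x {TC, IM}  -> 0..4,
#                       low 0-2, high 3-4.
#   CD8/PD-L1 composite: CD8 density, PD-L1 density and CD8~PD-L1
#                       engaged-cell proximity x {IM, TC} -> 0..6,
#                       low 0-4, high 5-6.
# A bit is 1 iff the sample's value is strictly greater than the column
# cutoff, so ties at the cutoff score 0 and at most half the cohort can be
# above an interpolated median.

#' Linear-interpolation percentile cutoff
#'
#' The convention placing the k-th order statistic at probability
#' (k-1)/(n-1) (type-7 quantile, the R default).
#'
#' @param values Numeric vector (>= 2 finite values).
#' @param p Percentile in (0, 100), default 50.
#' @return The cutoff value.
#' @examples
#' percentile_cutoff(c(1, 2, 3, 4))  # 2.5
#' @export
percentile_cutoff <- function(values, p = 50) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("need at least 2 finite values to place a percentile cutoff", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 100) {
    stop("p must be a single percentage in (0, 100)", call. = FALSE)
  }
  unname(stats::quantile(values, p / 100, type = 7))
}

#' Dichotomize a metric matrix at cohort percentile cutoffs
#'
#' Per column, bit = 1 iff value > cutoff (strict). A constant column
#' yields all-zero bits with a warning (degenerate cohort).
#'
#' @param matrix Tibble with a `sample_id` column and numeric metric
#'   columns; must be complete (no NA) for the scored samples.
#' @param p Percentile, default 50 (the median).
#' @return List with `bits` (tibble of 0/1 with `sample_id`) and `cutoffs`
#'   (named numeric vector).
#' @export
dichotomize <- function(matrix, p = 50) {
  stopifnot(is.data.frame(matrix), "sample_id" %in% names(matrix))
  metric_cols <- setdiff(names(matrix), "sample_id")
  if (anyNA(matrix[metric_cols])) {
    stop("metric matrix has missing values; exclude incomplete samples first",
         call. = FALSE)
  }
  cutoffs <- vapply(matrix[metric_cols], percentile_cutoff, numeric(1), p = p)
  bits <- matrix[, "sample_id", drop = FALSE]
  for (cc in metric_cols) {
    if (length(unique(matrix[[cc]])) == 1) {
      warning("metric column '", cc, "' is constant; all bits set to 0", call. = FALSE)
    }
    bits[[cc]] <- as.integer(matrix[[cc]] > cutoffs[[cc]])
  }
  list(bits = tibble::as_tibble(bits), cutoffs = cutoffs)
}

score_from_bits <- function(bits, cutoffs, scheme, bit_order, high_min) {
  total <- as.integer(rowSums(bits[, bit_order, drop = FALSE]))
  out <- tibble::tibble(
    sample_id = bits$sample_id,
    scheme = scheme,
    bits = lapply(seq_len(nrow(bits)), function(i) {
      vapply(bit_order, function(cc) bits[[cc]][i], integer(1))
    }),
    total = total,
    category = factor(ifelse(total >= high_min, "high", "low"),
                      levels = c("low", "high"))
  )
  attr(out, "cutoffs") <- cutoffs
  attr(out, "high_min") <- high_min
  class(out) <- c("mif_scores", class(out))
  out
}

#' Immunoscore (0-4) from CD3/CD8 densities in TC and IM
#'
#' Each of the four density columns is dichotomized at the cohort 50th
#' percentile; the total over the four bits gives I0-I4, categorized low
#' (0-2) vs high (3-4). Samples with a missing region are excluded with a
#' message.
#'
#' @param matrix Tibble with columns `sample_id`, `CD3_TC`, `CD3_IM`,
#'   `CD8_TC`, `CD8_IM` (densities in cells/mm2); build it with
#'   [immunoscore_matrix()].
#' @param p Dichotomization percentile (default 50).
#' @return A `mif_scores` tibble (`sample_id`, `scheme`, `bits`, `total`,
#'   `category`) with cutoffs in `attr(, "cutoffs")`.
#' @export
immunoscore <- function(matrix, p = 50) {
  need <- c("CD3_TC", "CD3_IM", "CD8_TC", "CD8_IM")
  matrix <- complete_scored(matrix, need)
  d <- dichotomize(matrix[, c("sample_id", need)], p)
  score_from_bits(d$bits, d$cutoffs, "immunoscore",
                  bit_order = need, high_min = 3L)
}

#' Composite CD8/PD-L1 score (0-6)
#'
#' Integrates CD8+ density, PD-L1+ density and the CD8~PD-L1 engaged-cell
#' proximity density in both IM and TC. Each of the six columns is
#' dichotomized at the cohort median; totals 0-6 are categorized low (0-4)
#' vs high (5-6).
#'
#' @param matrix Tibble with columns `sample_id`, `CD8_IM`, `PDL1_IM`,
#'   `PROX_IM`, `CD8_TC`, `PDL1_TC`, `PROX_TC`; build it with
#'   [cd8_pdl1_matrix()].
#' @param p Dichotomization percentile (default 50).
#' @param tc_only Score only the three TC components (0-3 variant of the
#'   original tumor-center classifier); high is then total 3.
#' @return A `mif_scores` tibble.
#' @export
cd8_pdl1_score <- function(matrix, p = 50, tc_only = FALSE) {
  need <- if (tc_only) {
    c("CD8_TC", "PDL1_TC", "PROX_TC")
  } else {
    c("CD8_IM", "PDL1_IM", "PROX_IM", "CD8_TC", "PDL1_TC", "PROX_TC")
  }
  matrix <- complete_scored(matrix, need)
  d <- dichotomize(matrix[, c("sample_id", need)], p)
  score_from_bits(d$bits, d$cutoffs, if (tc_only) "cd8_pdl1_tc" else "cd8_pdl1",
                  bit_order = need, high_min = if (tc_only) 3L else 5L)
}

complete_scored <- function(matrix, need) {
  stopifnot(is.data.frame(matrix), "sample_id" %in% names(matrix))
  miss <- setdiff(need, names(matrix))
  if (length(miss)) {
    stop("metric matrix is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(matrix[, need, drop = FALSE])
  if (any(!ok)) {
    message("excluding ", sum(!ok), " sample(s) with a missing region/metric: ",
            paste(matrix$sample_id[!ok], collapse = ", "))
  }
  tibble::as_tibble(matrix[ok, , drop = FALSE])
}

#' Build the Immunoscore metric matrix from density records
#'
#' @param densities Density tibble from [compute_densities()].
#' @param cd3_panel,cd8_panel Panels to read CD3 and CD8 from (defaults:
#'   CD3 from the T-cell subset panel P3, CD8 from the cytotoxic panel P2).
#' @return Wide tibble `sample_id`, `CD3_TC`, `CD3_IM`, `CD8_TC`, `CD8_IM`.
#' @export
immunoscore_matrix <- function(densities, cd3_panel = "P3", cd8_panel = "P2") {
  wide <- function(ph, pan, nm) {
    densities |>
      dplyr::filter(.data$phenotype == ph, .data$panel == pan) |>
      dplyr::select("sample_id", "region", "density") |>
      tidyr::pivot_wider(names_from = "region", values_from = "density",
                         names_prefix = paste0(nm, "_"))
  }
  dplyr::full_join(wide("CD3+", cd3_panel, "CD3"), wide("CD8+", cd8_panel, "CD8"),
                   by = "sample_id") |>
    dplyr::rename_with(~ sub("^(CD[38])_(IM|TC)$", "\\1_\\2", .x))
}

#' Build the CD8/PD-L1 composite metric matrix
#'
#' @param densities Density tibble ([compute_densities()]).
#' @param proximity Proximity tibble ([proximity_table()]).
#' @param metric `"engaged_density"` (default) or `"pair_density"` as the
#'   proximity component.
#' @return Wide tibble `sample_id`, `CD8_IM`, `PDL1_IM`, `PROX_IM`,
#'   `CD8_TC`, `PDL1_TC`, `PROX_TC`.
#' @export
cd8_pdl1_matrix <- function(densities, proximity,
                            metric = c("engaged_density", "pair_density")) {
  metric <- match.arg(metric)
  dens <- densities |>
    dplyr::filter(.data$panel == "P2", .data$phenotype %in% c("CD8+", "PD-L1+")) |>
    dplyr::mutate(metric_name = paste0(
      ifelse(.data$phenotype == "CD8+", "CD8", "PDL1"), "_", .data$region)) |>
    dplyr::select("sample_id", "metric_name", value = "density")
  prox <- proximity |>
    dplyr::mutate(metric_name = paste0("PROX_", .data$region)) |>
    dplyr::select("sample_id", "metric_name", value = dplyr::all_of(metric))
  dplyr::bind_rows(dens, prox) |>
    tidyr::pivot_wider(names_from = "metric_name", values_from = "value")
}

#' @export
print.mif_scores <- function(x, ...) {
  cat("<mif_scores> scheme:", x$scheme[1], " n =", nrow(x),
      " high:", sum(x$category == "high"), "\n")
  NextMethod()
}

#' Tidy a score object into one row per component bit
#'
#' @param x A `mif_scores` object.
#' @param ... Unused.
#' @return Tibble `sample_id`, `scheme`, `component`, `bit`, `cutoff`.
#' @export
tidy.mif_scores <- function(x, ...) {
  cutoffs <- attr(x, "cutoffs")
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    b <- x$bits[[i]]
    tibble::tibble(sample_id = x$sample_id[i], scheme = x$scheme[i],
                   component = names(b), bit = unname(b),
                   cutoff = unname(cutoffs[names(b)]))
  })
}

#' One-row summary of a score object
#'
#' @param x A `mif_scores` object.
#' @param ... Unused.
#' @return Tibble `scheme`, `n`, `n_high`, `n_low`, `median_total`.
#' @export
glance.mif_scores <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme[1], n = nrow(x),
    n_high = sum(x$category == "high"),
    n_low = sum(x$category == "low"),
    median_total = stats::median(x$total)
  )
}
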