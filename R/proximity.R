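# CD8/PD-L1 (and arbitrary phenotype-pair) spatial proximity at a radius.
#
# A cell of phenotype A is "engaged" if at least one phenotype-B cell lies
# within the proximity radius (closed ball, default 20 um). The scored
# statistic is the engaged-cell density (engaged A cells per mm2 of
# analysed area); the raw A-B pair count is also reported.

#' All point pairs within a radius
#'
#' Grid-bucketed fixed-radius neighbor search: points are binned into
#' radius-sized cells and only the 3 x 3 bin neighborhood is scanned, so
#' the cost is near-linear for spatially homogeneous patterns. Distances
#' are Euclidean and the ball is closed (a pair at exactly `radius_um`
#' counts).
#'
#' @param a_points,b_points Two-column matrices or data frames of x, y
#'   coordinates in um.
#' @param radius_um Positive radius.
#' @param same Treat the two sets as the same point set and return each
#'   unordered pair once (`i < j`), excluding self-pairs. Defaults to TRUE
#'   when `a_points` and `b_points` are identical.
#' @return Tibble with columns `i` (row in a), `j` (row in b), `d_um`.
#' @export
radius_pairs <- function(a_points, b_points, radius_um = 20,
                         same = identical(a_points, b_points)) {
  stopifnot(is.numeric(radius_um), length(radius_um) == 1, radius_um > 0)
  a <- as.matrix(a_points)[, 1:2, drop = FALSE]
  b <- as.matrix(b_points)[, 1:2, drop = FALSE]
  storage.mode(a) <- storage.mode(b) <- "double"
  empty <- tibble::tibble(i = integer(0), j = integer(0), d_um = numeric(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  ox <- min(a[, 1], b[, 1]); oy <- min(a[, 2], b[, 2])
  bx_a <- floor((a[, 1] - ox) / radius_um); by_a <- floor((a[, 2] - oy) / radius_um)
  bx_b <- floor((b[, 1] - ox) / radius_um); by_b <- floor((b[, 2] - oy) / radius_um)
  span <- max(bx_a, bx_b) + 3
  key_b <- bx_b + span * by_b
  b_by_bin <- split(seq_len(nrow(b)), key_b)
  out_i <- vector("list", nrow(a)); out_j <- vector("list", nrow(a))
  r2 <- radius_um^2
  for (ia in seq_len(nrow(a))) {
    js <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- as.character((bx_a[ia] + dx) + span * (by_a[ia] + dy))
      hit <- b_by_bin[[k]]
      if (!is.null(hit)) js <- c(js, hit)
    }
    if (length(js)) {
      d2 <- (b[js, 1] - a[ia, 1])^2 + (b[js, 2] - a[ia, 2])^2
      keep <- d2 <= r2
      if (same) keep <- keep & js > ia
      if (any(keep)) {
        out_i[[ia]] <- rep.int(ia, sum(keep))
        out_j[[ia]] <- js[keep]
      }
    }
  }
  i <- unlist(out_i); j <- unlist(out_j)
  if (is.null(i)) return(empty)
  d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
  tibble::tibble(i = as.integer(i), j = as.integer(j), d_um = d)[order(i, j), ]
}

#' Proximity summary for a phenotype pair in one compartment
#'
#' A cells are phenotype-`a` cells carrying the region label and lying in
#' the region's analysis fields; B cells are phenotype-`b` cells (any
#' region label) within the fields dilated by the radius, so neighbors
#' just outside a field edge still count. Engaged density is the number of
#' A cells with at least one B neighbor within the radius, per mm2 of
#' analysed field area.
#'
#' @param cells Gated, region-assigned cell tibble.
#' @param region `"IM"` or `"TC"`.
#' @param phenotype_a,phenotype_b Phenotype labels (e.g. `"CD8+"`,
#'   `"PD-L1+"`).
#' @param radius_um Proximity radius in um (default 20).
#' @param fields Field tibble for this sample ([select_fields()]).
#' @param panel Panel carrying both phenotypes (default `"P2"`).
#' @return One-row tibble: `region`, `phenotype_a`, `phenotype_b`,
#'   `radius_um`, `n_a`, `n_b`, `n_a_engaged`, `n_pairs`, `area_mm2`,
#'   `engaged_density`, `pair_density`.
#' @export
proximity_stat <- function(cells, region, phenotype_a = "CD8+",
                           phenotype_b = "PD-L1+", radius_um = 20,
                           fields, panel = "P2") {
  stopifnot(radius_um > 0)
  f <- fields[fields$region == region, , drop = FALSE]
  area <- sum(f$area_mm2)
  has_ph <- function(ph) vapply(cells$phenotypes, function(p) ph %in% p, logical(1))
  pa <- cells$panel == panel & has_ph(phenotype_a)
  a_cells <- cells[pa & cells$region == region &
                     in_any_field(cells$x_um, cells$y_um, f), , drop = FALSE]
  pb <- cells$panel == panel & has_ph(phenotype_b)
  b_cells <- cells[pb & in_any_field(cells$x_um, cells$y_um, f, dilate_um = radius_um),
                   , drop = FALSE]
  if (nrow(a_cells) == 0 || nrow(b_cells) == 0) {
    pairs <- tibble::tibble(i = integer(0), j = integer(0))
  } else {
    pairs <- radius_pairs(cbind(a_cells$x_um, a_cells$y_um),
                          cbind(b_cells$x_um, b_cells$y_um),
                          radius_um, same = FALSE)
    if (identical(phenotype_a, phenotype_b)) {
      # same phenotype: drop self-pairs (zero distance to one's own record)
      pairs <- pairs[pairs$d_um > 0, , drop = FALSE]
    }
  }
  n_eng <- length(unique(pairs$i))
  tibble::tibble(
    region = region, phenotype_a = phenotype_a, phenotype_b = phenotype_b,
    radius_um = radius_um,
    n_a = nrow(a_cells), n_b = nrow(b_cells),
    n_a_engaged = n_eng, n_pairs = nrow(pairs),
    area_mm2 = area,
    engaged_density = if (area > 0) n_eng / area else NA_real_,
    pair_density = if (area > 0) nrow(pairs) / area else NA_real_
  )
}

#' Proximity records for every sample and compartment
#'
#' Convenience wrapper applying [proximity_stat()] per sample and region.
#'
#' @inheritParams proximity_stat
#' @param fields Field tibble with a `sample_id` column (or recycled).
#' @return Tibble of proximity records with a `sample_id` column.
#' @export
proximity_table <- function(cells, fields, phenotype_a = "CD8+",
                            phenotype_b = "PD-L1+", radius_um = 20,
                            panel = "P2") {
  if (!"sample_id" %in% names(fields)) {
    fields <- tidyr::crossing(sample_id = unique(cells$sample_id), fields)
  }
  purrr::map_dfr(unique(cells$sample_id), function(sid) {
    sc <- cells[cells$sample_id == sid, , drop = FALSE]
    sf <- fields[fields$sample_id == sid, , drop = FALSE]
    purrr::map_dfr(intersect(c("IM", "TC"), unique(sf$region)), function(reg) {
      proximity_stat(sc, reg, phenotype_a, phenotype_b, radius_um,
                     sf, panel = panel)
    }) |>
      dplyr::mutate(sample_id = sid, .before = 1)
  })
}
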