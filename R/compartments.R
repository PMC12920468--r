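# Compartment delineation: tumor center (TC) vs invasive margin (IM).
#
# The IM is the band of fixed total perpendicular width (default 1 mm)
# spanning the tumor-stroma interface; the TC is the tumor polygon minus
# that band. Coordinates are micrometres throughout, y increasing downward
# (image convention).

#' Specify a synthetic tumor-stroma interface
#'
#' Describes the tissue extent and the shape of the tumor-stroma interface
#' used by [make_geometry()]. The interface runs left-to-right across the
#' tissue; the tumor side is the +y half (below the interface in image
#' coordinates).
#'
#' @param length_mm Chord length of the interface polyline in mm (> 0).
#' @param shape `"straight"` or `"sinusoidal"`.
#' @param amplitude_mm Peak deviation of a sinusoidal interface from its
#'   baseline, in mm (ignored for `"straight"`).
#' @param tissue_extent_mm Numeric length-2 vector `c(width, height)` in mm.
#' @param wavelength_mm Wavelength of the sinusoid in mm; the default (one
#'   period over the interface chord) keeps the curvature radius well above
#'   half the band width so offset bands stay parallel.
#' @return An object of class `interface_spec`.
#' @examples
#' interface_spec(5, "sinusoidal", amplitude_mm = 0.4)
#' @export
interface_spec <- function(length_mm = 5, shape = c("straight", "sinusoidal"),
                           amplitude_mm = 0, tissue_extent_mm = c(6, 4),
                           wavelength_mm = length_mm) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(length_mm), length(length_mm) == 1, is.finite(length_mm))
  if (length_mm <= 0) stop("interface length must be positive", call. = FALSE)
  if (!is.numeric(amplitude_mm) || amplitude_mm < 0) {
    stop("amplitude_mm must be a non-negative number", call. = FALSE)
  }
  if (length(tissue_extent_mm) != 2 || any(!is.finite(tissue_extent_mm)) ||
      any(tissue_extent_mm <= 0)) {
    stop("tissue extent must be two positive lengths (mm); a zero-area tissue is degenerate",
         call. = FALSE)
  }
  if (length_mm > tissue_extent_mm[1]) {
    stop("interface chord longer than the tissue width", call. = FALSE)
  }
  structure(
    list(length_mm = length_mm, shape = shape, amplitude_mm = amplitude_mm,
         tissue_extent_mm = as.numeric(tissue_extent_mm),
         wavelength_mm = wavelength_mm),
    class = "interface_spec"
  )
}

# Evaluate the full-width split curve y(x) of a spec at abscissae x_um.
# phase is drawn once per geometry; outside the interface chord the curve
# continues flat at its baseline so the tissue is always split in two.
split_curve_y <- function(spec, x_um, phase) {
  H <- spec$tissue_extent_mm[2] * 1000
  W <- spec$tissue_extent_mm[1] * 1000
  y0 <- H / 2
  if (spec$shape == "straight" || spec$amplitude_mm == 0) return(rep(y0, length(x_um)))
  L <- spec$length_mm * 1000
  x0 <- (W - L) / 2
  k <- 2 * pi / (spec$wavelength_mm * 1000)
  y <- y0 + spec$amplitude_mm * 1000 * sin(k * (x_um - x0) + phase)
  y[x_um < x0 | x_um > x0 + L] <-
    y0 + spec$amplitude_mm * 1000 * sin(phase)  # continue flat beyond chord
  # clamp inside tissue
  pmin(pmax(y, 0), H)
}

#' Build synthetic compartment geometry
#'
#' Constructs a rectangular tissue, a tumor-stroma interface per the spec,
#' the tumor-side and stroma-side polygons, and derives the IM band and TC
#' polygon. Deterministic for a fixed `(spec, seed)` pair (the seed fixes
#' the sinusoid phase).
#'
#' @param spec An [interface_spec()].
#' @param seed Integer seed controlling the interface phase.
#' @param im_width_um Total perpendicular width of the invasive margin band
#'   (default 1000).
#' @return A `mif_geometry` object: a list with elements `tissue`, `tumor`,
#'   `stroma`, `interface`, `split_curve` (polygon/polyline matrices, um),
#'   `im_band`, `tc`, `im_width_um`.
#' @examples
#' g <- make_geometry(interface_spec(5, "straight"), seed = 1)
#' attr(g, "areas_mm2")
#' @export
make_geometry <- function(spec, seed = 1L, im_width_um = 1000) {
  stopifnot(inherits(spec, "interface_spec"))
  withr::with_seed(as.integer(seed), make_geometry_rng(spec, im_width_um))
}

# RNG-stream version used inside simulate_cohort()'s single seeded block.
make_geometry_rng <- function(spec, im_width_um = 1000) {
  W <- spec$tissue_extent_mm[1] * 1000
  H <- spec$tissue_extent_mm[2] * 1000
  phase <- if (spec$shape == "sinusoidal") stats::runif(1, 0, 2 * pi) else 0
  step <- 50  # um discretisation of curved interfaces
  xs <- seq(0, W, by = step)
  if (xs[length(xs)] < W) xs <- c(xs, W)
  ys <- split_curve_y(spec, xs, phase)
  split_curve <- cbind(x = xs, y = ys)
  if (spec$shape == "straight") split_curve <- split_curve[c(1, nrow(split_curve)), , drop = FALSE]

  # interface polyline: the central length_mm chord of the split curve
  L <- spec$length_mm * 1000
  x0 <- (W - L) / 2; x1 <- x0 + L
  keep <- xs >= x0 - 1e-9 & xs <= x1 + 1e-9
  xi <- xs[keep]
  if (length(xi) == 0 || min(xi) > x0) xi <- c(x0, xi)
  if (max(xi) < x1) xi <- c(xi, x1)
  xi <- sort(unique(c(x0, xi, x1)))
  interface <- cbind(x = xi, y = split_curve_y(spec, xi, phase))
  if (spec$shape == "straight") interface <- interface[c(1, nrow(interface)), , drop = FALSE]

  tissue <- rect_polygon(0, 0, W, H)
  # tumor side: y >= split curve (image convention: tumor below the line)
  tumor <- rbind(split_curve, cbind(x = c(W, 0), y = c(H, H)))
  stroma <- rbind(split_curve[rev(seq_len(nrow(split_curve))), , drop = FALSE],
                  cbind(x = c(0, W), y = c(0, 0)))
  colnames(tumor) <- colnames(stroma) <- c("x", "y")
  g <- derive_regions(tumor, interface, im_width_um,
                      tissue = tissue, split_curve = split_curve, stroma = stroma)
  g$phase <- phase
  g
}

#' Build the invasive-margin band polygon
#'
#' Dilates the interface polyline by `width_um / 2` perpendicular on each
#' side with flat end caps, so the total perpendicular width equals
#' `width_um` and the band does not extend beyond the delineated interface.
#'
#' @param interface Polyline matrix (um).
#' @param width_um Total band width in um (> 0).
#' @return Polygon matrix (um).
#' @examples
#' band <- build_im_band(cbind(c(0, 5000), c(0, 0)), 1000)
#' polygon_area(band) / 1e6  # 5 mm^2
#' @export
build_im_band <- function(interface, width_um = 1000) {
  interface <- as.matrix(interface)
  if (nrow(interface) < 2) stop("interface needs at least 2 vertices", call. = FALSE)
  buffer_polyline(interface, width_um)
}

#' Derive IM and TC compartments from tumor geometry
#'
#' The IM is the flat-capped band of total width `width_um` around the
#' interface; the TC is the tumor polygon beyond that band. The tumor
#' polygon must lie on one side of the interface, with the interface an
#' x-monotone polyline spanning the tumor's x-extent (the geometry model
#' produced by [make_geometry()] and the GeoJSON dialect).
#'
#' @param tumor_polygon Polygon matrix (um).
#' @param interface Polyline matrix (um).
#' @param width_um IM band total width (um, > 0).
#' @param tissue,split_curve,stroma Optional precomputed pieces (used
#'   internally by [make_geometry()]); when missing, the tissue is the
#'   bounding box of the tumor polygon and the split curve is the interface.
#' @return A `mif_geometry` object (see [make_geometry()]); attribute
#'   `areas_mm2` carries tissue/tumor/im/tc areas.
#' @export
derive_regions <- function(tumor_polygon, interface, width_um = 1000,
                           tissue = NULL, split_curve = NULL, stroma = NULL) {
  tumor_polygon <- as.matrix(tumor_polygon)
  interface <- as.matrix(interface)
  if (is.null(split_curve)) split_curve <- interface
  if (is.null(tissue)) {
    tissue <- rect_polygon(min(tumor_polygon[, 1]), min(tumor_polygon[, 2]),
                           max(tumor_polygon[, 1]), max(tumor_polygon[, 2]))
  }
  bbox <- c(min(tissue[, 1]), min(tissue[, 2]), max(tissue[, 1]), max(tissue[, 2]))
  band <- buffer_polyline(interface, width_um)
  band <- clip_polygon_convex(band, tissue)

  # which side of the split curve is tumor? test the tumor area centroid
  cen <- polygon_centroid(tumor_polygon)
  cx <- cen[1]; cy <- cen[2]
  ymid <- stats::approx(split_curve[, 1], split_curve[, 2], xout = cx, rule = 2)$y
  tumor_up <- cy >= ymid  # tumor on +y side
  # the left normal of a left-to-right curve points to +y, so +w/2 moves
  # the curve into an upper tumor
  off <- offset_polyline(split_curve, if (tumor_up) width_um / 2 else -width_um / 2)
  off[, 1] <- pmin(pmax(off[, 1], bbox[1]), bbox[3])
  off[, 2] <- pmin(pmax(off[, 2], bbox[2]), bbox[4])
  tc <- if (tumor_up) {
    rbind(off, cbind(c(bbox[3], bbox[1]), c(bbox[4], bbox[4])))
  } else {
    rbind(off[rev(seq_len(nrow(off))), , drop = FALSE],
          cbind(c(bbox[1], bbox[3]), c(bbox[2], bbox[2])))
  }
  colnames(tc) <- c("x", "y")
  tc <- clip_polygon_convex(tc, tissue)

  tumor_area <- polygon_area(tumor_polygon) / 1e6
  tc_area <- polygon_area(tc) / 1e6
  if (tc_area < 1e-9) {
    warning("TC is empty after removing the IM band (tumor smaller than the band)",
            call. = FALSE)
  }
  g <- structure(
    list(tissue = tissue, tumor = tumor_polygon, stroma = stroma,
         interface = interface, split_curve = split_curve,
         im_band = band, tc = tc, im_width_um = width_um),
    class = "mif_geometry"
  )
  attr(g, "areas_mm2") <- c(
    tissue = polygon_area(tissue) / 1e6,
    tumor = tumor_area,
    IM = polygon_area(band) / 1e6,
    TC = tc_area
  )
  g
}

#' @export
print.mif_geometry <- function(x, ...) {
  a <- attr(x, "areas_mm2")
  cat("<mif_geometry> tissue", sprintf("%.2f", a["tissue"]), "mm2 |",
      "tumor", sprintf("%.2f", a["tumor"]), "| IM", sprintf("%.2f", a["IM"]),
      "| TC", sprintf("%.2f", a["TC"]), "mm2; IM width",
      x$im_width_um, "um\n")
  invisible(x)
}

#' Assign cells to compartments
#'
#' Labels every cell `IM`, `TC` or `outside`. A cell is in the IM iff its
#' perpendicular distance to the interface polyline is at most half the band
#' width (closed band: a cell at exactly width/2 is IM); IM takes precedence
#' over TC. Otherwise a cell inside the tumor polygon is TC; everything else
#' is `outside`.
#'
#' @param cells Data frame with `x_um`, `y_um` columns.
#' @param geometry A `mif_geometry`.
#' @return The cell tibble with a `region` factor column
#'   (`levels IM, TC, outside`).
#' @export
assign_regions <- function(cells, geometry) {
  stopifnot(inherits(geometry, "mif_geometry"))
  cells <- tibble::as_tibble(cells)
  x <- cells$x_um; y <- cells$y_um
  im <- in_band(x, y, geometry$interface, geometry$im_width_um)
  tum <- point_in_polygon(x, y, geometry$tumor)
  region <- ifelse(im, "IM", ifelse(tum, "TC", "outside"))
  cells$region <- factor(region, levels = c("IM", "TC", "outside"))
  cells
}

#' Select representative analysis fields within a compartment
#'
#' Formalises "up to 5 representative fields" as a greedy maximum-overlap
#' rule: candidate square fields on a half-field grid are ranked by their
#' overlap area with the region polygon, and up to `n_max` non-overlapping
#' fields are chosen in rank order. Ties in overlap area are broken by a
#' seeded random order, so the choice is deterministic given the seed.
#'
#' @param geometry A `mif_geometry`.
#' @param region `"IM"` or `"TC"`.
#' @param n_max Maximum number of fields (default 5).
#' @param side_um Field side length in um (default 1000, i.e. 1 mm2 fields).
#' @param seed Integer seed for tie-breaking.
#' @return Tibble with columns `region`, `field_id`, `x0_um`, `y0_um`,
#'   `side_um`, `area_mm2` (field-by-region overlap actually analysed).
#' @export
select_fields <- function(geometry, region = c("IM", "TC"), n_max = 5,
                          side_um = 1000, seed = 1L) {
  region <- match.arg(region)
  stopifnot(inherits(geometry, "mif_geometry"), n_max >= 1, side_um > 0)
  poly <- if (region == "IM") geometry$im_band else geometry$tc
  if (is.null(poly) || nrow(poly) < 3 || polygon_area(poly) < 1e-9) {
    stop("region polygon is empty; cannot place fields", call. = FALSE)
  }
  bb <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
  step <- side_um / 2
  ox <- seq(bb[1] - side_um / 2, bb[3] - side_um / 2, by = step)
  oy <- seq(bb[2] - side_um / 2, bb[4] - side_um / 2, by = step)
  cand <- expand.grid(x0 = ox, y0 = oy)
  cx <- cand$x0 + side_um / 2; cy <- cand$y0 + side_um / 2
  keep <- region_membership(cx, cy, geometry) == region
  cand <- cand[keep, , drop = FALSE]
  small <- polygon_area(poly) < side_um^2
  if (small) {
    warning("region smaller than one field; returning a single clipped field",
            call. = FALSE)
    n_max <- 1
  }
  if (nrow(cand) == 0) {
    cen <- polygon_centroid(poly)
    cand <- data.frame(x0 = cen[1] - side_um / 2, y0 = cen[2] - side_um / 2)
  }
  ov <- vapply(seq_len(nrow(cand)), function(i) {
    sq <- rect_polygon(cand$x0[i], cand$y0[i], cand$x0[i] + side_um, cand$y0[i] + side_um)
    clipped <- clip_polygon_convex(poly, sq)
    polygon_area(clipped)
  }, numeric(1))
  ord <- withr::with_seed(as.integer(seed), {
    tie <- sample.int(nrow(cand))
    order(-ov, tie)
  })
  chosen <- integer(0)
  for (i in ord) {
    if (ov[i] <= 0 && !small) next
    overlaps <- FALSE
    for (j in chosen) {
      if (abs(cand$x0[i] - cand$x0[j]) < side_um && abs(cand$y0[i] - cand$y0[j]) < side_um) {
        overlaps <- TRUE; break
      }
    }
    if (!overlaps) chosen <- c(chosen, i)
    if (length(chosen) == n_max) break
  }
  tibble::tibble(
    region = region,
    field_id = seq_along(chosen),
    x0_um = cand$x0[chosen],
    y0_um = cand$y0[chosen],
    side_um = side_um,
    area_mm2 = ov[chosen] / 1e6
  )
}

# Region label of arbitrary points under the assignment rule.
region_membership <- function(x, y, geometry) {
  im <- in_band(x, y, geometry$interface, geometry$im_width_um)
  tum <- point_in_polygon(x, y, geometry$tumor)
  ifelse(im, "IM", ifelse(tum, "TC", "outside"))
}

# TRUE for points inside any of the given square fields (closed boundary),
# optionally dilated by `dilate_um` on each side.
in_any_field <- function(x, y, fields, dilate_um = 0) {
  inf <- rep(FALSE, length(x))
  for (i in seq_len(nrow(fields))) {
    inf <- inf |
      (x >= fields$x0_um[i] - dilate_um & x <= fields$x0_um[i] + fields$side_um[i] + dilate_um &
       y >= fields$y0_um[i] - dilate_um & y <= fields$y0_um[i] + fields$side_um[i] + dilate_um)
  }
  inf
}

#' Compute per-phenotype cell densities over analysis fields
#'
#' For each (sample, region, panel, phenotype): the count of phenotype cells
#' that carry that region label and fall inside the union of the region's
#' fields, divided by the summed field-by-region overlap area (pooled
#' counts over pooled areas). `density * area` therefore recovers the
#' integer count exactly.
#'
#' @param cells Gated, region-assigned cell tibble (needs `sample_id`,
#'   `panel`, `x_um`, `y_um`, `region`, `phenotypes` list-column).
#' @param fields Tibble of fields as returned by [select_fields()], with a
#'   `sample_id` column when `cells` spans several samples (fields without
#'   one are recycled to every sample).
#' @param phenotypes Optional tibble (`phenotype`, `panel`) or character
#'   vector restricting/padding the output: requested phenotypes absent
#'   from a sample get an explicit zero-density record.
#' @return Tibble of density records: `sample_id`, `region`, `panel`,
#'   `phenotype`, `n_cells`, `area_mm2`, `density` (cells/mm2).
#' @export
compute_densities <- function(cells, fields, phenotypes = NULL) {
  stopifnot(is.data.frame(cells), is.data.frame(fields))
  if (!"phenotypes" %in% names(cells)) {
    stop("cells must be gated first (missing 'phenotypes' column); see gate_phenotypes()",
         call. = FALSE)
  }
  if (!"region" %in% names(cells)) {
    stop("cells must be region-assigned first; see assign_regions()", call. = FALSE)
  }
  if (!"sample_id" %in% names(fields)) {
    fields <- tidyr::crossing(sample_id = unique(cells$sample_id), fields)
  }
  areas <- fields |>
    dplyr::group_by(.data$sample_id, .data$region) |>
    dplyr::summarise(area_mm2 = sum(.data$area_mm2), .groups = "drop")
  zero_area <- areas$area_mm2 <= 0
  if (any(zero_area)) {
    warning("suppressing density records with zero analysed area", call. = FALSE)
    areas <- areas[!zero_area, , drop = FALSE]
  }

  samp_ids <- unique(cells$sample_id)
  counts <- purrr::map_dfr(samp_ids, function(sid) {
    sc <- cells[cells$sample_id == sid, , drop = FALSE]
    purrr::map_dfr(c("IM", "TC"), function(reg) {
      f <- fields[fields$sample_id == sid & fields$region == reg, , drop = FALSE]
      if (nrow(f) == 0) return(NULL)
      inside <- sc$region == reg & in_any_field(sc$x_um, sc$y_um, f)
      sub <- sc[inside, c("panel", "phenotypes")]
      if (nrow(sub) == 0) {
        return(tibble::tibble(sample_id = sid, region = reg,
                              panel = character(0), phenotype = character(0),
                              n_cells = integer(0)))
      }
      long <- tidyr::unnest(sub, "phenotypes") |>
        dplyr::count(.data$panel, phenotype = .data$phenotypes, name = "n_cells")
      dplyr::mutate(long, sample_id = sid, region = reg, .before = 1)
    })
  })

  if (is.null(phenotypes)) {
    phen <- dplyr::distinct(counts, .data$panel, .data$phenotype)
  } else if (is.character(phenotypes)) {
    phen <- dplyr::distinct(counts[counts$phenotype %in% phenotypes, ],
                            .data$panel, .data$phenotype)
    missing <- setdiff(phenotypes, phen$phenotype)
    if (length(missing)) {
      pan <- dplyr::distinct(cells, .data$panel)$panel[1]
      phen <- dplyr::bind_rows(phen, tibble::tibble(panel = pan, phenotype = missing))
    }
  } else {
    phen <- tibble::as_tibble(phenotypes)
  }

  grid <- tidyr::crossing(areas, phen)
  out <- grid |>
    dplyr::left_join(counts, by = c("sample_id", "region", "panel", "phenotype")) |>
    dplyr::mutate(
      n_cells = as.integer(dplyr::coalesce(.data$n_cells, 0L)),
      density = .data$n_cells / .data$area_mm2
    ) |>
    dplyr::select("sample_id", "region", "panel", "phenotype",
                  "n_cells", "area_mm2", "density") |>
    dplyr::arrange(.data$sample_id, .data$region, .data$panel, .data$phenotype)
  out
}
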