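# Cell-table and geometry IO, marker vocabulary, and phenotype gating.
#
# Cell tables are tidy CSVs: sample_id, panel, x_um, y_um, then one 0/1
# column per marker. Coordinates are micrometres, y increasing downward.
# A documented alias map accepts QuPath-style export headers.

#' The 14-marker vocabulary and the three staining panels
#'
#' Panel 1 profiles overall immune composition (B cells, dendritic cells,
#' neutrophils, T cells, macrophages), Panel 2 cytotoxic and functional
#' markers around the PD-1/PD-L1 axis, Panel 3 T-cell subsets and NK cells.
#' Cytokeratin (CK) marks tumor epithelium on every panel.
#'
#' @return Named list of character vectors of marker names per panel.
#' @export
panel_markers <- function() {
  list(
    P1 = c("CK", "CD20", "CD11c", "CD15", "CD3", "CD163"),
    P2 = c("CK", "PD-1", "CD8", "PD-L1", "Ki67", "GrzB"),
    P3 = c("CK", "CD3", "CD4", "Foxp3", "CD56", "CD8")
  )
}

#' @rdname panel_markers
#' @export
all_markers <- function() {
  c("CK", "CD20", "CD11c", "CD163", "CD15", "CD56", "CD3", "CD4", "CD8",
    "Foxp3", "GrzB", "Ki67", "PD-1", "PD-L1")
}

#' Column alias map for QuPath-style exports
#'
#' Maps common header variants (QuPath centroid columns, hyphen-less marker
#' names, case variants) onto the canonical dialect. Users can extend the
#' returned named character vector (`alias -> canonical`) and pass it to
#' [read_cell_table()].
#'
#' @return Named character vector.
#' @export
qupath_aliases <- function() {
  c(
    "Centroid X µm" = "x_um", "Centroid Y µm" = "y_um",
    "Centroid X um" = "x_um", "Centroid Y um" = "y_um",
    "Image" = "sample_id", "Parent" = "panel",
    "PDL1" = "PD-L1", "PD1" = "PD-1", "FOXP3" = "Foxp3", "FoxP3" = "Foxp3",
    "GRZB" = "GrzB", "Granzyme B" = "GrzB", "KI67" = "Ki67",
    "Cytokeratin" = "CK", "PanCK" = "CK"
  )
}

#' Read a per-cell detection table
#'
#' Parses the CSV dialect (or a QuPath-style variant via the alias map),
#' validates coordinates, and keeps only known marker columns. Unknown
#' marker-like columns are dropped with a warning; rows with non-finite
#' coordinates are rejected with row-level diagnostics.
#'
#' @param path CSV file.
#' @param aliases Named character vector mapping foreign headers to the
#'   canonical dialect (default [qupath_aliases()]).
#' @return Cell tibble: `sample_id`, `panel`, `x_um`, `y_um`, one integer
#'   0/1 column per marker present.
#' @export
read_cell_table <- function(path, aliases = qupath_aliases()) {
  if (!file.exists(path)) stop("cell table not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(tab)
  hit <- nm %in% names(aliases)
  nm[hit] <- unname(aliases[nm[hit]])
  names(tab) <- nm
  if (!all(c("x_um", "y_um") %in% nm)) {
    stop("cell table is missing coordinate columns x_um/y_um (after alias mapping)",
         call. = FALSE)
  }
  if (!"sample_id" %in% nm) tab$sample_id <- "sample_1"
  if (!"panel" %in% nm) tab$panel <- "P1"
  known <- c("sample_id", "panel", "x_um", "y_um", "region",
             "true_phenotype", "true_region", all_markers())
  unknown <- setdiff(nm, known)
  if (length(unknown)) {
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    tab <- tab[, setdiff(names(tab), unknown), drop = FALSE]
  }
  bad <- !is.finite(tab$x_um) | !is.finite(tab$y_um)
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with non-finite coordinates (rows ",
            paste(utils::head(which(bad), 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", ")", call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  for (m in intersect(all_markers(), names(tab))) {
    tab[[m]] <- as.integer(tab[[m]] != 0)
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab$panel <- as.character(tab$panel)
  tibble::as_tibble(tab)
}

#' Write a cell table in the canonical CSV dialect
#'
#' @param cells Cell tibble; list columns (derived phenotypes) are dropped,
#'   since they are re-derivable by [gate_phenotypes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  keep <- !vapply(cells, is.list, logical(1))
  flat <- cells[, keep, drop = FALSE]
  if ("region" %in% names(flat)) flat$region <- as.character(flat$region)
  lead <- intersect(c("sample_id", "panel", "x_um", "y_um"), names(flat))
  flat <- flat[, c(lead, setdiff(names(flat), lead)), drop = FALSE]
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Default phenotype gating rules
#'
#' One rule per reported population: B cells (CD20+), dendritic cells
#' (CD11c+), neutrophils (CD15+), macrophages (CD163+), T cells (CD3+),
#' CD8+ and CD4+ T cells, checkpoint-positive cells (PD-1+, PD-L1+),
#' functional markers (GrzB+, Ki67+), exhausted cytotoxic cells
#' (CD8+PD-1+), regulatory T cells (CD4+Foxp3+), NK cells (CD56+) and
#' tumor epithelium (CK+). NK cells follow the permissive CD56+ gate; set
#' `strict_nk = TRUE` for a CD56+CD3- gate.
#'
#' @param strict_nk Logical; require CD3 negativity for the NK gate.
#' @return Tibble with columns `phenotype`, `panel`, `pos`, `neg` (the
#'   latter two list-columns of marker names).
#' @export
default_gating_rules <- function(strict_nk = FALSE) {
  r <- function(phenotype, panel, pos, neg = character(0)) {
    tibble::tibble(phenotype = phenotype, panel = panel,
                   pos = list(pos), neg = list(neg))
  }
  nk <- if (strict_nk) r("CD56+", "P3", "CD56", "CD3") else r("CD56+", "P3", "CD56")
  dplyr::bind_rows(
    r("CD20+", "P1", "CD20"),
    r("CD11c+", "P1", "CD11c"),
    r("CD15+", "P1", "CD15"),
    r("CD3+", "P1", "CD3"),
    r("CD163+", "P1", "CD163"),
    r("CK+", "P1", "CK"),
    r("PD-1+", "P2", "PD-1"),
    r("CD8+", "P2", "CD8"),
    r("PD-L1+", "P2", "PD-L1"),
    r("Ki67+", "P2", "Ki67"),
    r("GrzB+", "P2", "GrzB"),
    r("CD8+PD-1+", "P2", c("CD8", "PD-1")),
    r("CK+", "P2", "CK"),
    r("CD3+", "P3", "CD3"),
    r("CD4+", "P3", "CD4"),
    r("CD8+", "P3", "CD8"),
    r("CD4+Foxp3+", "P3", c("CD4", "Foxp3")),
    nk,
    r("CK+", "P3", "CK")
  )
}

validate_rules <- function(rules) {
  pm <- panel_markers()
  ok <- rep(TRUE, nrow(rules))
  for (i in seq_len(nrow(rules))) {
    pos <- rules$pos[[i]]; neg <- rules$neg[[i]]
    if (length(intersect(pos, neg))) {
      stop("gating rule '", rules$phenotype[i],
           "' requires a marker both positive and negative", call. = FALSE)
    }
    avail <- pm[[rules$panel[i]]]
    if (is.null(avail) || !all(c(pos, neg) %in% avail)) {
      warning("gating rule '", rules$phenotype[i], "' references markers absent from panel ",
              rules$panel[i], "; rule skipped", call. = FALSE)
      ok[i] <- FALSE
    }
  }
  rules[ok, , drop = FALSE]
}

#' Derive phenotype labels from marker flags
#'
#' Each cell receives every phenotype whose rule it satisfies on its own
#' panel (multi-label: a CD3+CD8+ cell is both `CD3+` and `CD8+`). Gating
#' is deterministic, order-independent in the rule list, and idempotent.
#'
#' @param cells Cell tibble with marker columns.
#' @param rules Gating rules as from [default_gating_rules()].
#' @return `cells` with a `phenotypes` list-column of character vectors.
#' @export
gate_phenotypes <- function(cells, rules = default_gating_rules()) {
  cells <- tibble::as_tibble(cells)
  rules <- validate_rules(rules)
  rules <- rules[order(rules$phenotype, rules$panel), , drop = FALSE]
  n <- nrow(cells)
  hits <- matrix(FALSE, n, nrow(rules))
  for (i in seq_len(nrow(rules))) {
    idx <- cells$panel == rules$panel[i]
    for (m in rules$pos[[i]]) {
      idx <- idx & (m %in% names(cells)) &
        (if (m %in% names(cells)) cells[[m]] == 1L else FALSE)
    }
    for (m in rules$neg[[i]]) {
      idx <- idx & (if (m %in% names(cells)) cells[[m]] == 0L else TRUE)
    }
    hits[, i] <- idx
  }
  labs <- rules$phenotype
  # rows share few distinct hit patterns; derive the label set once per pattern
  pattern <- as.vector(hits %*% (2^(seq_len(ncol(hits)) - 1)))
  upat <- unique(pattern)
  lookup <- lapply(upat, function(p) unique(labs[hits[match(p, pattern), ]]))
  cells$phenotypes <- lookup[match(pattern, upat)]
  cells
}

#' Split PD-L1+ cells by cellular compartment
#'
#' Adds `PD-L1+CK+` (epithelial) or `PD-L1+CK-` (stromal/immune) to the
#' phenotype set of each PD-L1-positive Panel 2 cell, distinguishing
#' tumor-cell from myeloid/stromal PD-L1 expression.
#'
#' @param cells Gated cell tibble (Panel 2 cells carry `PD-L1` and `CK`).
#' @return `cells` with augmented `phenotypes`.
#' @export
split_pdl1_by_compartment <- function(cells) {
  if (!"phenotypes" %in% names(cells)) {
    stop("gate cells before splitting PD-L1 by compartment", call. = FALSE)
  }
  if (!all(c("PD-L1", "CK") %in% names(cells))) return(cells)
  pdl1 <- cells$panel == "P2" & cells[["PD-L1"]] == 1L
  lab <- ifelse(cells[["CK"]] == 1L, "PD-L1+CK+", "PD-L1+CK-")
  idx <- which(pdl1)
  cells$phenotypes[idx] <- lapply(idx, function(i) unique(c(cells$phenotypes[[i]], lab[i])))
  cells
}

# ---- Geometry GeoJSON ------------------------------------------------------

#' Write compartment geometry as GeoJSON
#'
#' One FeatureCollection with Polygon features tagged
#' `role` in `tissue`, `tumor`, `stroma`, `im_band`, `tc` and a LineString
#' feature with `role = "interface"`. Coordinates are micrometres with the
#' y axis increasing downward (image convention); `im_width_um` is stored
#' as a collection property.
#'
#' @param geometry A `mif_geometry`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "mif_geometry"))
  close_ring <- function(m) rbind(m, m[1, , drop = FALSE])
  feat_poly <- function(role, m) {
    list(type = "Feature", properties = list(role = role),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(close_ring(m), 1, as.numeric, simplify = FALSE)))))
  }
  feat_line <- function(role, m) {
    list(type = "Feature", properties = list(role = role),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(m, 1, as.numeric, simplify = FALSE))))
  }
  feats <- list(
    feat_poly("tissue", geometry$tissue),
    feat_poly("tumor", geometry$tumor),
    feat_line("interface", geometry$interface),
    feat_line("split_curve", geometry$split_curve),
    feat_poly("im_band", geometry$im_band),
    feat_poly("tc", geometry$tc)
  )
  if (!is.null(geometry$stroma)) feats <- c(feats, list(feat_poly("stroma", geometry$stroma)))
  fc <- list(type = "FeatureCollection",
             properties = list(units = "um", y_axis = "down",
                               im_width_um = geometry$im_width_um),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read compartment geometry from GeoJSON
#'
#' Inverse of [write_geometry()]. If only `tumor` and `interface` features
#' are present, the IM band and TC are re-derived via [derive_regions()].
#'
#' @param path GeoJSON file.
#' @return A `mif_geometry`.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path, call. = FALSE)
  fc <- jsonlite::read_json(path)
  get_coords <- function(g) {
    cc <- if (g$type == "Polygon") g$coordinates[[1]] else g$coordinates
    m <- do.call(rbind, lapply(cc, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    if (g$type == "Polygon" && nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    m
  }
  parts <- list()
  for (f in fc$features) {
    parts[[f$properties$role]] <- get_coords(f$geometry)
  }
  width <- fc$properties$im_width_um
  if (is.null(width)) width <- 1000
  if (is.null(parts$tumor) || is.null(parts$interface)) {
    stop("GeoJSON must contain 'tumor' and 'interface' features", call. = FALSE)
  }
  derive_regions(parts$tumor, parts$interface, width,
                 tissue = parts$tissue, split_curve = parts$split_curve,
                 stroma = parts$stroma)
}
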