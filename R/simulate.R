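# Synthetic mIF cohort generator.
#
# Emulates compartment-resolved marked point patterns: per-phenotype
# homogeneous Poisson or Thomas-cluster processes with separate TC and IM
# intensities (cells/mm2), cross-phenotype co-clustering (offspring seeded
# at another phenotype's cluster parents), lognormal between-sample
# intensity heterogeneity, planted high/low CD8/PD-L1 infiltration groups,
# and latent-factor control of the Pearson correlation between two
# phenotypes' log densities. One integer seed fully determines a cohort.

#' Specify a phenotype's generating intensity
#'
#' @param phenotype Phenotype label (must have a default gating rule or an
#'   entry in the marker map, e.g. `"CD8+"`, `"PD-L1+CK+"`).
#' @param panel Staining panel (`"P1"`, `"P2"`, `"P3"`).
#' @param lambda_tc,lambda_im Intensities in cells/mm2 (finite, >= 0).
#' @param process `"poisson"` (homogeneous) or `"thomas"` (clustered).
#' @param cluster_parent_rate Parents/mm2 (> 0 for Thomas).
#' @param cluster_sd_um Offspring dispersion SD in um (> 0 for Thomas).
#' @param coupled_to Optional phenotype label whose Thomas parents seed
#'   this phenotype's clusters (co-clustering across serial sections).
#' @return One-row tibble.
#' @export
phenotype_intensity <- function(phenotype, panel, lambda_tc, lambda_im,
                                process = c("poisson", "thomas"),
                                cluster_parent_rate = 0, cluster_sd_um = 0,
                                coupled_to = NA_character_) {
  process <- match.arg(process)
  if (!all(is.finite(c(lambda_tc, lambda_im))) || lambda_tc < 0 || lambda_im < 0) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (process == "thomas" && (cluster_parent_rate <= 0 || cluster_sd_um <= 0)) {
    stop("thomas process needs cluster_parent_rate > 0 and cluster_sd_um > 0",
         call. = FALSE)
  }
  tibble::tibble(phenotype = phenotype, panel = panel,
                 lambda_tc = lambda_tc, lambda_im = lambda_im,
                 process = process, cluster_parent_rate = cluster_parent_rate,
                 cluster_sd_um = cluster_sd_um, coupled_to = coupled_to)
}

# phenotype label -> defining positive markers (everything else negative)
marker_map <- function() {
  list(
    "CD20+" = "CD20", "CD11c+" = "CD11c", "CD15+" = "CD15", "CD3+" = "CD3",
    "CD163+" = "CD163", "CK+" = "CK", "PD-1+" = "PD-1", "CD8+" = "CD8",
    "PD-L1+" = "PD-L1", "Ki67+" = "Ki67", "GrzB+" = "GrzB",
    "CD8+PD-1+" = c("CD8", "PD-1"), "CD4+" = "CD4",
    "CD4+Foxp3+" = c("CD4", "Foxp3"), "CD56+" = "CD56",
    "PD-L1+CK+" = c("PD-L1", "CK"), "PD-L1+CK-" = "PD-L1"
  )
}

# Uniform rejection sampling of n points in the region labelled `region`.
sample_in_region <- function(n, geometry, region) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  poly <- if (region == "IM") geometry$im_band else geometry$tc
  bb <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
  out_x <- numeric(0); out_y <- numeric(0)
  guard <- 0
  while (length(out_x) < n && guard < 1000) {
    m <- max(2 * (n - length(out_x)), 100)
    px <- stats::runif(m, bb[1], bb[3]); py <- stats::runif(m, bb[2], bb[4])
    keep <- region_membership(px, py, geometry) == region
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
    guard <- guard + 1
  }
  if (length(out_x) < n) stop("rejection sampling failed; degenerate region", call. = FALSE)
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

region_area_mm2 <- function(geometry, region) {
  unname(attr(geometry, "areas_mm2")[region])
}

#' Simulate one sample's cell table
#'
#' For a homogeneous Poisson spec, the cell count in region R is Poisson
#' with mean `lambda_R * area(R)` and positions are uniform in R. For a
#' Thomas spec, Poisson parents at `cluster_parent_rate` carry Poisson
#' offspring (mean `lambda / cluster_parent_rate`) displaced by isotropic
#' Gaussian noise; `coupled_to` re-uses another phenotype's parents so the
#' two phenotypes co-cluster. Marker flags are set for each phenotype's
#' defining markers only (no spillover).
#'
#' @param specs Tibble of [phenotype_intensity()] rows. A phenotype named
#'   in `coupled_to` must appear earlier in the list with a Thomas process.
#' @param geometry A `mif_geometry` with derived IM/TC.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return Cell tibble: `sample_id`, `panel`, `x_um`, `y_um`, 14 marker
#'   columns, `true_phenotype`, `true_region`.
#' @export
simulate_sample <- function(specs, geometry, seed = 1L, sample_id = "sample_1") {
  withr::with_seed(as.integer(seed),
                   simulate_sample_rng(specs, geometry, sample_id))
}

simulate_sample_rng <- function(specs, geometry, sample_id) {
  specs <- tibble::as_tibble(specs)
  known <- specs$phenotype
  bad <- !is.na(specs$coupled_to) &
    !(specs$coupled_to %in% known &
        match(specs$coupled_to, known) < seq_len(nrow(specs)))
  if (any(bad)) {
    stop("coupled_to refers to a phenotype not simulated earlier: ",
         paste(specs$coupled_to[bad], collapse = ", "), call. = FALSE)
  }
  mm <- marker_map()
  unknown <- setdiff(specs$phenotype, names(mm))
  if (length(unknown)) {
    stop("no marker definition for phenotype(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  parents_cache <- list()
  rows <- vector("list", nrow(specs) * 2)
  ri <- 0
  # Batch the Poisson phenotypes per region: draw each count from its own
  # Poisson law, then place all points with a single rejection run (iid
  # uniform positions are exchangeable across phenotypes).
  pois_pts <- list()
  for (reg in c("TC", "IM")) {
    idx <- which(specs$process == "poisson")
    area <- region_area_mm2(geometry, reg)
    if (length(idx) == 0 || area <= 0) next
    lam <- if (reg == "TC") specs$lambda_tc[idx] else specs$lambda_im[idx]
    ns <- stats::rpois(length(idx), lam * area)
    pts <- sample_in_region(sum(ns), geometry, reg)
    splits <- rep.int(seq_along(idx), ns)
    for (k in seq_along(idx)) {
      pois_pts[[paste(idx[k], reg)]] <- pts[splits == k, , drop = FALSE]
    }
  }
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    for (reg in c("TC", "IM")) {
      lam <- if (reg == "TC") sp$lambda_tc else sp$lambda_im
      area <- region_area_mm2(geometry, reg)
      if (lam <= 0 || area <= 0) next
      if (sp$process == "poisson") {
        pts <- pois_pts[[paste(i, reg)]]
      } else {
        key <- paste(if (!is.na(sp$coupled_to)) sp$coupled_to else sp$phenotype, reg)
        if (!is.na(sp$coupled_to)) {
          par_pts <- parents_cache[[key]]
          if (is.null(par_pts)) {
            stop("coupled_to phenotype '", sp$coupled_to,
                 "' has no cached cluster parents in region ", reg, call. = FALSE)
          }
        } else {
          n_par <- stats::rpois(1, sp$cluster_parent_rate * area)
          par_pts <- sample_in_region(n_par, geometry, reg)
          parents_cache[[key]] <- par_pts
        }
        n_par <- nrow(par_pts)
        if (n_par == 0) next
        kappa <- if (!is.na(sp$coupled_to)) n_par / area else sp$cluster_parent_rate
        mu <- lam / kappa
        n_off <- stats::rpois(n_par, mu)
        if (sum(n_off) == 0) next
        px <- rep(par_pts[, 1], n_off); py <- rep(par_pts[, 2], n_off)
        pts <- cbind(x = px + stats::rnorm(length(px), 0, sp$cluster_sd_um),
                     y = py + stats::rnorm(length(py), 0, sp$cluster_sd_um))
        # keep offspring inside the tissue
        tis <- geometry$tissue
        keep <- pts[, 1] >= min(tis[, 1]) & pts[, 1] <= max(tis[, 1]) &
          pts[, 2] >= min(tis[, 2]) & pts[, 2] <= max(tis[, 2])
        pts <- pts[keep, , drop = FALSE]
      }
      if (nrow(pts) == 0) next
      ri <- ri + 1
      rows[[ri]] <- tibble::tibble(
        sample_id = sample_id, panel = sp$panel,
        x_um = pts[, 1], y_um = pts[, 2],
        true_phenotype = sp$phenotype, true_region = reg
      )
    }
  }
  cells <- dplyr::bind_rows(rows[seq_len(ri)])
  if (nrow(cells) == 0) {
    cells <- tibble::tibble(sample_id = character(0), panel = character(0),
                            x_um = numeric(0), y_um = numeric(0),
                            true_phenotype = character(0), true_region = character(0))
  }
  # marker flags: defining markers positive, all others negative
  for (m in all_markers()) cells[[m]] <- 0L
  for (ph in unique(cells$true_phenotype)) {
    idx <- cells$true_phenotype == ph
    for (m in mm[[ph]]) cells[[m]][idx] <- 1L
  }
  lead <- c("sample_id", "panel", "x_um", "y_um")
  cells[, c(lead, all_markers(), "true_phenotype", "true_region")]
}

#' Specify a synthetic cohort
#'
#' @param n_samples Number of samples (>= 2; cohort-relative cutoffs are
#'   undefined below that).
#' @param groups Tibble `sample_id`, `group` (`planted_high`/`planted_low`),
#'   `msi` (`MSI-H`/`MSS`) covering all samples; default emulates a
#'   15-sample cohort with 6 high (5 MSI-H, 1 MSS) and 9 low (3 MSI-H,
#'   6 MSS).
#' @param intensities Tibble of [phenotype_intensity()] rows: the
#'   planted-low baseline.
#' @param high_multipliers Named numeric vector: per-phenotype fold change
#'   applied to both regions' intensities in the planted-high group.
#' @param sigma_log Between-sample lognormal SD on the log-intensity scale
#'   (mean-preserving), default 0.35.
#' @param correlation_targets Tibble `phenotype_a`, `phenotype_b`,
#'   `region`, `r` (|r| < 1): target Pearson correlation of the two
#'   phenotypes' log intensities in that region, induced by a shared
#'   latent factor.
#' @param interface [interface_spec()] for the per-sample geometry.
#' @param im_width_um IM band width (default 1000).
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 15,
                        groups = default_groups(n_samples),
                        intensities = default_intensities(),
                        high_multipliers = default_high_multipliers(),
                        sigma_log = 0.35,
                        correlation_targets = NULL,
                        interface = interface_spec(5, "sinusoidal",
                                                   amplitude_mm = 0.35,
                                                   tissue_extent_mm = c(6, 4)),
                        im_width_um = 1000,
                        seed = 1L) {
  if (n_samples < 2) {
    stop("a cohort needs at least 2 samples (cohort cutoffs undefined otherwise)",
         call. = FALSE)
  }
  groups <- tibble::as_tibble(groups)
  if (nrow(groups) != n_samples || anyNA(groups$group)) {
    stop("group assignments must cover every sample", call. = FALSE)
  }
  if (!is.null(correlation_targets)) {
    correlation_targets <- tibble::as_tibble(correlation_targets)
    if (any(abs(correlation_targets$r) >= 1)) {
      stop("|target r| must be < 1", call. = FALSE)
    }
  }
  structure(
    list(n_samples = n_samples, groups = groups, intensities = intensities,
         high_multipliers = high_multipliers, sigma_log = sigma_log,
         correlation_targets = correlation_targets, interface = interface,
         im_width_um = im_width_um, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_groups <- function(n_samples = 15) {
  if (n_samples == 15) {
    grp <- c(rep("planted_high", 6), rep("planted_low", 9))
    msi <- c(rep("MSI-H", 5), "MSS", rep("MSI-H", 3), rep("MSS", 6))
  } else {
    n_high <- max(1, round(n_samples * 0.4))
    grp <- c(rep("planted_high", n_high), rep("planted_low", n_samples - n_high))
    msi <- rep(c("MSI-H", "MSS"), length.out = n_samples)
  }
  tibble::tibble(sample_id = sprintf("S%02d", seq_len(n_samples)),
                 group = grp, msi = msi)
}

#' @rdname cohort_spec
#' @export
default_intensities <- function() {
  dplyr::bind_rows(
    phenotype_intensity("CK+", "P1", 2500, 1200),
    phenotype_intensity("CD20+", "P1", 60, 150),
    phenotype_intensity("CD11c+", "P1", 80, 120),
    phenotype_intensity("CD15+", "P1", 50, 80),
    phenotype_intensity("CD3+", "P1", 400, 700),
    phenotype_intensity("CD163+", "P1", 150, 400, process = "thomas",
                        cluster_parent_rate = 3, cluster_sd_um = 60),
    phenotype_intensity("CK+", "P2", 2500, 1200),
    phenotype_intensity("PD-1+", "P2", 100, 200),
    phenotype_intensity("CD8+", "P2", 250, 450),
    phenotype_intensity("CD8+PD-1+", "P2", 60, 130),
    phenotype_intensity("Ki67+", "P2", 300, 250),
    phenotype_intensity("GrzB+", "P2", 70, 100),
    phenotype_intensity("PD-L1+", "P2", 80, 220),
    phenotype_intensity("PD-L1+CK+", "P2", 15, 10),
    phenotype_intensity("CK+", "P3", 2500, 1200),
    phenotype_intensity("CD3+", "P3", 400, 700),
    phenotype_intensity("CD4+", "P3", 200, 350),
    phenotype_intensity("CD8+", "P3", 250, 450),
    phenotype_intensity("CD4+Foxp3+", "P3", 50, 90),
    phenotype_intensity("CD56+", "P3", 30, 80)
  )
}

#' @rdname cohort_spec
#' @export
default_high_multipliers <- function() {
  c("CD8+" = 3, "PD-L1+" = 3, "PD-1+" = 2.5, "CD8+PD-1+" = 2.5,
    "CD20+" = 2, "CD3+" = 2, "CD56+" = 2.2)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Each sample gets its own geometry (same interface spec, seeded phase),
#' per-phenotype intensities drawn lognormally (mean-preserving,
#' `sigma_log` on the log scale) around its group's means, correlated
#' across samples for targeted phenotype pairs via a shared latent
#' factor, and a simulated cell table. Reproducible bit-for-bit from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `mif_cohort` list: `cells` (all samples bound), `geometries`
#'   (named list), `truth` (sample, group, msi, per-phenotype/region
#'   generating intensities), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    ints <- tibble::as_tibble(spec$intensities)
    # per-sample log-scale z draws, one per phenotype x region
    key <- paste(rep(ints$phenotype, 2), rep(ints$panel, 2),
                 rep(c("TC", "IM"), each = nrow(ints)))
    z <- matrix(stats::rnorm(n * length(key)), n, length(key),
                dimnames = list(spec$groups$sample_id, key))
    if (!is.null(spec$correlation_targets)) {
      for (ti in seq_len(nrow(spec$correlation_targets))) {
        tg <- spec$correlation_targets[ti, ]
        z0 <- stats::rnorm(n)
        for (ph in c(tg$phenotype_a, tg$phenotype_b)) {
          pan <- ints$panel[ints$phenotype == ph][1]
          k <- paste(ph, pan, tg$region)
          if (!k %in% key) stop("correlation target names unknown phenotype/region: ", k,
                                call. = FALSE)
          z[, k] <- sqrt(abs(tg$r)) * z0 * sign(1) +
            sqrt(1 - abs(tg$r)) * stats::rnorm(n)
          if (tg$r < 0 && ph == tg$phenotype_b) z[, k] <- -z[, k]
        }
      }
    }
    sig <- spec$sigma_log
    cells <- vector("list", n)
    geoms <- vector("list", n)
    truth <- vector("list", n)
    for (s in seq_len(n)) {
      sid <- spec$groups$sample_id[s]
      g <- make_geometry_rng(spec$interface, spec$im_width_um)
      si <- ints
      mult <- rep(1, nrow(si))
      if (spec$groups$group[s] == "planted_high") {
        hit <- match(si$phenotype, names(spec$high_multipliers))
        mult <- ifelse(is.na(hit), 1, spec$high_multipliers[hit])
      }
      ztc <- z[s, paste(si$phenotype, si$panel, "TC")]
      zim <- z[s, paste(si$phenotype, si$panel, "IM")]
      si$lambda_tc <- si$lambda_tc * mult * exp(sig * ztc - sig^2 / 2)
      si$lambda_im <- si$lambda_im * mult * exp(sig * zim - sig^2 / 2)
      cells[[s]] <- simulate_sample_rng(si, g, sid)
      geoms[[s]] <- g
      truth[[s]] <- tibble::tibble(
        sample_id = sid, group = spec$groups$group[s], msi = spec$groups$msi[s],
        phenotype = si$phenotype, panel = si$panel,
        lambda_tc = si$lambda_tc, lambda_im = si$lambda_im
      )
    }
    names(geoms) <- spec$groups$sample_id
    structure(
      list(cells = dplyr::bind_rows(cells), geometries = geoms,
           truth = dplyr::bind_rows(truth), spec = spec),
      class = "mif_cohort"
    )
  })
}

#' @export
print.mif_cohort <- function(x, ...) {
  cat("<mif_cohort>", x$spec$n_samples, "samples,",
      nrow(x$cells), "cells,",
      length(unique(x$cells$panel)), "panels; seed", x$spec$seed, "\n")
  invisible(x)
}

#' Write a cohort's artifacts to disk
#'
#' Cell table CSV, per-sample geometry GeoJSON, and the ground-truth CSV
#' (sample, group, MSI, per-phenotype generating intensities).
#'
#' @param cohort A `mif_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mif_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cells = file.path(dir, "cells.csv"),
             truth = file.path(dir, "truth.csv"))
  write_cell_table(cohort$cells, paths["cells"])
  readr::write_csv(cohort$truth, paths["truth"], progress = FALSE)
  for (sid in names(cohort$geometries)) {
    p <- file.path(dir, paste0("geometry_", sid, ".geojson"))
    write_geometry(cohort$geometries[[sid]], p)
    paths[paste0("geometry_", sid)] <- p
  }
  invisible(paths)
}
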