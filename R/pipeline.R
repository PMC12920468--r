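# End-to-end pipeline: simulate (or read) -> gate -> regions -> fields ->
# densities -> proximity -> scores -> statistics, with every stage's
# outputs written to disk and a JSON manifest (config echo, per-stage row
# counts, file checksums). Rerunning with the same config and seed is
# byte-identical.

#' Pipeline configuration
#'
#' Houses the method constants: IM band width (1 mm), field size (1 mm2),
#' up to 5 fields per region, proximity radius (20 um), median (50th
#' percentile) dichotomization.
#'
#' @param cells_csv,geometry_files Input paths (ignored in simulate mode).
#' @param simulate `NULL`, or a [cohort_spec()] to generate the inputs.
#' @param out_dir Output directory.
#' @param im_width_um IM band total width (um, > 0).
#' @param field_side_um Analysis-field side (um, > 0).
#' @param n_fields Maximum fields per region (>= 1).
#' @param proximity_radius_um Proximity radius (um, > 0).
#' @param proximity_metric `"engaged_density"` or `"pair_density"`.
#' @param percentile Dichotomization percentile in (0, 100).
#' @param seed Integer seed for field tie-breaking (and simulation when
#'   `simulate` carries no seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cells_csv = NULL, geometry_files = NULL,
                            simulate = NULL, out_dir = tempfile("mif_run_"),
                            im_width_um = 1000, field_side_um = 1000,
                            n_fields = 5, proximity_radius_um = 20,
                            proximity_metric = c("engaged_density", "pair_density"),
                            percentile = 50, seed = 1L) {
  proximity_metric <- match.arg(proximity_metric)
  stopifnot(im_width_um > 0, field_side_um > 0, n_fields >= 1,
            proximity_radius_um > 0, percentile > 0, percentile < 100)
  structure(
    list(cells_csv = cells_csv, geometry_files = geometry_files,
         simulate = simulate, out_dir = out_dir,
         im_width_um = im_width_um, field_side_um = field_side_um,
         n_fields = n_fields, proximity_radius_um = proximity_radius_um,
         proximity_metric = proximity_metric, percentile = percentile,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full contexture pipeline
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly written as
#'   `manifest.json` in `out_dir` together with every stage's CSV/GeoJSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "mifcontext",
    version = as.character(utils::packageVersion("mifcontext")),
    seed = config$seed,
    config = config[setdiff(names(config), c("simulate"))],
    stages = list(), files = list(), warnings = character(0)
  )
  stage <- "init"
  wlog <- character(0)
  note <- function(...) wlog <<- c(wlog, paste0(...))
  run <- function(name, expr) {
    stage <<- name
    withCallingHandlers(expr, warning = function(w) {
      note(name, ": ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  result <- tryCatch({
    # --- inputs ---
    if (!is.null(config$simulate)) {
      cohort <- run("simulate", simulate_cohort(config$simulate))
      cells <- cohort$cells
      geoms <- cohort$geometries
      run("simulate", write_cohort(cohort, file.path(config$out_dir, "inputs")))
    } else {
      cells <- run("read_cells", read_cell_table(config$cells_csv))
      geoms <- run("regions", {
        if (is.null(config$geometry_files)) stop("no geometry files configured")
        gl <- lapply(config$geometry_files, read_geometry)
        nm <- names(config$geometry_files)
        if (is.null(nm)) nm <- unique(cells$sample_id)[seq_along(gl)]
        stats::setNames(gl, nm)
      })
    }
    manifest$stages$input <- list(n_cells = nrow(cells), n_samples = length(geoms))

    # --- gate ---
    cells <- run("gate", gate_phenotypes(cells) |> split_pdl1_by_compartment())
    manifest$stages$gate <- list(n_cells = nrow(cells))

    # --- regions + fields ---
    fields <- run("fields", purrr::map_dfr(names(geoms), function(sid) {
      g <- geoms[[sid]]
      dplyr::bind_rows(
        select_fields(g, "IM", config$n_fields, config$field_side_um, config$seed),
        select_fields(g, "TC", config$n_fields, config$field_side_um, config$seed)
      ) |> dplyr::mutate(sample_id = sid, .before = 1)
    }))
    cells <- run("regions", purrr::map_dfr(names(geoms), function(sid) {
      assign_regions(cells[cells$sample_id == sid, , drop = FALSE], geoms[[sid]])
    }))
    manifest$stages$regions <- list(n_fields = nrow(fields))

    # --- densities ---
    dens <- run("densities", compute_densities(cells, fields))
    manifest$stages$densities <- list(n_records = nrow(dens))

    # --- proximity ---
    prox <- run("proximity", proximity_table(
      cells, fields, "CD8+", "PD-L1+", config$proximity_radius_um))
    manifest$stages$proximity <- list(n_records = nrow(prox))

    # --- scores ---
    have <- dplyr::distinct(dens, .data$panel, .data$phenotype)
    iscore <- NULL
    if (any(have$phenotype == "CD3+") && any(have$phenotype == "CD8+")) {
      imat <- run("score", immunoscore_matrix(dens))
      iscore <- run("score", suppressMessages(immunoscore(imat, config$percentile)))
    } else {
      note("score: CD3+ or CD8+ densities unavailable; Immunoscore skipped")
    }
    cmat <- run("score", cd8_pdl1_matrix(dens, prox, config$proximity_metric))
    cscore <- run("score", cd8_pdl1_score(cmat, config$percentile))
    manifest$stages$score <- list(
      immunoscore = if (is.null(iscore)) 0L else nrow(iscore),
      cd8_pdl1 = nrow(cscore))

    # --- statistics ---
    stats_out <- run("stats", {
      paired <- purrr::map_dfr(c("PD-L1+", "CD163+", "CD56+", "PD-1+", "CD8+PD-1+"),
                               function(ph) {
        tryCatch(paired_region_compare(dens, ph), error = function(e) NULL)
      })
      panel <- association_panel(dens, cscore)
      strat <- suppressWarnings(region_stratified_panel(dens, cscore))
      list(paired = paired, panel = panel, strat = strat)
    })
    manifest$stages$stats <- list(paired = nrow(stats_out$paired),
                                  panel_rows = nrow(stats_out$panel))

    # --- write outputs ---
    run("write", {
      out <- function(x, f) {
        p <- file.path(config$out_dir, f)
        readr::write_csv(x, p, progress = FALSE)
        p
      }
      flat_scores <- function(s) {
        dplyr::mutate(s, bits = vapply(bits, paste, "", collapse = ""),
                      category = as.character(category))
      }
      files <- c(
        out(write_flat_cells(cells), "cells_gated.csv"),
        out(fields, "fields.csv"),
        out(dens, "densities.csv"),
        out(prox, "proximity.csv"),
        if (!is.null(iscore)) out(flat_scores(iscore), "scores_immunoscore.csv"),
        out(flat_scores(cscore), "scores_cd8_pdl1.csv"),
        out(stats_out$paired, "stats_paired.csv"),
        out(stats_out$panel, "stats_association_panel.csv"),
        out(stats_out$strat, "stats_region_panels.csv")
      )
      writeLines(format_panel_md(stats_out$panel),
                 file.path(config$out_dir, "association_panel.md"))
      files <- c(files, file.path(config$out_dir, "association_panel.md"))
      jsonlite::write_json(
        list(immunoscore = if (!is.null(iscore)) attr(iscore, "cutoffs"),
             cd8_pdl1 = attr(cscore, "cutoffs")),
        file.path(config$out_dir, "cutoffs.json"), auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(config$out_dir, "cutoffs.json"))
      files
    })
    list(cells = cells, fields = fields, densities = dens, proximity = prox,
         immunoscore = iscore, cd8_pdl1 = cscore, stats = stats_out)
  }, error = function(e) {
    manifest$error <- list(stage = stage, message = conditionMessage(e))
    manifest$warnings <- wlog
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$warnings <- wlog
  outs <- setdiff(list.files(config$out_dir, recursive = TRUE, full.names = TRUE),
                  file.path(config$out_dir, "manifest.json"))
  manifest$files <- lapply(stats::setNames(outs, basename(outs)),
                           function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(manifest, list(results = result)))
}

write_flat_cells <- function(cells) {
  flat <- cells
  flat$phenotypes <- vapply(flat$phenotypes, paste, "", collapse = ";")
  flat$region <- as.character(flat$region)
  flat
}
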