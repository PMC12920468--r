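# Synthetic cohort generator: calibration, clustering, coupling,
# reproducibility.

test_that("intensity and cohort specs validate their invariants", {
  expect_error(phenotype_intensity("CD8+", "P2", -1, 10), "non-negative")
  expect_error(phenotype_intensity("CD8+", "P2", 10, Inf), "non-negative")
  expect_error(phenotype_intensity("CD8+", "P2", 10, 10, process = "thomas"),
               "cluster_parent_rate")
  expect_error(cohort_spec(n_samples = 1), "at least 2")
  expect_error(
    cohort_spec(correlation_targets = tibble::tibble(
      phenotype_a = "PD-L1+", phenotype_b = "CD163+", region = "IM", r = 1)),
    "< 1")
})

test_that("region counts are Poisson with mean lambda x area", {
  g <- straight_geom(4, 3)
  a_tc <- attr(g, "areas_mm2")[["TC"]]
  spec <- phenotype_intensity("CD8+", "P2", lambda_tc = 100, lambda_im = 0)
  counts <- vapply(1:500, function(s) {
    nrow(simulate_sample(spec, g, seed = s))
  }, numeric(1))
  mu <- 100 * a_tc
  se <- sqrt(mu / 500)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # Poisson calibration: variance/mean near 1
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.25)
})

test_that("zero intensity regions stay empty and cells stay in tissue", {
  g <- straight_geom(4, 3)
  spec <- phenotype_intensity("CD8+", "P2", lambda_tc = 0, lambda_im = 150)
  cells <- simulate_sample(spec, g, seed = 5)
  expect_true(all(cells$true_region == "IM"))
  expect_true(all(cells$x_um >= 0 & cells$x_um <= 4000))
  expect_true(all(cells$y_um >= 0 & cells$y_um <= 3000))
  # simulated region labels agree with the assignment rule
  lab <- assign_regions(cells, g)
  expect_equal(as.character(lab$region), cells$true_region)
})

test_that("marker flags encode exactly the defining markers", {
  g <- straight_geom(4, 3)
  specs <- dplyr::bind_rows(
    phenotype_intensity("CD8+PD-1+", "P2", 50, 50),
    phenotype_intensity("CD4+Foxp3+", "P3", 50, 50)
  )
  cells <- simulate_sample(specs, g, seed = 2)
  ex <- cells[cells$true_phenotype == "CD8+PD-1+", ]
  expect_true(all(ex$CD8 == 1L & ex$`PD-1` == 1L))
  expect_true(all(ex$CD4 == 0L & ex$CK == 0L))
  # gating recovers the planted phenotype (no spillover by construction)
  gated <- gate_phenotypes(cells)
  treg <- gated[gated$true_phenotype == "CD4+Foxp3+", ]
  expect_true(all(vapply(treg$phenotypes, function(p) "CD4+Foxp3+" %in% p, TRUE)))
})

test_that("coupled Thomas offspring cluster around their parent phenotype", {
  g <- straight_geom(4, 3)
  specs <- dplyr::bind_rows(
    phenotype_intensity("CD163+", "P1", 150, 300, process = "thomas",
                        cluster_parent_rate = 3, cluster_sd_um = 40),
    phenotype_intensity("PD-L1+", "P2", 100, 200, process = "thomas",
                        cluster_parent_rate = 3, cluster_sd_um = 40,
                        coupled_to = "CD163+")
  )
  nn_dist <- function(cells) {
    cd163 <- cells[cells$true_phenotype == "CD163+", ]
    pdl1 <- cells[cells$true_phenotype == "PD-L1+", ]
    mean(vapply(seq_len(nrow(pdl1)), function(i) {
      min(sqrt((cd163$x_um - pdl1$x_um[i])^2 + (cd163$y_um - pdl1$y_um[i])^2))
    }, numeric(1)))
  }
  pois <- dplyr::mutate(specs, process = "poisson", coupled_to = NA_character_)
  d_coupled <- vapply(1:5, function(s) nn_dist(simulate_sample(specs, g, s)),
                      numeric(1))
  d_pois <- vapply(1:5, function(s) nn_dist(simulate_sample(pois, g, s + 100)),
                   numeric(1))
  expect_lt(mean(d_coupled), mean(d_pois))
  # coupling to a phenotype that is not simulated earlier is rejected
  bad <- specs[2, ]
  expect_error(simulate_sample(bad, g, 1), "not simulated earlier")
  expect_error(
    simulate_sample(dplyr::bind_rows(
      phenotype_intensity("GrzB+", "P2", 10, 10),
      phenotype_intensity("Mystery+", "P2", 10, 10)), g, 1),
    "no marker definition")
})

test_that("a cohort is reproducible bit for bit from its seed", {
  spec <- cohort_spec(n_samples = 4, groups = default_groups(4),
                      intensities = cd8_pdl1_specs(),
                      interface = interface_spec(3, "straight",
                                                 tissue_extent_mm = c(3, 2)),
                      seed = 99)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$cells, c2$cells)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(cohort_spec(n_samples = 4, groups = default_groups(4),
                                    intensities = cd8_pdl1_specs(),
                                    interface = spec$interface, seed = 100))
  expect_false(identical(c1$cells, c3$cells))
  # truth table covers every sample x phenotype with generating intensities
  expect_equal(nrow(c1$truth), 4 * nrow(cd8_pdl1_specs()))
  expect_true(all(c1$truth$lambda_tc > 0))
})

test_that("latent-factor construction hits the target log-density correlation", {
  trg <- tibble::tibble(phenotype_a = "PD-L1+", phenotype_b = "CD163+",
                        region = "IM", r = 0.8)
  spec <- cohort_spec(
    n_samples = 60, groups = default_groups(60),
    intensities = dplyr::bind_rows(
      phenotype_intensity("PD-L1+", "P2", 80, 220),
      phenotype_intensity("CD163+", "P1", 150, 400)
    ),
    high_multipliers = c("CD8+" = 1),  # no group shift for this check
    correlation_targets = trg,
    interface = interface_spec(3, "straight", tissue_extent_mm = c(3, 2)),
    seed = 17)
  coh <- simulate_cohort(spec)
  lam <- tidyr::pivot_wider(coh$truth[, c("sample_id", "phenotype", "lambda_im")],
                            names_from = "phenotype", values_from = "lambda_im")
  r_hat <- cor(log(lam$`PD-L1+`), log(lam$`CD163+`))
  ci <- stats::cor.test(log(lam$`PD-L1+`), log(lam$`CD163+`))$conf.int
  expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
  expect_gt(r_hat, 0.6)
  # untargeted region stays unconstrained (independent draws)
  lam_tc <- tidyr::pivot_wider(coh$truth[, c("sample_id", "phenotype", "lambda_tc")],
                               names_from = "phenotype", values_from = "lambda_tc")
  expect_lt(abs(cor(log(lam_tc$`PD-L1+`), log(lam_tc$`CD163+`))), 0.45)
})

test_that("cohort artifacts write to plain-text files", {
  spec <- cohort_spec(n_samples = 2, groups = default_groups(2),
                      intensities = cd8_pdl1_specs(c(50, 80), c(30, 60)),
                      interface = interface_spec(2, "straight",
                                                 tissue_extent_mm = c(2, 1.5)),
                      seed = 3)
  coh <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cell_table(paths[["cells"]])
  expect_equal(nrow(back), nrow(coh$cells))
  g <- read_geometry(paths[["geometry_S01"]])
  expect_s3_class(g, "mif_geometry")
})
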