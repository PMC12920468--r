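# Compartment geometry: tissue splitting, IM band construction, region
# assignment, field placement, density computation.

test_that("a straight interface splits the tissue with area conserved", {
  g <- make_geometry(interface_spec(5, "straight", tissue_extent_mm = c(6, 4)),
                     seed = 1)
  a_tumor <- polygon_area(g$tumor) / 1e6
  a_stroma <- polygon_area(g$stroma) / 1e6
  expect_equal(a_tumor + a_stroma, 24, tolerance = 1e-9)
  expect_equal(a_tumor, 12, tolerance = 1e-9)
})

test_that("geometry construction is deterministic for fixed spec and seed", {
  sp <- interface_spec(5, "sinusoidal", amplitude_mm = 0.4)
  g1 <- make_geometry(sp, seed = 11)
  g2 <- make_geometry(sp, seed = 11)
  expect_identical(g1$interface, g2$interface)
  expect_identical(g1$im_band, g2$im_band)
  expect_identical(g1$tc, g2$tc)
  g3 <- make_geometry(sp, seed = 12)
  expect_false(isTRUE(all.equal(g1$interface, g3$interface)))
})

test_that("sinusoidal interface arc length matches numeric integration", {
  sp <- interface_spec(5, "sinusoidal", amplitude_mm = 0.5)
  g <- make_geometry(sp, seed = 3)
  # numeric arc-length oracle: integrate sqrt(1 + f'(x)^2) over the chord
  A <- 500; k <- 2 * pi / 5000
  arc <- stats::integrate(function(x) sqrt(1 + (A * k * cos(k * x + g$phase))^2),
                          0, 5000, rel.tol = 1e-10)$value
  expect_gte(polyline_length(g$interface), 5000)  # >= straight chord
  expect_equal(polyline_length(g$interface), arc, tolerance = 1e-3)
})

test_that("degenerate tissue extents are rejected with a clear diagnostic", {
  expect_error(interface_spec(5, tissue_extent_mm = c(0, 4)), "degenerate")
  expect_error(interface_spec(0), "positive")
})

test_that("straight IM band is a 1 mm wide rectangle with flat caps", {
  iface <- cbind(c(500, 5500), c(2000, 2000))
  band <- build_im_band(iface, 1000)
  expect_equal(polygon_area(band) / 1e6, 5, tolerance = 1e-12)
  expect_equal(diff(range(band[, 2])), 1000)   # perpendicular width
  expect_equal(range(band[, 1]), c(500, 5500)) # no extension beyond caps
  expect_error(build_im_band(iface, 0), "positive")
  expect_error(build_im_band(iface, -5), "positive")
})

test_that("sinusoidal band area matches arc length x width within 1%", {
  g <- make_geometry(interface_spec(6, "sinusoidal", amplitude_mm = 0.4,
                                    tissue_extent_mm = c(6, 4)), seed = 5)
  band <- build_im_band(g$interface, 1000)
  expected <- polyline_length(g$interface) * 1000
  expect_equal(polygon_area(band), expected, tolerance = 0.01)
  # independent fine-grid membership oracle for the same area
  xs <- seq(0, 6000, by = 20); ys <- seq(0, 4000, by = 20)
  grid <- expand.grid(x = xs, y = ys)
  frac <- mean(mifcontext:::in_band(grid$x, grid$y, g$interface, 1000))
  expect_equal(frac * 24e6, polygon_area(band), tolerance = 0.02)
})

test_that("TC equals tumor minus the band overlap (straight case)", {
  g <- straight_geom()
  a <- attr(g, "areas_mm2")
  # band centred on the interface: half its area lies tumor-side
  expect_equal(a[["TC"]], a[["tumor"]] - a[["IM"]] / 2, tolerance = 1e-9)
  g2 <- make_geometry(interface_spec(6, "straight", tissue_extent_mm = c(6, 4)),
                      seed = 1)  # re-derivation determinism
  expect_identical(g$tc, g2$tc)
})

test_that("a band covering the whole tumor leaves an empty TC with a warning", {
  expect_warning(
    make_geometry(interface_spec(2, "straight", tissue_extent_mm = c(2, 0.8)),
                  seed = 1, im_width_um = 1000),
    "TC is empty"
  )
})

test_that("cells are assigned to IM/TC/outside by interface distance", {
  g <- straight_geom()  # interface at y = 2000, tumor below (y > 2000)
  cells <- tibble::tibble(
    x_um = c(3000, 3000, 3000, 3000, 3000),
    y_um = c(2300, 4000 - 0.5, 2500, 1500, 800)
  )
  out <- assign_regions(cells, g)
  expect_equal(as.character(out$region),
               c("IM", "TC", "IM", "IM", "outside"))
  # boundary cell at exactly width/2 from the interface is IM (closed band)
  b <- assign_regions(tibble::tibble(x_um = 1234, y_um = 2500), g)
  expect_equal(as.character(b$region), "IM")
})

test_that("region assignment matches independent point-in-polygon oracle", {
  g <- make_geometry(interface_spec(6, "sinusoidal", amplitude_mm = 0.35,
                                    tissue_extent_mm = c(6, 4)), seed = 9)
  set.seed(42)
  pts <- tibble::tibble(x_um = runif(1000, 0, 6000), y_um = runif(1000, 0, 4000))
  got <- as.character(assign_regions(pts, g)$region)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    d <- dense_polyline_dist(pts$x_um[i], pts$y_um[i], g$interface)
    if (d <= 500) "IM"
    else if (winding_inside(pts$x_um[i], pts$y_um[i], g$tumor)) "TC"
    else "outside"
  }, character(1))
  # exclude points within discretisation tolerance of the band boundary
  near <- vapply(seq_len(nrow(pts)), function(i) {
    abs(dense_polyline_dist(pts$x_um[i], pts$y_um[i], g$interface) - 500) < 2
  }, logical(1))
  expect_gt(sum(!near), 900)
  expect_equal(got[!near], oracle[!near])
})

test_that("field selection fills capacity, clips small regions, and is deterministic", {
  g <- straight_geom()
  f_im <- select_fields(g, "IM", seed = 4)
  expect_equal(nrow(f_im), 5)
  expect_true(all(f_im$area_mm2 <= 1 + 1e-12))
  expect_identical(f_im, select_fields(g, "IM", seed = 4))
  # non-overlap of chosen squares
  if (nrow(f_im) > 1) {
    for (i in 1:(nrow(f_im) - 1)) for (j in (i + 1):nrow(f_im)) {
      expect_true(abs(f_im$x0_um[i] - f_im$x0_um[j]) >= 1000 ||
                    abs(f_im$y0_um[i] - f_im$y0_um[j]) >= 1000)
    }
  }
  # tiny region: single clipped field with warning
  gs <- suppressWarnings(
    make_geometry(interface_spec(0.6, "straight", tissue_extent_mm = c(0.6, 3)),
                  seed = 1))
  expect_warning(f1 <- select_fields(gs, "IM", seed = 1), "smaller than one field")
  expect_equal(nrow(f1), 1)
  expect_lt(f1$area_mm2, 1)
})

test_that("densities are counts over analysed area, exactly", {
  g <- straight_geom()
  f <- dplyr::bind_rows(select_fields(g, "IM", seed = 1),
                        select_fields(g, "TC", seed = 1))
  # 50 CD8+ cells placed inside one full IM field
  fld <- f[f$region == "IM" & f$area_mm2 == 1, ][1, ]
  set.seed(1)
  cells <- tibble::tibble(
    sample_id = "s1", panel = "P2",
    x_um = runif(50, fld$x0_um + 1, fld$x0_um + 999),
    y_um = runif(50, fld$y0_um + 1, fld$y0_um + 999),
    CD8 = 1L
  )
  cells <- gate_phenotypes(cells) |> assign_regions(geometry = g)
  dens <- compute_densities(cells, f[f$field_id == fld$field_id & f$region == "IM", ])
  cd8 <- dens[dens$phenotype == "CD8+", ]
  expect_equal(cd8$n_cells, 50L)
  expect_equal(cd8$density, 50)
  # absent phenotype gets an explicit zero record
  dens0 <- compute_densities(cells, f, phenotypes = c("CD8+", "PD-L1+"))
  pdl1 <- dens0[dens0$phenotype == "PD-L1+", ]
  expect_true(all(pdl1$density == 0))
  # closure: density * area returns the integer count
  expect_equal(dens0$density * dens0$area_mm2, as.numeric(dens0$n_cells))
})

test_that("geometry areas agree between polygon and predicate views", {
  g <- make_geometry(interface_spec(6, "sinusoidal", amplitude_mm = 0.3,
                                    tissue_extent_mm = c(6, 4)), seed = 2)
  xs <- seq(5, 5995, by = 15); ys <- seq(5, 3995, by = 15)
  grid <- expand.grid(x = xs, y = ys)
  lab <- mifcontext:::region_membership(grid$x, grid$y, g)
  a <- attr(g, "areas_mm2")
  expect_equal(mean(lab == "IM") * 24, a[["IM"]], tolerance = 0.01)
  expect_equal(mean(lab == "TC") * 24, a[["TC"]], tolerance = 0.01)
})
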