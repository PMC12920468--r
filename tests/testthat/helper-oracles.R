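# Independent oracles and small fixtures, deliberately implemented with
# different algorithms than the package internals they check.

# O(n^2) all-pairs radius neighbours via a full distance matrix.
brute_pairs <- function(a, b, radius, same = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  dm <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  hit <- which(dm <= radius^2, arr.ind = TRUE)
  out <- data.frame(i = hit[, 1], j = hit[, 2])
  if (same) out <- out[out$j > out$i, , drop = FALSE]
  out[order(out$i, out$j), , drop = FALSE]
}

# Winding-number point-in-polygon, one point at a time (independent of the
# package's even-odd ray caster).
winding_inside <- function(px, py, poly) {
  n <- nrow(poly)
  wn <- 0
  for (k in seq_len(n)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]
    kk <- if (k == n) 1 else k + 1
    x2 <- poly[kk, 1]; y2 <- poly[kk, 2]
    if (y1 <= py) {
      if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0) wn <- wn + 1
    } else {
      if (y2 <= py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Distance to a polyline by dense resampling (1 um steps along segments).
dense_polyline_dist <- function(px, py, line, step = 1) {
  pts <- do.call(rbind, lapply(seq_len(nrow(line) - 1), function(i) {
    d <- line[i + 1, ] - line[i, ]
    len <- sqrt(sum(d^2))
    tt <- seq(0, 1, by = step / len)
    cbind(line[i, 1] + tt * d[1], line[i, 2] + tt * d[2])
  }))
  min(sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns.
exact_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
exact_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Fixtures -------------------------------------------------------------

# Straight-interface geometry on a 6 x 4 mm tissue (interface spans the
# full width so flat caps coincide with the tissue edge).
straight_geom <- function(width_mm = 6, height_mm = 4, im_width_um = 1000) {
  make_geometry(interface_spec(width_mm, "straight",
                               tissue_extent_mm = c(width_mm, height_mm)),
                seed = 1, im_width_um = im_width_um)
}

# Minimal two-phenotype Panel 2 intensity set.
cd8_pdl1_specs <- function(lam_cd8 = c(250, 450), lam_pdl1 = c(80, 220)) {
  dplyr::bind_rows(
    phenotype_intensity("CD8+", "P2", lam_cd8[1], lam_cd8[2]),
    phenotype_intensity("PD-L1+", "P2", lam_pdl1[1], lam_pdl1[2])
  )
}

# Assign + fields + densities + proximity + composite score for a small
# cohort, reusing one field set per distinct geometry.
score_mini_cohort <- function(cohort, seed = 1) {
  geoms <- cohort$geometries
  fields <- purrr::map_dfr(names(geoms), function(sid) {
    dplyr::bind_rows(
      select_fields(geoms[[sid]], "IM", seed = seed),
      select_fields(geoms[[sid]], "TC", seed = seed)
    ) |> dplyr::mutate(sample_id = sid, .before = 1)
  })
  cells <- gate_phenotypes(cohort$cells)
  cells <- purrr::map_dfr(names(geoms), function(sid) {
    assign_regions(cells[cells$sample_id == sid, , drop = FALSE], geoms[[sid]])
  })
  dens <- compute_densities(cells, fields)
  prox <- proximity_table(cells, fields)
  mat <- cd8_pdl1_matrix(dens, prox)
  list(densities = dens, proximity = prox,
       scores = cd8_pdl1_score(mat), fields = fields)
}
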