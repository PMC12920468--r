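# Paired, group-wise and correlation statistics plus the association panel.

dens_from_matrix <- function(im, tc, phenotype = "CD8+", panel = "P2") {
  n <- length(im)
  tibble::tibble(
    sample_id = rep(sprintf("s%02d", 1:n), 2),
    region = rep(c("IM", "TC"), each = n),
    panel = panel, phenotype = phenotype,
    n_cells = c(im, tc), area_mm2 = 1, density = c(im, tc)
  )
}

test_that("paired comparison: degenerate, shifted and oracle cases", {
  d <- dens_from_matrix(c(5, 7, 9, 11), c(5, 7, 9, 11))
  r <- paired_region_compare(d, "CD8+")
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  # n = 6 uniform shift: exact two-sided p = 2/64
  set.seed(1)
  tc <- runif(6, 10, 20)
  r2 <- paired_region_compare(dens_from_matrix(tc + 10, tc), "CD8+")
  expect_equal(r2$p_value, 2 / 64)
  expect_equal(r2$estimate, 10)
  # random paired data matches exact sign-pattern enumeration for n <= 12
  for (n in c(5, 8, 12)) {
    im <- rnorm(n, 1); tc <- rnorm(n)
    r3 <- paired_region_compare(dens_from_matrix(im, tc), "CD8+")
    expect_equal(r3$p_value, exact_signed_rank_p(im, tc), tolerance = 1e-12)
  }
  expect_error(paired_region_compare(dens_from_matrix(1:2, 2:3), "CD8+"),
               "at least 3")
})

test_that("group comparison: separation, identity and permutation oracle", {
  sep <- group_compare(c(1, 2, 3, 10, 11, 12),
                       rep(c("low", "high"), each = 3))
  expect_equal(sep$p_value, 0.1)      # 2/20 orderings as or more extreme
  expect_true(abs(sep$estimate) == 1) # complete rank separation
  same <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
  set.seed(2)
  for (k in 1:4) {
    x <- rnorm(5); y <- rnorm(5, 0.5)
    r <- group_compare(c(x, y), rep(c("a", "b"), each = 5))
    expect_equal(r$p_value, exact_mann_whitney_p(x, y), tolerance = 1e-12)
  }
  expect_error(group_compare(1:4, rep("a", 4)), "two non-empty groups")
})

test_that("correlation recovers exact linear relations and matches hand formula", {
  x <- c(1, 2, 3, 4, 5)
  r <- correlate(x, 2 * x + 1)
  expect_equal(r$estimate, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  # hand-computed Pearson r for a small dataset
  x2 <- c(1, 2, 4, 5, 7); y2 <- c(2, 1, 5, 4, 8)
  num <- sum((x2 - mean(x2)) * (y2 - mean(y2)))
  den <- sqrt(sum((x2 - mean(x2))^2) * sum((y2 - mean(y2))^2))
  r2 <- correlate(x2, y2)
  expect_equal(r2$estimate, num / den, tolerance = 1e-12)
  tval <- r2$estimate * sqrt(3 / (1 - r2$estimate^2))
  expect_equal(r2$p_value, 2 * stats::pt(-abs(tval), 3), tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "constant")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("null correlation is centred at zero", {
  set.seed(5)
  rs <- replicate(200, correlate(rnorm(50), rnorm(50))$estimate)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("significance stars follow the reporting convention", {
  expect_equal(signif_stars(c(0.05, 0.051, 0.009, 0.0009, 0.2, NA)),
               c("*", "ns", "**", "***", "ns", NA))
})

test_that("association panel flags constructed correlations and inert rows", {
  set.seed(11)
  n <- 50
  ids <- sprintf("s%02d", 1:n)
  cd8 <- rexp(n, 1 / 300)
  build <- function(ph, panel, dens) {
    tibble::tibble(sample_id = rep(ids, 2), region = rep(c("IM", "TC"), each = n),
                   panel = panel, phenotype = ph, n_cells = rep(dens, 2),
                   area_mm2 = 1, density = rep(dens, 2))
  }
  dens <- dplyr::bind_rows(
    build("CD8+", "P2", cd8),
    build("PD-L1+", "P2", rexp(n, 1 / 100)),
    build("CD3+", "P3", cd8 * 1.5),          # perfectly coupled to CD8
    build("CD56+", "P3", rexp(n, 1 / 50)),   # independent
    build("CD20+", "P1", rep(0, n))          # everywhere zero: not evaluable
  )
  scores <- tibble::tibble(
    sample_id = ids,
    category = factor(rep(c("low", "high"), length.out = n),
                      levels = c("low", "high"))
  )
  rows <- tibble::tribble(~panel, ~phenotype,
                          "P3", "CD3+", "P3", "CD56+", "P1", "CD20+")
  pan <- association_panel(dens, scores, rows = rows)
  expect_equal(pan$stars_cor_cd8[pan$phenotype == "CD3+"], "***")
  expect_false(pan$evaluable[pan$phenotype == "CD20+"])
  expect_true(all(is.na(pan$p_group[!pan$evaluable])))
})

test_that("region stratification localises a planted IM-only correlation", {
  set.seed(12)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  cd8_im <- rexp(n, 1 / 300); cd8_tc <- rexp(n, 1 / 300)
  trg_im <- cd8_im * 0.5 + rnorm(n, 0, 5)   # correlated with CD8 in IM only
  trg_tc <- rexp(n, 1 / 150)
  mk <- function(ph, panel, im, tc) {
    tibble::tibble(sample_id = rep(ids, 2), region = rep(c("IM", "TC"), each = n),
                   panel = panel, phenotype = ph, n_cells = c(im, tc),
                   area_mm2 = 1, density = c(im, tc))
  }
  dens <- dplyr::bind_rows(
    mk("CD8+", "P2", cd8_im, cd8_tc),
    mk("PD-L1+", "P2", rexp(n, 1 / 100), rexp(n, 1 / 100)),
    mk("CD56+", "P3", trg_im, trg_tc)
  )
  scores <- tibble::tibble(
    sample_id = ids,
    category = factor(rep(c("low", "high"), length.out = n),
                      levels = c("low", "high"))
  )
  rows <- tibble::tibble(panel = "P3", phenotype = "CD56+")
  strat <- region_stratified_panel(dens, scores, rows = rows)
  expect_lt(strat$p_cor_cd8[strat$region == "IM"], 0.001)
  expect_gt(strat$p_cor_cd8[strat$region == "TC"], 0.05)
  # a one-region panel equals the pooled association panel
  pooled <- association_panel(dens[dens$region == "IM", ], scores, rows = rows)
  expect_equal(strat$p_cor_cd8[strat$region == "IM"], pooled$p_cor_cd8)
  # stratum smaller than 3 samples is suppressed with a warning
  meta <- tibble::tibble(sample_id = ids,
                         msi = c("MSI-H", "MSI-H", rep("MSS", n - 2)))
  warns <- testthat::capture_warnings(
    strat2 <- region_stratified_panel(dens, scores, metadata = meta, rows = rows))
  expect_true(length(warns) >= 1 && all(grepl("fewer than 3", warns)))
  expect_false(any(strat2$msi == "MSI-H"))
})

test_that("contingency utility picks chi-square or Fisher as appropriate", {
  big <- matrix(c(30, 10, 12, 28), 2)
  r1 <- contingency_test(big)
  expect_equal(r1$test, "chi_square")
  expect_equal(r1$p_value, stats::chisq.test(big, correct = FALSE)$p.value)
  small <- matrix(c(4, 1, 1, 5), 2)
  r2 <- contingency_test(small)
  expect_equal(r2$test, "fisher_exact")
  expect_equal(r2$p_value, stats::fisher.test(small)$p.value)
})
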