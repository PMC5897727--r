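test_that("fold_angle maps to [0, 90] with the dorsoventral symmetry and is
           idempotent", {
  expect_equal(fold_angle(135), 45)
  expect_equal(fold_angle(-90), 90)
  expect_equal(fold_angle(0), 0)
  expect_equal(fold_angle(90), 90)
  thetas <- seq(-720, 720, by = 7.3)
  folded <- fold_angle(thetas)
  expect_true(all(folded >= 0 & folded <= 90))
  expect_equal(fold_angle(folded), folded)
})

test_that("ellipse fit recovers orientation and aspect ratio of rendered
           ellipses", {
  for (ang in c(0, 18, 30, 45, 63, 90)) {
    m <- render_ellipse_mask(ang, 30, 15)
    cells <- measure_cells(m * 1L, c(1, 1))
    expect_lt(axial_abs_diff(cells$orientation_deg, fold_angle(ang)), 2)
    expect_equal(cells$aspect_ratio, 2, tolerance = 0.05)
  }
  # accuracy summary over many angles (the ellipse-fit error bound)
  errs <- vapply(seq(5, 85, by = 10), function(ang) {
    cells <- measure_cells(render_ellipse_mask(ang, 24, 16) * 1L, c(1, 1))
    axial_abs_diff(cells$orientation_deg, ang)
  }, numeric(1))
  expect_lt(mean(errs), 3)
})

test_that("a perfect circle is round, unit aspect ratio, and flagged
           degenerate", {
  m <- render_ellipse_mask(0, 20, 20)
  cells <- measure_cells(m * 1L, c(1, 1))
  expect_equal(cells$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(cells$roundness, 1, tolerance = 0.03)
  expect_true(cells$degenerate)
})

test_that("second-moment fit agrees with the EBImage moment features
           (independent route)", {
  m <- render_ellipse_mask(30, 30, 15)
  cells <- measure_cells(m * 1L, c(1, 1))
  f <- EBImage::computeFeatures.moment(matrix(as.integer(m), nrow(m)))
  expect_lt(axial_abs_diff(cells$orientation_deg,
                           fold_angle(f[, "m.theta"] * 180 / pi)), 1)
  ar_ebimage <- 1 / sqrt(1 - f[, "m.eccentricity"]^2)
  expect_equal(cells$aspect_ratio, unname(ar_ebimage), tolerance = 0.02)
})

test_that("orientation is invariant under 180-degree rotation; area under
           90-degree rotation", {
  m <- render_ellipse_mask(28, 25, 14) * 1L
  a <- measure_cells(m, c(1, 1))
  b <- measure_cells(m[nrow(m):1, ncol(m):1], c(1, 1))
  expect_lt(axial_abs_diff(a$orientation_deg, b$orientation_deg), 1e-6)
  r90 <- measure_cells(t(m), c(1, 1))
  expect_equal(a$area_um2, r90$area_um2)
  expect_equal(a$aspect_ratio, r90$aspect_ratio, tolerance = 0.05)
})

test_that("tiny cells are skipped with a message and edge cells excluded", {
  labs <- matrix(0L, 20, 20)
  labs[5:12, 5:12] <- 1L
  labs[15, 15] <- 2L                       # 1 px
  labs[1:3, 14:19] <- 3L                   # touches the edge
  expect_message(res <- measure_cells(labs, c(1, 1)), "below 5 px")
  expect_identical(res$label, 1L)
})

test_that("division angle follows the axis conventions and is symmetric", {
  expect_equal(division_angle(c(0, 0), c(5, 0)), 0)      # pure ML
  expect_equal(division_angle(c(0, 0), c(0, 5)), 90)     # pure RC
  expect_equal(division_angle(c(0, 0), c(1, 1)), 45)
  expect_equal(division_angle(c(2, 3), c(7, 1)),
               division_angle(c(7, 1), c(2, 3)))
  expect_error(division_angle(c(1, 1), c(1, 1)), "distinct")
})

test_that("midline ROI selects a band of cells around the midline", {
  p <- sheet_phantom_params(grid_size = c(140L, 96L, 40L), n_cells = 120L,
                            noise_sd = 0, seed = 6L)
  ph <- phantom_surface_image(p)
  labs <- ph$truth$cell_labels
  mid <- (nrow(labs) - 1) * ph$spacing[1] / 2
  roi0 <- midline_roi(labs, ph$spacing, mid, half_width_cells = 0)
  sel0 <- unique(labs[roi0])
  ctr <- ph$truth$cell_table
  expect_true(all(abs(ctr$seed_ml_um[match(sel0, ctr$label)] - mid) <
                    2 * sqrt(mean(table(labs)) * prod(ph$spacing) / pi) * 2))
  roi6 <- midline_roi(labs, ph$spacing, mid, half_width_cells = 6)
  cells6 <- suppressMessages(measure_cells(labs, ph$spacing, roi_mask = roi6))
  # about a 12-cell-wide band: all selected centroids within the band width
  diam <- stats::median(2 * sqrt(cells6$area_um2 / pi))
  expect_true(all(abs(cells6$centroid_ml_um - mid) <= 6.5 * diam))
  expect_gt(nrow(cells6), 20)
  expect_warning(out <- midline_roi(labs, ph$spacing, 1e5), "outside")
  expect_false(any(out))
})

test_that("axial mean handles wraparound at the rostrocaudal pole", {
  # samples straddling 90 degrees (axes 85..95) must average to 90, not drift
  ax <- c(85, 87, 93, 95, 90)
  expect_equal(axial_mean_deg(ax), 90)
  expect_lt(axial_dispersion(ax), 0.02)
})
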