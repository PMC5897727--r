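test_that("parameter validation rejects out-of-range settings", {
  expect_error(sheet_phantom_params(border_anisotropy_a = 0), "> 0")
  expect_error(sheet_phantom_params(orientation_mean_deg = 120), "0, 90")
  expect_error(sheet_phantom_params(voxel_spacing = c(0.59, -1, 1)), "> 0")
  expect_error(sheet_phantom_params(deep_layer_offset_um = 5), ">= 10")
})

test_that("grid too small for surface amplitude raises a sizing error", {
  p <- sheet_phantom_params(grid_size = c(48L, 48L, 12L),
                            surface_amplitude_um = 25)
  expect_error(generate_sheet_stack(p), "grid too small")
})

test_that("same seed reproduces the phantom bit for bit; seeds differ", {
  p <- sheet_phantom_params(grid_size = c(64L, 64L, 40L), n_cells = 40L,
                            seed = 11L)
  a <- generate_sheet_stack(p)
  b <- generate_sheet_stack(p)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$cell_labels, b$truth$cell_labels)
  p2 <- p; p2$seed <- 12L
  c2 <- generate_sheet_stack(p2)
  expect_false(identical(a$truth$cell_labels, c2$truth$cell_labels))
})

test_that("isotropic phantom (a = 1, kappa = 0) has unit programmed ratios
           and a near-uniform orientation histogram", {
  p <- sheet_phantom_params(border_anisotropy_a = 1, orientation_kappa = 0,
                            noise_sd = 0, seed = 1L)
  ph <- generate_sheet_stack(p)
  r <- ph$truth$per_cell_true_ratio$true_ratio
  expect_true(all(abs(r[!is.na(r)] - 1) < 1e-9))
  o <- ph$truth$cell_table$orientation_deg
  counts <- angular_distribution(o)$counts
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)    # no gross bias
})

test_that("programmed anisotropy a = 2 is exact on painted voxel classes", {
  p <- sheet_phantom_params(border_anisotropy_a = 2, noise_sd = 0, seed = 7L)
  ph <- generate_sheet_stack(p)
  tr <- ph$truth
  nz <- dim(ph$stack$voxels)[3]
  ml3 <- tr$layer_mask & array(rep(tr$paint_class == 3L, nz),
                               dim(ph$stack$voxels))
  rc3 <- tr$layer_mask & array(rep(tr$paint_class == 2L, nz),
                               dim(ph$stack$voxels))
  ratio <- mean(ph$stack$voxels[ml3]) / mean(ph$stack$voxels[rc3])
  expect_equal(ratio, 2, tolerance = 1e-9)
})

test_that("deep_layer_intensity = 0 leaves zero signal below 10 um under the
           surface", {
  p <- sheet_phantom_params(deep_layer_intensity = 0, noise_sd = 0, seed = 2L)
  ph <- generate_sheet_stack(p)
  vol <- ph$stack$voxels
  dz <- p$voxel_spacing[3]
  k0 <- round(ph$truth$true_surface_depth / dz) + 1L
  below <- array(FALSE, dim(vol))
  for (k in seq_len(dim(vol)[3]))
    below[, , k] <- k > (k0 + 10 / dz)
  expect_equal(sum(vol[below]), 0)
})

test_that("interior cells of the tessellation have at least three borders", {
  p <- sheet_phantom_params(seed = 3L)
  ph <- phantom_surface_image(p)
  g <- build_border_graph(ph$truth$cell_labels, ph$spacing)
  interior <- setdiff(as.integer(names(g$cell_edges)), g$boundary_labels)
  n_borders <- lengths(g$cell_edges[as.character(interior)])
  expect_true(all(n_borders >= 3L))
})

test_that("orientation concentration: dispersion of rendered long axes
           decreases monotonically in kappa", {
  disp <- vapply(c(0, 1, 4, 16), function(k) {
    p <- sheet_phantom_params(grid_size = c(140L, 140L, 40L), n_cells = 200L,
                              orientation_kappa = k,
                              orientation_mean_deg = 90, noise_sd = 0,
                              seed = 21L)
    ph <- phantom_surface_image(p)
    cells <- suppressMessages(measure_cells(ph$truth$cell_labels, ph$spacing))
    axial_dispersion(cells$orientation_axial_deg)
  }, numeric(1))
  expect_true(all(diff(disp) < 0))
})

test_that("division phantom: axis-aligned pairs and exact centroids", {
  d0 <- generate_division_image(c(0), seed = 1L)
  expect_equal(d0$truth$rc_1, d0$truth$rc_2, tolerance = 1e-9)   # pure ML
  d90 <- generate_division_image(c(90), seed = 1L)
  expect_equal(d90$truth$ml_1, d90$truth$ml_2, tolerance = 1e-9) # pure RC
  expect_error(generate_division_image(c(120)), "0, 90")
})

test_that("division phantom: centroid-detected angles match programmed ones
           within half a degree", {
  d <- generate_division_image(c(30, 60), seed = 5L)
  det <- detect_division_pairs(d$image, d$spacing)
  expect_equal(sort(det$angle_deg), c(30, 60), tolerance = 0.5 / 30)
})

test_that("cross-section phantom renders programmed signed elevations", {
  for (elev in c(30, -15, 0)) {
    cs <- generate_cross_section(elev, seed = 2L)
    lm <- extract_section_landmarks(cs$image, cs$spacing)
    measured <- fold_elevation(section_landmarks(lm$ventral_apical_midline,
                                                 lm$fold_tips))
    expect_lt(abs(measured - elev), max(cs$spacing))     # within one voxel
  }
  # programmed truth is exact by construction
  cs <- generate_cross_section(-15, seed = 2L)
  expect_equal(unname(mean(cs$truth$fold_tips[, 2]) -
                        cs$truth$ventral_apical_midline[2]), -15)
})

test_that("ablation phantom pair: programmed widening, zero and negative", {
  for (w in c(0, 40, -10)) {
    ab <- generate_ablation_pair(100, w, seed = 2L)
    aw <- ablation_widening(ab$pre, ab$post,
                            rc_level_um = ab$truth$canthus_rc_um,
                            spacing = ab$spacing)
    expect_lt(abs(aw$widening - w), max(ab$spacing))     # within one voxel
  }
})
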