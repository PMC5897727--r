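test_that("two cells split by a straight line share one border with the
           expected orientation", {
  labs <- matrix(1L, 20, 20)
  labs[, 11:20] <- 2L                      # split along the RC direction
  g <- build_border_graph(labs, c(1, 1))
  expect_equal(length(g$edges), 1L)
  img <- matrix(1, 20, 20)
  m <- measure_borders(g, img)
  expect_equal(m$orientation_deg, 0)       # border runs along ML
  expect_equal(m$class, "ML")
  # a split across ML gives an RC-running border
  g2 <- build_border_graph(t(labs), c(1, 1))
  m2 <- measure_borders(g2, img)
  expect_equal(m2$orientation_deg, 90)
  expect_equal(m2$class, "RC")
})

test_that("a single cell yields an empty edge set", {
  labs <- matrix(0L, 12, 12); labs[4:9, 4:9] <- 1L
  g <- build_border_graph(labs, c(1, 1))
  expect_equal(length(g$edges), 0L)
  expect_equal(nrow(g$edge_table), 0L)
})

test_that("grid map adjacency count matches enumeration", {
  labs <- grid_label_map(3, 3)             # 3x3 cells: 2*3 + 2*3 = 12 borders
  g <- build_border_graph(labs, c(1, 1))
  expect_equal(length(g$edges), 12L)
  labs2 <- grid_label_map(2, 4)            # 1*4 + 3*2 = 10
  expect_equal(length(build_border_graph(labs2, c(1, 1))$edges), 10L)
})

test_that("border class follows the 45-degree rule with RC ties", {
  expect_equal(ifelse(44.9 < 45, "ML", "RC"), "ML")
  # rendered diagonal border at 60 degrees classifies RC
  n <- 30
  labs <- matrix(1L, n, n)
  i <- matrix(seq_len(n), n, n); j <- t(i)
  # half-plane whose boundary runs at 60 deg from the ML axis
  labs[-(i - n / 2) * sin(60 * pi / 180) + (j - n / 2) * cos(60 * pi / 180) >
         0] <- 2L
  g <- build_border_graph(labs, c(1, 1))
  m <- measure_borders(g, matrix(1, n, n))
  expect_equal(m$class, "RC")
  expect_equal(m$orientation_deg, 60, tolerance = 0.05)
})

test_that("painted anisotropy is recovered by border measurement within
           10 percent", {
  p <- sheet_phantom_params(border_anisotropy_a = 2, noise_sd = 0, seed = 7L)
  ph <- phantom_surface_image(p)
  g <- build_border_graph(ph$truth$cell_labels, ph$spacing)
  m <- measure_borders(g, ph$image)
  ratio <- mean(m$mean_intensity[m$class == "ML"]) /
    mean(m$mean_intensity[m$class == "RC"])
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("per-cell ratios: exact values on constructed intensity maps", {
  labs <- grid_label_map(3, 3)
  g <- build_border_graph(labs, c(1, 1))
  # equal intensity everywhere -> every ratio 1
  m <- measure_borders(g, matrix(7, nrow(labs), ncol(labs)))
  r <- suppressMessages(cell_enrichment_ratios(g, m, exclude_boundary = FALSE))
  expect_true(all(abs(r$ratio - 1) < 1e-9))
  # ML borders at 200, RC at 100 -> ratio 2
  m2 <- m
  m2$mean_intensity <- ifelse(m2$class == "ML", 200, 100)
  r2 <- suppressMessages(cell_enrichment_ratios(g, m2,
                                                exclude_boundary = FALSE))
  expect_true(all(abs(r2$ratio - 2) < 1e-9))
  # the centre cell of a 3x3 grid has both classes; corner cells also do
  expect_true(5 %in% r2$label)
})

test_that("cells lacking one border class are excluded, not infinite", {
  labs <- rbind(matrix(1L, 6, 12), matrix(2L, 6, 12))  # single ML border
  g <- build_border_graph(labs, c(1, 1))
  m <- measure_borders(g, matrix(1, 12, 12))
  expect_message(
    r <- cell_enrichment_ratios(g, m, exclude_boundary = FALSE),
    "lacking")
  expect_equal(nrow(r), 0L)
  expect_setequal(attr(r, "excluded"), c(1L, 2L))
})

test_that("embryo score is the median of ratios with the n >= 35 validity
           rule", {
  expect_equal(embryo_enrichment_score(c(1, 1, 1))$embryo_score, 1)
  expect_equal(embryo_enrichment_score(c(0.5, 1, 2))$embryo_score, 1)
  expect_false(embryo_enrichment_score(c(0.5, 1, 2))$valid)
  expect_true(embryo_enrichment_score(rep(1.2, 35))$valid)
  expect_error(embryo_enrichment_score(c(1, -1, 2)), "positive")
})

test_that("enrichment pipeline is invariant to global intensity scaling", {
  p <- sheet_phantom_params(border_anisotropy_a = 1.5, seed = 3L)
  ph <- phantom_surface_image(p)
  g <- build_border_graph(ph$truth$cell_labels, ph$spacing)
  m1 <- measure_borders(g, ph$image)
  m2 <- measure_borders(g, ph$image * 37.5)
  r1 <- suppressMessages(cell_enrichment_ratios(g, m1))
  r2 <- suppressMessages(cell_enrichment_ratios(g, m2))
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  p1 <- detect_profiles(g, m1, k = 1.25)
  p2 <- detect_profiles(g, m2, k = 1.25)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$orientation_deg, p2$orientation_deg)
})

test_that("swapping the ML and RC axis roles reciprocates per-cell ratios", {
  p <- sheet_phantom_params(border_anisotropy_a = 1.5, noise_sd = 0,
                            seed = 13L)
  ph <- phantom_surface_image(p)
  g <- build_border_graph(ph$truth$cell_labels, ph$spacing)
  m <- measure_borders(g, ph$image)
  r <- suppressMessages(cell_enrichment_ratios(g, m))
  gt <- build_border_graph(t(ph$truth$cell_labels), rev(ph$spacing))
  mt <- measure_borders(gt, t(ph$image))
  rt <- suppressMessages(cell_enrichment_ratios(gt, mt))
  common <- intersect(r$label, rt$label)
  prod <- r$ratio[match(common, r$label)] * rt$ratio[match(common, rt$label)]
  expect_equal(stats::median(prod), 1, tolerance = 0.1)
})

test_that("profile detection: none on uniform images, single-edge minimal
           chains, ML bias on strongly anisotropic phantoms", {
  labs <- grid_label_map(3, 3)
  g <- build_border_graph(labs, c(1, 1))
  m <- measure_borders(g, matrix(5, nrow(labs), ncol(labs)))
  expect_equal(nrow(detect_profiles(g, m, k = 1.5)), 0L)
  expect_error(detect_profiles(g, m, k = 1), "k > 1")
  # one bright border -> exactly one single-edge profile spanning 2 cells
  m$mean_intensity[3] <- 50
  pr <- detect_profiles(g, m, k = 1.5)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$n_edges, 1L)
  expect_equal(pr$n_cells, 2L)
  # strongly ML-anisotropic phantom: profiles mostly ML-oriented
  p <- sheet_phantom_params(border_anisotropy_a = 3,
                            orientation_mean_deg = 0, orientation_kappa = 8,
                            noise_sd = 0, seed = 17L)
  ph <- phantom_surface_image(p)
  g2 <- build_border_graph(ph$truth$cell_labels, ph$spacing)
  m2 <- measure_borders(g2, ph$image)
  pr2 <- detect_profiles(g2, m2, k = 1.5)
  expect_gt(nrow(pr2), 5)
  expect_gte(mean(pr2$orientation_deg < 30), 0.8)
})
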