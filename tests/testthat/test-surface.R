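roles <- c("mediolateral", "rostrocaudal", "dorsoventral")

test_that("phantom surface is detected within one voxel nearly everywhere", {
  p <- sheet_phantom_params(seed = 11L)
  ph <- generate_sheet_stack(p)
  mask <- binarise(ph$stack)
  # >= 95% of true-layer voxels binarise as foreground
  expect_gt(mean(mask[ph$truth$layer_mask]), 0.95)
  dm <- find_top_surface(mask, spacing_dv = p$voxel_spacing[3])
  err <- abs(dm - round(ph$truth$true_surface_depth))
  expect_gt(mean(err <= p$voxel_spacing[3], na.rm = TRUE), 0.99)
})

test_that("peeling is idempotent and never increases total intensity", {
  p <- sheet_phantom_params(grid_size = c(64L, 64L, 40L), n_cells = 40L,
                            seed = 4L)
  ph <- generate_sheet_stack(p)
  s <- ph$stack
  ex <- extract_surface(s)
  once <- ex$peeled
  twice <- peel(once, ex$band)
  expect_identical(once$voxels, twice$voxels)
  expect_lte(sum(once$voxels), sum(s$voxels))
  # band covering everything is the identity
  all_band <- structure(list(depth_map = matrix(0, 64, 64), band_depth_um = 40,
                             band_mask = array(TRUE, dim(s$voxels))),
                        class = "surface_band")
  expect_identical(peel(s, all_band)$voxels, s$voxels)
  expect_equal(sum(peel(s, all_band)$voxels), sum(s$voxels))
})

test_that("band voxels stay in the true surface layer and the deep layer is
           removed, across amplitudes and noise", {
  for (amp in c(0, 10, 25)) for (ns in c(0, 30)) {
    p <- sheet_phantom_params(surface_amplitude_um = amp, noise_sd = ns,
                              grid_size = c(96L, 96L, 56L), seed = 11L)
    ph <- generate_sheet_stack(p)
    ex <- extract_surface(ph$stack)
    in_layer <- sum(ex$band$band_mask & ph$truth$layer_mask) /
      sum(ex$band$band_mask)
    expect_gt(in_layer, 0.95)
    deep_total <- sum(ph$stack$voxels[ph$truth$deep_mask])
    deep_left <- sum(ex$peeled$voxels[ph$truth$deep_mask])
    expect_lt(deep_left / deep_total, 0.01)
  }
})

test_that("projection of a single nonzero voxel lands at its lateral
           position", {
  v <- array(0, c(5, 6, 7)); v[2, 3, 4] <- 9
  s <- image_stack(v, c(1, 1, 1), roles)
  pr <- surface_project(s)
  expect_equal(pr$image[2, 3], 9)
  expect_equal(sum(pr$image), 9)
})

test_that("peeling removes deep-layer contamination from the projected
           border network", {
  p <- sheet_phantom_params(noise_sd = 0, seed = 9L)
  ph <- generate_sheet_stack(p)
  ex <- extract_surface(ph$stack)
  thr <- (p$interior_intensity + p$border_intensity) / 2
  truth_net <- ph$truth$paint_class >= 2L
  jacc <- function(img) {
    net <- img > thr
    d <- function(m) as.matrix(EBImage::dilate(EBImage::Image(m),
                                               EBImage::makeBrush(3, "box")))
    a <- d(net) > 0.5; b <- d(truth_net) > 0.5
    sum(a & b) / sum(a | b)
  }
  j_peeled <- jacc(surface_project(ex$peeled)$image)
  j_raw <- jacc(surface_project(ph$stack)$image)
  expect_gt(j_peeled, 0.8)
  expect_lt(j_raw, j_peeled)
})

test_that("contrast enhancement: flat image stays flat, oversized block
           errors, default schedule is the two-step one", {
  sched <- default_clahe_schedule()
  expect_equal(vapply(sched, `[[`, numeric(1), "rolling_ball_radius"),
               c(30, 30))
  expect_equal(vapply(sched, `[[`, numeric(1), "block_size"), c(50, 30))
  flat <- matrix(0.7, 120, 120)
  expect_equal(clahe_enhance(flat), matrix(0, 120, 120))
  expect_error(clahe_enhance(matrix(stats::runif(100), 10),
                             list(list(rolling_ball_radius = 0,
                                       block_size = 50, bins = 100,
                                       slope = 3))),
               "block size")
})

test_that("enhancement rescues membrane segmentation under uneven
           illumination", {
  set.seed(4)
  n <- 200
  membrane <- matrix(FALSE, n, n)
  membrane[seq(6, n, by = 12), ] <- TRUE
  membrane[, seq(6, n, by = 12)] <- TRUE
  illum <- matrix(seq(0.12, 1, length.out = n), n, n)
  img <- pmax(ifelse(membrane, 1, 0.15) * illum +
                matrix(stats::rnorm(n * n, 0, 0.01), n), 0)
  otsu_mask <- function(x) {
    r <- range(x); xn <- matrix((x - r[1]) / diff(r), ncol = 1)
    thr <- EBImage::otsu(EBImage::Image(xn))
    matrix(xn > thr, nrow(x), ncol(x))
  }
  recall_pre <- mean(otsu_mask(img)[membrane])
  recall_post <- mean(otsu_mask(clahe_enhance(img))[membrane])
  expect_lte(recall_pre, 0.80)
  expect_gte(recall_post, 0.95)
})
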