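# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope); kappa = 0
# falls back to the uniform circle. Returns radians in [0, 2*pi).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
    }
  }
  out %% (2 * pi)
}

# axial orientations in [0, 180): von Mises on doubled angles, mean in degrees
raxial_deg <- function(n, mean_deg, kappa) {
  rvonmises(n, 2 * mean_deg * pi / 180, kappa) / 2 * 180 / pi
}

run_seeded <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Parameters of the curved epithelial-sheet phantom
#'
#' Bundles the generative parameters of the synthetic confocal stack used to
#' ground-truth the pipeline: a smooth curved top surface carrying a
#' tessellation of polygonal cells whose borders are brighter mediolaterally
#' than rostrocaudally by the anisotropy factor `border_anisotropy_a`
#' (ML border intensity = a x RC border intensity), with a dimmer second cell
#' layer deeper in the tissue and additive Gaussian noise.
#'
#' @param grid_size integer length-3: voxels along (ML, RC, DV).
#' @param voxel_spacing um per voxel along (ML, RC, DV); default
#'   `c(0.59, 0.59, 1)`, the acquisition geometry the pipeline targets.
#' @param surface_amplitude_um peak-to-trough height of the sinusoidal top
#'   surface (um).
#' @param surface_wavelength_um lateral wavelength of the surface (um).
#' @param surface_base_um dorsal margin above the shallowest surface point.
#' @param n_cells number of cells seeded in the tessellation.
#' @param border_anisotropy_a dimensionless > 0; programmed ML:RC border
#'   intensity ratio (1 = isotropic).
#' @param orientation_mean_deg mean cell long-axis orientation, `[0, 90]`
#'   (0 = ML, 90 = RC).
#' @param orientation_kappa von Mises concentration of long-axis orientations
#'   (0 = uniform).
#' @param elongation anisotropy of the per-cell distance metric; the aspect
#'   ratio of rendered cells grows with its square.
#' @param seed_jitter jitter of the hexagonal seed lattice, as a fraction of
#'   the lattice pitch (0 = regular honeycomb).
#' @param interior_intensity intensity of non-border surface-layer voxels.
#' @param border_intensity intensity of RC-class border voxels (ML-class =
#'   `border_anisotropy_a` times this).
#' @param border_cv lognormal coefficient of variation of per-border intensity
#'   (0 = every border exactly at its class intensity).
#' @param layer_thickness_um thickness of the top cell layer (default 5 um,
#'   matching the surface-subtraction band).
#' @param deep_layer_intensity border intensity of the second, deeper layer
#'   (0 disables it).
#' @param deep_layer_offset_um depth of the second layer below the surface
#'   (>= 10 um).
#' @param noise_sd additive Gaussian noise standard deviation (clipped at 0).
#' @param lloyd_iters Lloyd relaxation steps applied to the tessellation
#'   seeds (>= 1).
#' @param seed integer random seed; the same seed reproduces the phantom bit
#'   for bit.
#' @return list of class `sheet_phantom_params`.
#' @export
sheet_phantom_params <- function(grid_size = c(96L, 96L, 40L),
                                 voxel_spacing = c(0.59, 0.59, 1.0),
                                 surface_amplitude_um = 10,
                                 surface_wavelength_um = 60,
                                 surface_base_um = 3,
                                 n_cells = 90L,
                                 border_anisotropy_a = 1,
                                 orientation_mean_deg = 90,
                                 orientation_kappa = 0,
                                 elongation = 1.4,
                                 seed_jitter = 0.08,
                                 interior_intensity = 80,
                                 border_intensity = 150,
                                 border_cv = 0,
                                 layer_thickness_um = 5,
                                 deep_layer_intensity = 120,
                                 deep_layer_offset_um = 15,
                                 noise_sd = 10,
                                 lloyd_iters = 1L,
                                 seed = 1L) {
  p <- as.list(environment())
  if (p$border_anisotropy_a <= 0) stop("border_anisotropy_a must be > 0")
  if (p$orientation_mean_deg < 0 || p$orientation_mean_deg > 90)
    stop("orientation_mean_deg must lie in [0, 90]")
  if (any(p$voxel_spacing <= 0)) stop("voxel spacings must be > 0")
  if (p$orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  if (p$deep_layer_intensity > 0 && p$deep_layer_offset_um < 10)
    stop("deep layer must sit >= 10 um below the surface")
  if (p$lloyd_iters < 1) stop("at least one Lloyd relaxation is required")
  structure(p, class = "sheet_phantom_params")
}

# anisotropic nearest-seed assignment: per-cell metric compressed along the
# cell's long axis so cells elongate along their programmed orientation
assign_cells <- function(X, Y, sx, sy, theta_deg, elong) {
  best <- matrix(Inf, nrow(X), ncol(X))
  lab <- matrix(0L, nrow(X), ncol(X))
  th <- theta_deg * pi / 180
  for (c in seq_along(sx)) {
    dx <- X - sx[c]; dy <- Y - sy[c]
    u <- dx * cos(th[c]) + dy * sin(th[c])
    v <- -dx * sin(th[c]) + dy * cos(th[c])
    d2 <- (u / elong)^2 + (v * elong)^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- c
  }
  lab
}

# jittered hexagonal seed lattice: epithelium-like packing with low intrinsic
# shape anisotropy, so a cell's rendered long axis tracks its programmed one
hex_seed_points <- function(n, Lx, Ly, jitter_frac) {
  pitch <- sqrt(Lx * Ly / n / (sqrt(3) / 2))
  xs <- seq(pitch / 2, Lx, by = pitch)
  ys <- seq(pitch * sqrt(3) / 4, Ly, by = pitch * sqrt(3) / 2)
  g <- expand.grid(x = xs, y = ys)
  odd <- (match(g$y, ys) %% 2) == 0
  g$x[odd] <- g$x[odd] + pitch / 2
  g <- g[g$x <= Lx, ]
  g$x <- pmin(pmax(g$x + stats::runif(nrow(g), -1, 1) * jitter_frac * pitch,
                   0), Lx)
  g$y <- pmin(pmax(g$y + stats::runif(nrow(g), -1, 1) * jitter_frac * pitch,
                   0), Ly)
  g
}

# lateral generator shared by the 3D sheet phantom and the 2D surface phantom:
# tessellation, orientations, border classification/intensities, painted
# pre-noise surface image and ground truth
generate_sheet_lateral <- function(p) {
  nx <- p$grid_size[1]; ny <- p$grid_size[2]
  dx <- p$voxel_spacing[1]; dy <- p$voxel_spacing[2]
  Lx <- (nx - 1) * dx; Ly <- (ny - 1) * dy
  X <- matrix((seq_len(nx) - 1) * dx, nx, ny)
  Y <- matrix((seq_len(ny) - 1) * dy, nx, ny, byrow = TRUE)

  pts <- hex_seed_points(p$n_cells, Lx, Ly, p$seed_jitter)
  sx <- pts$x; sy <- pts$y
  theta <- raxial_deg(length(sx), p$orientation_mean_deg, p$orientation_kappa)

  for (it in seq_len(p$lloyd_iters)) {       # isotropic Lloyd relaxation
    lab <- assign_cells(X, Y, sx, sy, theta, elong = 1)
    g <- as.vector(lab)
    cnt <- tabulate(g, nbins = length(sx))
    sums_x <- rowsum(as.vector(X), g)
    sums_y <- rowsum(as.vector(Y), g)
    present <- as.integer(rownames(sums_x))
    sx[present] <- sums_x[, 1] / cnt[present]
    sy[present] <- sums_y[, 1] / cnt[present]
  }
  labels <- assign_cells(X, Y, sx, sy, theta, elong = p$elongation)

  graph <- build_border_graph(labels, spacing = c(dx, dy))
  et <- graph$edge_table
  sp <- c(dx, dy); pxv <- mean(sp^2) / 12
  orient <- vapply(graph$edges, function(e) {
    xy <- cbind((e$pixels[, 1] - 1) * dx, (e$pixels[, 2] - 1) * dy)
    principal_axis(xy, pxv)$orientation_deg
  }, numeric(1))
  cls <- ifelse(orient < 45, "ML", "RC")
  mult <- if (p$border_cv > 0)
    exp(stats::rnorm(nrow(et), 0, p$border_cv)) else rep(1, nrow(et))
  base <- ifelse(cls == "ML",
                 p$border_anisotropy_a * p$border_intensity,
                 p$border_intensity)
  edge_int <- base * mult
  len <- vapply(graph$edges, function(e) {
    xy <- cbind((e$pixels[, 1] - 1) * dx, (e$pixels[, 2] - 1) * dy)
    pa <- principal_axis(xy, pxv)
    u <- c(cos(pa$orientation_deg * pi / 180),
           sin(pa$orientation_deg * pi / 180))
    diff(range(xy %*% u)) + mean(sp)
  }, numeric(1))

  # paint: interior everywhere, then RC borders, then ML borders, each border
  # pixel set dilated by 1 px (the same capture region the analysis measures)
  paint <- matrix(p$interior_intensity, nx, ny)
  pclass <- matrix(1L, nx, ny)       # 1 interior, 2 RC, 3 ML
  for (pass in c("RC", "ML")) {
    for (e in which(cls == pass)) {
      idx <- dilate_px(graph$edges[[e]]$pixels, nx, ny)
      paint[idx] <- edge_int[e]
      pclass[idx] <- if (pass == "ML") 3L else 2L
    }
  }

  # programmed per-cell ML:RC ratio from the painted border intensities
  ratios <- vapply(names(graph$cell_edges), function(cl) {
    eids <- graph$cell_edges[[cl]]
    ml <- eids[cls[eids] == "ML"]; rc <- eids[cls[eids] == "RC"]
    if (length(ml) == 0L || length(rc) == 0L) return(NA_real_)
    stats::weighted.mean(edge_int[ml], len[ml]) /
      stats::weighted.mean(edge_int[rc], len[rc])
  }, numeric(1))

  cells_present <- as.integer(names(graph$cell_edges))
  list(labels = labels, graph = graph,
       cell_table = data.frame(
         label = cells_present,
         seed_ml_um = sx[cells_present], seed_rc_um = sy[cells_present],
         orientation_axial_deg = theta[cells_present] %% 180,
         orientation_deg = fold_angle(theta[cells_present])),
       border_table = data.frame(
         edge_id = et$edge_id, cell_a = et$cell_a, cell_b = et$cell_b,
         orientation_deg = orient, class = cls, intensity = edge_int,
         length_um = len, n_px = et$n_px),
       paint = paint, paint_class = pclass,
       per_cell_true_ratio = data.frame(
         label = cells_present, true_ratio = ratios[as.character(cells_present)]))
}

#' Generate a ground-truthed curved epithelial sheet stack
#'
#' Renders a 3D confocal-like stack: the brightest thin shell follows a
#' sinusoidal surface height field and carries a Voronoi-like tessellation of
#' elongated cells (per-cell long axes drawn from a folded von Mises
#' distribution); border voxels classified mediolateral carry
#' `border_anisotropy_a` times the intensity of rostrocaudal ones; a dimmer
#' second layer sits `deep_layer_offset_um` below the surface; Gaussian noise
#' (clipped at zero) is added last. The exact ground truth (surface depth map,
#' label map, per-cell orientations and programmed ratios, border classes,
#' painted voxel classes, layer masks) is returned alongside.
#'
#' @param params a [sheet_phantom_params()].
#' @return list with `stack` (an [image_stack()], canonical `(ml, rc, dv)`
#'   order) and `truth` (class `phantom_truth`).
#' @export
generate_sheet_stack <- function(params) {
  stopifnot(inherits(params, "sheet_phantom_params"))
  p <- params
  run_seeded(p$seed, {
    nx <- p$grid_size[1]; ny <- p$grid_size[2]; nz <- p$grid_size[3]
    dz <- p$voxel_spacing[3]
    lat <- generate_sheet_lateral(p)

    dx <- p$voxel_spacing[1]; dy <- p$voxel_spacing[2]
    X <- matrix((seq_len(nx) - 1) * dx, nx, ny)
    Y <- matrix((seq_len(ny) - 1) * dy, nx, ny, byrow = TRUE)
    depth <- p$surface_base_um + p$surface_amplitude_um *
      (1 + sin(2 * pi * X / p$surface_wavelength_um) *
           sin(2 * pi * Y / p$surface_wavelength_um)) / 2

    n_layer <- max(1L, round(p$layer_thickness_um / dz))
    k0 <- round(depth / dz) + 1L
    deep_off <- round(p$deep_layer_offset_um / dz)
    k_need <- max(k0) + n_layer - 1L +
      if (p$deep_layer_intensity > 0) deep_off + n_layer - 1L else 0L
    if (k_need > nz)
      stop("grid too small: surface amplitude + layers need ", k_need,
           " dorsoventral slices but grid has ", nz)

    vol <- array(0, c(nx, ny, nz))
    layer_mask <- array(FALSE, c(nx, ny, nz))
    ii <- as.vector(row(depth)); jj <- as.vector(col(depth))
    for (off in seq_len(n_layer) - 1L) {
      idx3 <- cbind(ii, jj, as.vector(k0) + off)
      vol[idx3] <- as.vector(lat$paint)
      layer_mask[idx3] <- TRUE
    }

    deep_mask <- array(FALSE, c(nx, ny, nz))
    if (p$deep_layer_intensity > 0) {
      shift <- max(1L, round(sqrt(nx * ny / p$n_cells) / 2))
      roll <- function(m) m[c((shift + 1):nx, 1:shift),
                            c((shift + 1):ny, 1:shift)]
      deep_paint <- ifelse(roll(lat$paint_class) >= 2L,
                           p$deep_layer_intensity,
                           0.5 * p$deep_layer_intensity)
      for (off in seq_len(n_layer) - 1L) {
        idx3 <- cbind(ii, jj, as.vector(k0) + deep_off + off)
        vol[idx3] <- as.vector(deep_paint)
        deep_mask[idx3] <- TRUE
      }
    }

    if (p$noise_sd > 0)
      vol <- pmax(vol + stats::rnorm(length(vol), 0, p$noise_sd), 0)

    truth <- structure(list(
      true_surface_depth = depth,
      cell_labels = lat$labels,
      cell_table = lat$cell_table,
      cell_orientations_deg = stats::setNames(lat$cell_table$orientation_deg,
                                              lat$cell_table$label),
      border_classes = lat$border_table,
      per_cell_true_ratio = lat$per_cell_true_ratio,
      surface_intensity = lat$paint,
      paint_class = lat$paint_class,
      layer_mask = layer_mask,
      deep_mask = deep_mask,
      params = p), class = "phantom_truth")

    list(stack = image_stack(vol, p$voxel_spacing, AXIS_ROLES), truth = truth)
  })
}

#' Generate the 2D apical-surface phantom directly
#'
#' Renders only the lateral (projected) surface image of the sheet phantom -
#' the painted tessellation plus noise - skipping the 3D stack. Shares the
#' lateral generator (and hence the ground truth semantics) with
#' [generate_sheet_stack()]; used where many embryos are simulated and only
#' the projected-surface analysis is under study.
#'
#' @param params a [sheet_phantom_params()].
#' @return list with `image` (matrix, `(ml, rc)`), `spacing`, and `truth`
#'   (label map, border classes, programmed ratios).
#' @export
phantom_surface_image <- function(params) {
  stopifnot(inherits(params, "sheet_phantom_params"))
  p <- params
  run_seeded(p$seed, {
    lat <- generate_sheet_lateral(p)
    img <- lat$paint
    if (p$noise_sd > 0)
      img <- pmax(img + stats::rnorm(length(img), 0, p$noise_sd), 0)
    truth <- structure(list(
      cell_labels = lat$labels, cell_table = lat$cell_table,
      cell_orientations_deg = stats::setNames(lat$cell_table$orientation_deg,
                                              lat$cell_table$label),
      border_classes = lat$border_table,
      per_cell_true_ratio = lat$per_cell_true_ratio,
      surface_intensity = lat$paint, paint_class = lat$paint_class,
      params = p), class = "phantom_truth")
    list(image = img, spacing = p$voxel_spacing[1:2], truth = truth)
  })
}
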