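# shared fixtures, all generated in code

# filled ellipse mask: semi-axes a >= b in pixels, long axis at theta_deg
# (dim 1 = ml convention, matching measure_cells)
render_ellipse_mask <- function(theta_deg, a, b, n = 2 * ceiling(a) + 11) {
  ctr <- (n + 1) / 2
  i <- matrix(seq_len(n), n, n) - ctr
  j <- t(matrix(seq_len(n), n, n)) - ctr
  th <- theta_deg * pi / 180
  u <- i * cos(th) + j * sin(th)
  v <- -i * sin(th) + j * cos(th)
  ((u / a)^2 + (v / b)^2) <= 1
}

# brute-force Otsu threshold over a 256-bin histogram: maximise between-class
# variance by exhaustive search (independent oracle for binarise)
otsu_brute <- function(x, levels = 256) {
  rng <- range(x)
  h <- tabulate(pmin(floor((x - rng[1]) / diff(rng) * levels) + 1L, levels),
                nbins = levels)
  p <- h / sum(h)
  mu <- cumsum(p * seq_len(levels))
  w <- cumsum(p)
  mu_t <- mu[levels]
  sb <- (mu_t * w - mu)^2 / (w * (1 - w))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1] + k / levels * diff(rng)
}

# label map of an r x c grid of square cells of side s (known adjacency:
# r*(c-1) + c*(r-1) shared borders)
grid_label_map <- function(r, c, s = 8L) {
  row_lab <- rep(seq_len(r), each = s)
  col_lab <- rep(seq_len(c), each = s)
  outer(row_lab, (col_lab - 1) * r, "+")
}

# quiet 2D-path embryo score from a phantom parameter set
phantom_embryo_score <- function(params, min_cells = 35L) {
  ph <- phantom_surface_image(params)
  g <- build_border_graph(ph$truth$cell_labels, ph$spacing)
  m <- measure_borders(g, ph$image)
  r <- suppressMessages(cell_enrichment_ratios(g, m))
  embryo_enrichment_score(r, min_cells = min_cells)
}

# full 3D-path per-cell ratios: generate, peel, project, measure
phantom_ratios_3d <- function(params) {
  ph <- generate_sheet_stack(params)
  ex <- extract_surface(ph$stack)
  proj <- surface_project(ex$peeled)
  g <- build_border_graph(ph$truth$cell_labels, params$voxel_spacing[1:2])
  m <- measure_borders(g, proj$image)
  suppressMessages(cell_enrichment_ratios(g, m))
}

axial_abs_diff <- function(a, b) pmin(abs(a - b), 180 - abs(a - b))
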