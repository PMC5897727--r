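#' Fold an angle into the [0, 90] degree mediolateral/rostrocaudal convention
#'
#' All orientations in this package assume symmetry around the dorsoventral
#' axis: an angle and its reflection are equivalent, so every angle is folded
#' to `[0, 90]` with 0 = mediolateral (ML) and 90 = rostrocaudal (RC).
#' Folding is idempotent.
#'
#' @param theta_deg numeric vector of angles in degrees (any real value).
#' @return angles in `[0, 90]`.
#' @export
fold_angle <- function(theta_deg) {
  t <- theta_deg %% 180
  pmin(t, 180 - t)
}

#' Circular mean of axial (orientation) data
#'
#' Orientations are axis-like (theta and theta + 180 identical), so the mean
#' is computed on doubled angles and halved, then folded to `[0, 90]`.
#'
#' @param theta_deg orientations in degrees.
#' @return mean orientation in `[0, 90]` degrees.
#' @export
axial_mean_deg <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  m <- atan2(mean(sin(a)), mean(cos(a))) / 2 * 180 / pi
  fold_angle(m)
}

#' Circular dispersion (1 - mean resultant length) of axial data
#'
#' 0 for perfectly aligned orientations, approaching 1 for uniform ones.
#'
#' @param theta_deg orientations in degrees.
#' @return dispersion in `[0, 1]`.
#' @export
axial_dispersion <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  1 - sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

# principal-axis orientation (degrees, folded) of a set of (ml, rc) um points,
# with an optional isotropic per-point variance (pixel footprint) added to the
# diagonal. Returns list(orientation_deg, var_major, var_minor).
principal_axis <- function(xy, point_var = 0) {
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  dx <- xy[, 1] - cx;  dy <- xy[, 2] - cy
  mu20 <- mean(dx * dx) + point_var
  mu02 <- mean(dy * dy) + point_var
  mu11 <- mean(dx * dy)
  common <- (mu20 + mu02) / 2
  delta <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  list(orientation_deg = fold_angle(theta),
       var_major = common + delta, var_minor = max(common - delta, 0),
       centroid = c(cx, cy))
}

#' Per-cell shape and orientation morphometry from a label map
#'
#' Fits the second-central-moment-equivalent ellipse to each labelled cell of
#' a segmented map and reports area, aspect ratio, roundness and folded
#' long-axis orientation (0 = ML, 90 = RC). Cells touching the image edge are
#' excluded (their shape is truncated), as are cells below `min_px` pixels.
#' Near-round cells (aspect ratio < 1.1) keep their orientation but are
#' flagged `degenerate`, since the long axis of a circle is arbitrary.
#'
#' @param labels integer matrix, dimension 1 = mediolateral, dimension 2 =
#'   rostrocaudal; 0 is background.
#' @param spacing um per pixel for the two lateral axes.
#' @param roi_mask optional logical matrix restricting the analysis; a cell is
#'   analysed when its centroid pixel count intersects the mask.
#' @param min_px minimum cell size in pixels (smaller cells are skipped with a
#'   message).
#' @return data.frame with one row per analysed cell: `label`, `n_px`,
#'   `area_um2`, `centroid_ml_um`, `centroid_rc_um`, `aspect_ratio`,
#'   `roundness`, `orientation_axial_deg` (unfolded axis in `[0, 180)`, the
#'   representation circular statistics need), `orientation_deg` (folded),
#'   `degenerate`.
#' @export
measure_cells <- function(labels, spacing = c(1, 1), roi_mask = NULL,
                          min_px = 5L) {
  stopifnot(is.matrix(labels), all(spacing > 0))
  idx <- which(labels > 0)
  if (length(idx) == 0L) stop("label map contains no cells")
  nr <- nrow(labels)
  i <- (idx - 1L) %% nr + 1L
  j <- (idx - 1L) %/% nr + 1L
  lab <- labels[idx]
  x <- (i - 1) * spacing[1]   # ml, um
  y <- (j - 1) * spacing[2]   # rc, um

  on_edge <- i == 1L | i == nr | j == 1L | j == ncol(labels)
  edge_labels <- unique(lab[on_edge])
  in_roi_labels <- if (is.null(roi_mask)) unique(lab) else
    unique(lab[roi_mask[idx]])

  g <- factor(lab)
  n <- as.vector(rowsum(rep(1, length(lab)), g))
  sx <- as.vector(rowsum(x, g)); sy <- as.vector(rowsum(y, g))
  sxx <- as.vector(rowsum(x * x, g)); syy <- as.vector(rowsum(y * y, g))
  sxy <- as.vector(rowsum(x * y, g))
  lev <- as.integer(levels(g))

  cx <- sx / n; cy <- sy / n
  pxv <- mean(spacing^2) / 12      # pixel footprint variance
  mu20 <- sxx / n - cx^2 + pxv
  mu02 <- syy / n - cy^2 + pxv
  mu11 <- sxy / n - cx * cy
  common <- (mu20 + mu02) / 2
  delta <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- common + delta; l2 <- pmax(common - delta, 1e-12)
  semi_major <- 2 * sqrt(l1)
  area <- n * prod(spacing)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi

  out <- data.frame(
    label = lev, n_px = n, area_um2 = area,
    centroid_ml_um = cx, centroid_rc_um = cy,
    aspect_ratio = sqrt(l1 / l2),
    roundness = pmin(area / (pi * semi_major^2), 1),
    orientation_axial_deg = theta %% 180,   # unfolded axis, for circular stats
    orientation_deg = fold_angle(theta))
  out$degenerate <- out$aspect_ratio < 1.1

  small <- out$n_px < min_px
  if (any(small))
    message(sum(small), " cell(s) below ", min_px, " px skipped: labels ",
            paste(out$label[small], collapse = ", "))
  keep <- !small & !(out$label %in% edge_labels) & out$label %in% in_roi_labels
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no analysable cells (all too small or on edge)")
  rownames(out) <- NULL
  out
}

#' Orientation of a cell division from its daughter-nucleus centroids
#'
#' The division angle is the folded angle of the displacement between the two
#' daughter-nucleus centroids in the (ML, RC) plane: 0 = division along the
#' mediolateral axis, 90 = along the rostrocaudal axis. Symmetric in the two
#' centroids.
#'
#' @param centroid_1,centroid_2 numeric length-2 um coordinates `(ml, rc)`.
#' @return angle in degrees, `[0, 90]`.
#' @export
division_angle <- function(centroid_1, centroid_2) {
  d <- as.numeric(centroid_2) - as.numeric(centroid_1)
  if (all(d == 0)) stop("daughter centroids must be distinct")
  fold_angle(atan2(d[2], d[1]) * 180 / pi)
}

#' Restrict analysis to a band of cells around the dorsal midline
#'
#' Mirrors the analysed region of surface-ectoderm morphometry: only cells
#' within about `half_width_cells` median cell diameters on either side of
#' the midline are retained, because tissue curvature distorts apparent cell
#' shape further laterally.
#'
#' @param labels integer label matrix (dim 1 = ML).
#' @param spacing um per pixel.
#' @param midline_ml_um mediolateral position of the midline, um.
#' @param half_width_cells band half-width in median cell diameters (default
#'   6). 0 selects only cells whose pixels straddle the midline.
#' @return logical mask matrix covering the selected cells.
#' @export
midline_roi <- function(labels, spacing = c(1, 1), midline_ml_um,
                        half_width_cells = 6) {
  extent_ml <- (nrow(labels) - 1) * spacing[1]
  if (midline_ml_um < 0 || midline_ml_um > extent_ml) {
    warning("midline (", midline_ml_um, " um) lies outside the image [0, ",
            round(extent_ml, 1), "] um; empty ROI returned")
    return(matrix(FALSE, nrow(labels), ncol(labels)))
  }
  idx <- which(labels > 0)
  i <- (idx - 1L) %% nrow(labels) + 1L
  lab <- labels[idx]
  x <- (i - 1) * spacing[1]
  if (half_width_cells == 0) {
    rng <- vapply(split(x, lab), range, numeric(2))
    sel <- as.integer(colnames(rng))[rng[1, ] <= midline_ml_um &
                                     rng[2, ] >= midline_ml_um]
  } else {
    g <- factor(lab)
    n <- as.vector(rowsum(rep(1, length(lab)), g))
    cx <- as.vector(rowsum(x, g)) / n
    diam <- 2 * sqrt(n * prod(spacing) / pi)
    sel <- as.integer(levels(g))[abs(cx - midline_ml_um) <=
                                 half_width_cells * stats::median(diam)]
  }
  matrix(labels %in% sel, nrow(labels), ncol(labels))
}
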