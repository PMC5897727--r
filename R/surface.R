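#' Binarise an image stack
#'
#' Thresholds the whole stack either at a fixed intensity or at the Otsu
#' threshold computed from a 256-bin histogram of all voxels (the default used
#' by the surface-subtraction pipeline). A voxel is foreground when its
#' intensity exceeds the threshold.
#'
#' @param stack an [image_stack()] (a bare array is also accepted).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity; required when `method = "fixed"`.
#' @return logical array of the same shape, with attribute `"threshold"`.
#' @export
binarise <- function(stack, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  x <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' requires `threshold`")
    thr <- threshold
  } else {
    rng <- range(x)
    if (diff(rng) == 0)
      stop("degenerate histogram: all voxels equal, Otsu threshold is ",
           "undefined; the all-false fallback would discard the image - ",
           "supply a fixed threshold instead")
    # EBImage's Otsu works on [0,1] and thresholds 3D images frame-wise;
    # flatten to a single frame for one global threshold, then map back
    xn <- matrix((x - rng[1]) / diff(rng), ncol = 1L)
    thr_n <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = 256)
    thr <- rng[1] + thr_n * diff(rng)
  }
  out <- x > thr
  attr(out, "threshold") <- thr
  out
}

#' Locate the top (most dorsal) tissue surface
#'
#' Scans each dorsoventral column of a binarised stack from the dorsal side
#' (slice index 1) and records the depth, in micrometres, of the first
#' foreground voxel. Columns with no foreground voxel are `NA` (legal:
#' positions with no tissue).
#'
#' @param mask logical 3D array in canonical `(ml, rc, dv)` order, or an
#'   [image_stack()]-shaped list carrying `axis_roles` to reorder by.
#' @param spacing_dv micrometres per slice along the dorsoventral axis.
#' @return matrix `(ml, rc)` of depths in um (`(slice - 1) * spacing_dv`),
#'   `NA` where undefined.
#' @export
find_top_surface <- function(mask, spacing_dv = 1) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  m2 <- matrix(aperm(mask, c(3L, 1L, 2L)), nrow = d[3])  # dv x lateral
  first <- apply(m2, 2L, function(col) match(TRUE, col))
  matrix((first - 1) * spacing_dv, nrow = d[1], ncol = d[2])
}

# NA-aware 2D median filter over a (2r+1)^2 window; NAs are ignored within the
# window and a position stays NA only if its whole window is NA.
median_filter_na <- function(m, radius = 2L) {
  if (radius <= 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  stackd <- array(NA_real_, c(nr, nc, nrow(offs)))
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    r_src <- pmin(pmax(seq_len(nr) + dr, 1L), nr)   # replicate edges
    c_src <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    stackd[, , k] <- m[r_src, c_src]
  }
  out <- apply(stackd, c(1L, 2L), function(v)
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  out
}

#' Build a fixed-depth surface band from a depth map
#'
#' Constructs the boolean band mask used for surface subtraction: at each
#' lateral position the band starts at the detected surface voxel (inclusive)
#' and extends ventrally `band_depth_um` micrometres. The depth map is first
#' median-smoothed (default radius 2 lateral positions) to suppress
#' single-column detection spikes. The band depth is converted to slices by
#' rounding half-up, so a 5 um band at a 1 um z-step spans 5 slices.
#'
#' @param depth_map matrix of surface depths in um (`NA` = no tissue).
#' @param dim_dv number of slices along the dorsoventral axis.
#' @param spacing_dv um per slice.
#' @param band_depth_um band thickness in um (default 5, the value used for
#'   surface-ectoderm visualisation).
#' @param smooth_radius median-filter radius in lateral positions (0 = off).
#' @return list of class `surface_band` with `depth_map` (smoothed),
#'   `band_depth_um`, and `band_mask` (logical, canonical `(ml, rc, dv)`).
#' @export
surface_band <- function(depth_map, dim_dv, spacing_dv, band_depth_um = 5,
                         smooth_radius = 2L) {
  stopifnot(band_depth_um > 0, spacing_dv > 0)
  dm <- median_filter_na(depth_map, smooth_radius)
  n_slices <- max(1L, floor(band_depth_um / spacing_dv + 0.5))
  k0 <- round(dm / spacing_dv) + 1L                      # surface slice
  mask <- array(FALSE, c(nrow(dm), ncol(dm), dim_dv))
  kmat <- matrix(rep(seq_len(dim_dv), each = length(dm)),
                 nrow = length(dm))
  k0v <- as.vector(k0)
  inband <- !is.na(k0v) & kmat >= k0v & kmat <= (k0v + n_slices - 1L)
  mask[] <- inband
  structure(list(depth_map = dm, band_depth_um = band_depth_um,
                 band_mask = mask),
            class = "surface_band")
}

#' Mask a stack to its surface band ("surface subtraction")
#'
#' Sets every voxel outside the band to zero and leaves voxels inside it
#' untouched, so the deeper tissue no longer contributes to downstream
#' projections. Peeling is idempotent.
#'
#' @param stack an [image_stack()] in canonical `(ml, rc, dv)` order.
#' @param band a [surface_band()] whose mask matches the stack's dimensions.
#' @return the peeled `image_stack`.
#' @export
peel <- function(stack, band) {
  stopifnot(inherits(stack, "image_stack"), inherits(band, "surface_band"))
  if (!identical(dim(stack$voxels), dim(band$band_mask)))
    stop("band mask dimensions do not match the stack")
  out <- stack
  out$voxels <- stack$voxels * band$band_mask
  out
}

#' Extract the surface band of a stack in one call
#'
#' Convenience wrapper running the reconstruction of the surface-subtraction
#' macro end to end: reslice to canonical order, binarise, scan for the top
#' surface, build the band, peel. Returns the peeled stack together with the
#' intermediates.
#'
#' @param stack an [image_stack()] (any axis order).
#' @param band_depth_um band thickness (um), default 5.
#' @param method,threshold passed to [binarise()].
#' @param smooth_radius passed to [surface_band()].
#' @return list with `peeled` (image_stack), `band` (surface_band),
#'   `threshold` (intensity used).
#' @export
extract_surface <- function(stack, band_depth_um = 5,
                            method = c("otsu", "fixed"), threshold = NULL,
                            smooth_radius = 2L) {
  s <- reslice_canonical(stack)
  mask <- binarise(s, method = method, threshold = threshold)
  dv <- 3L
  dm <- find_top_surface(mask, spacing_dv = s$spacing[dv])
  band <- surface_band(dm, dim_dv = dim(s$voxels)[dv],
                       spacing_dv = s$spacing[dv],
                       band_depth_um = band_depth_um,
                       smooth_radius = smooth_radius)
  list(peeled = peel(s, band), band = band,
       threshold = attr(mask, "threshold"))
}

#' Maximum-intensity projection along the dorsoventral axis
#'
#' @param stack an [image_stack()]; it is resliced to canonical order first.
#' @return list with `image` (matrix, `(ml, rc)`), `spacing` (um per pixel for
#'   the two lateral axes) and `axis_roles`.
#' @export
surface_project <- function(stack) {
  s <- reslice_canonical(stack)
  img <- apply(s$voxels, c(1L, 2L), max)
  list(image = img, spacing = s$spacing[1:2], axis_roles = s$axis_roles[1:2])
}

#' Default two-step contrast-enhancement schedule
#'
#' Rolling-ball background subtraction (radius 30 px) followed by CLAHE with
#' block size 50, 150 histogram bins, maximum slope 3; then the same
#' background subtraction followed by CLAHE with block size 30, 100 bins,
#' slope 3. This is the schedule used to equalise membrane signal in optical
#' cross-sections before manual landmarking.
#'
#' @export
default_clahe_schedule <- function() {
  list(list(rolling_ball_radius = 30, block_size = 50, bins = 150, slope = 3),
       list(rolling_ball_radius = 30, block_size = 30, bins = 100, slope = 3))
}

# rolling-ball background subtraction approximated by grayscale opening with
# a disc structuring element of the given radius
rolling_ball_subtract <- function(img, radius) {
  if (radius <= 0) return(img)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- EBImage::opening(EBImage::Image(img), brush)
  pmax(img - as.matrix(bg), 0)
}

#' Sequential local contrast enhancement (CLAHE) for cross-section viewing
#'
#' Applies an ordered schedule of (rolling-ball background subtraction, CLAHE)
#' steps. Intended only to aid visual landmarking of membrane outlines; never
#' used for intensity quantification. Output is rescaled to `[0, 1]`.
#'
#' @param image numeric matrix.
#' @param schedule list of steps, each a list with `rolling_ball_radius`,
#'   `block_size`, `bins`, `slope`; default [default_clahe_schedule()].
#' @return enhanced matrix in `[0, 1]`, same shape.
#' @export
clahe_enhance <- function(image, schedule = default_clahe_schedule()) {
  stopifnot(is.matrix(image))
  img <- image
  rng <- range(img)
  img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  for (step in schedule) {
    if (step$block_size > min(dim(img)))
      stop("CLAHE block size (", step$block_size,
           ") exceeds image dimension (", min(dim(img)), ")")
    img <- rolling_ball_subtract(img, step$rolling_ball_radius)
    if (diff(range(img)) == 0) next  # constant image: CLAHE is a no-op
    nx <- max(1L, round(nrow(img) / step$block_size))
    ny <- max(1L, round(ncol(img) / step$block_size))
    # the CLAHE implementation needs tile counts dividing the image size;
    # pad by edge replication to the next multiple, enhance, crop back
    nr <- ceiling(nrow(img) / nx) * nx
    nc <- ceiling(ncol(img) / ny) * ny
    pad <- img[pmin(seq_len(nr), nrow(img)), pmin(seq_len(nc), ncol(img))]
    enh <- as.matrix(EBImage::clahe(EBImage::Image(pad / max(pad)),
                                    nx = nx, ny = ny,
                                    bins = step$bins, limit = step$slope))
    img <- enh[seq_len(nrow(img)), seq_len(ncol(img))]
  }
  rng <- range(img)
  if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img
}
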