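# render a Gaussian blob (sigma in um) centred at (cx, cy) um onto img
add_blob <- function(img, cx, cy, sigma, spacing, amplitude = 100) {
  nr <- nrow(img); nc <- ncol(img)
  r_px <- ceiling(4 * sigma / spacing[1]); c_px <- ceiling(4 * sigma / spacing[2])
  i0 <- round(cx / spacing[1]) + 1L; j0 <- round(cy / spacing[2]) + 1L
  ri <- max(1L, i0 - r_px):min(nr, i0 + r_px)
  ci <- max(1L, j0 - c_px):min(nc, j0 + c_px)
  xs <- (ri - 1) * spacing[1] - cx
  ys <- (ci - 1) * spacing[2] - cy
  img[ri, ci] <- img[ri, ci] +
    amplitude * exp(-outer(xs^2, ys^2, "+") / (2 * sigma^2))
  img
}

#' Generate a 2D phantom of dividing-cell daughter nucleus pairs
#'
#' Renders one pair of Gaussian blobs per division event, the pair axis at the
#' programmed angle (0 = mediolateral, 90 = rostrocaudal). Pairs are laid out
#' on a grid with random jitter; if a jitter draw would bring blobs of
#' different events closer than 3 sigma it is retried, and an error is raised
#' after 20 failed attempts. Exact centroid coordinates are returned as
#' ground truth.
#'
#' @param angles_deg programmed division angles, each in `[0, 90]`.
#' @param spacing um per pixel (isotropic), default 0.59.
#' @param seed integer seed.
#' @param separation_um daughter-centroid separation (um).
#' @param sigma_um blob standard deviation (um).
#' @return list with `image` (matrix `(ml, rc)`), `spacing`, and `truth`
#'   (data.frame of centroid pairs and folded angles).
#' @export
generate_division_image <- function(angles_deg, spacing = 0.59, seed = 1L,
                                    separation_um = 12, sigma_um = 1.5) {
  if (any(angles_deg < 0 | angles_deg > 90))
    stop("angles must lie in [0, 90]")
  run_seeded(seed, {
    n <- length(angles_deg)
    cell <- 3 * separation_um
    ncol_grid <- ceiling(sqrt(n))
    nrow_grid <- ceiling(n / ncol_grid)
    Lx <- nrow_grid * cell; Ly <- ncol_grid * cell
    sp <- c(spacing, spacing)
    img <- matrix(0, round(Lx / spacing) + 1L, round(Ly / spacing) + 1L)

    centres <- NULL
    rows <- list()
    for (e in seq_len(n)) {
      gi <- (e - 1) %/% ncol_grid; gj <- (e - 1) %% ncol_grid
      th <- angles_deg[e] * pi / 180
      off <- separation_um / 2 * c(cos(th), sin(th))
      ok <- FALSE
      for (try in 1:20) {
        ctr <- c((gi + 0.5) * cell, (gj + 0.5) * cell) +
          stats::runif(2, -cell / 6, cell / 6)
        c1 <- ctr - off; c2 <- ctr + off
        if (is.null(centres) ||
            min(sqrt(colSums((t(centres) - c1)^2)),
                sqrt(colSums((t(centres) - c2)^2))) > 3 * sigma_um) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place division pair ", e,
                    " without overlap after 20 jitter attempts")
      centres <- rbind(centres, c1, c2)
      img <- add_blob(img, c1[1], c1[2], sigma_um, sp)
      img <- add_blob(img, c2[1], c2[2], sigma_um, sp)
      rows[[e]] <- data.frame(event = e,
                              ml_1 = c1[1], rc_1 = c1[2],
                              ml_2 = c2[1], rc_2 = c2[2],
                              angle_deg = fold_angle(angles_deg[e]))
    }
    list(image = img, spacing = sp, truth = do.call(rbind, rows))
  })
}

#' Recover daughter-centroid pairs from a rendered division image
#'
#' Thresholds at half the maximum, labels connected blobs, computes
#' intensity-weighted centroids and pairs each blob with its nearest
#' neighbour.
#'
#' @param image matrix from [generate_division_image()].
#' @param spacing um per pixel.
#' @return data.frame of paired centroids with the measured folded angle.
#' @export
detect_division_pairs <- function(image, spacing = c(0.59, 0.59)) {
  mask <- image > max(image) / 2
  labs <- EBImage::bwlabel(EBImage::Image(mask))
  lv <- as.vector(as.matrix(labs)); iv <- as.vector(image)
  sel <- lv > 0
  i <- ((which(sel) - 1L) %% nrow(image) + 1L - 1L) * spacing[1]
  j <- ((which(sel) - 1L) %/% nrow(image) + 1L - 1L) * spacing[2]
  w <- iv[sel]; g <- lv[sel]
  cx <- rowsum(i * w, g)[, 1] / rowsum(w, g)[, 1]
  cy <- rowsum(j * w, g)[, 1] / rowsum(w, g)[, 1]
  n <- length(cx)
  used <- logical(n); rows <- list()
  d <- as.matrix(stats::dist(cbind(cx, cy))); diag(d) <- Inf
  for (b in seq_len(n)) {
    if (used[b]) next
    mate <- which.min(ifelse(used, Inf, d[b, ]))
    used[b] <- used[mate] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      ml_1 = cx[b], rc_1 = cy[b], ml_2 = cx[mate], rc_2 = cy[mate],
      angle_deg = division_angle(c(cx[b], cy[b]), c(cx[mate], cy[mate])))
  }
  do.call(rbind, rows)
}

#' Generate a phantom optical cross-section with programmed fold elevation
#'
#' Renders a membrane-like neural-plate cross-section: a smooth apical curve
#' from the left neural fold tip through the ventral apical midline point to
#' the right tip, with the tips at the programmed signed height relative to
#' the midline point (positive = elevated dorsally, negative = everted below
#' it). Landmark coordinates are recorded in ground truth.
#'
#' @param elevation_um signed fold-tip elevation (um).
#' @param width_um mediolateral tip-to-tip distance (um).
#' @param seed integer seed (jitters membrane intensity only).
#' @param spacing um per pixel `(ml, dv)`.
#' @return list with `image` (matrix, dim 1 = ML, dim 2 = DV with dorsal at
#'   increasing index), `spacing`, `truth` (landmarks in um).
#' @export
generate_cross_section <- function(elevation_um, width_um = 120, seed = 1L,
                                   spacing = c(0.59, 1.0)) {
  run_seeded(seed, {
    margin <- 15
    base_dv <- max(10, margin - min(elevation_um, 0))  # keep tips in frame
    Lx <- width_um + 2 * margin
    Ldv <- base_dv + max(elevation_um, 0) + margin
    nr <- round(Lx / spacing[1]) + 1L
    nc <- round(Ldv / spacing[2]) + 1L
    img <- matrix(0, nr, nc)
    mid_ml <- Lx / 2
    half <- width_um / 2
    xs <- seq(mid_ml - half, mid_ml + half, by = spacing[1] / 2)
    dv <- base_dv + elevation_um * ((xs - mid_ml) / half)^2
    ii <- round(xs / spacing[1]) + 1L
    jj <- round(dv / spacing[2]) + 1L
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    img[cbind(ii[ok], jj[ok])] <- 100 + stats::runif(sum(ok), -5, 5)
    truth <- list(
      ventral_apical_midline = c(ml = mid_ml, dv = base_dv),
      fold_tips = rbind(c(ml = mid_ml - half, dv = base_dv + elevation_um),
                        c(ml = mid_ml + half, dv = base_dv + elevation_um)),
      programmed_elevation_um = elevation_um, width_um = width_um)
    list(image = img, spacing = spacing, truth = truth)
  })
}

#' Extract section landmarks (midline point and fold tips) from a rendered
#' cross-section
#'
#' Finds the membrane pixels (above half maximum), takes the leftmost and
#' rightmost occupied mediolateral columns as the fold tips and the occupied
#' pixel at the central column as the ventral apical midline point.
#'
#' @param image matrix from [generate_cross_section()].
#' @param spacing um per pixel `(ml, dv)`.
#' @return list with `ventral_apical_midline` and `fold_tips` (um, `(ml, dv)`).
#' @export
extract_section_landmarks <- function(image, spacing = c(0.59, 1.0)) {
  mask <- image > max(image) / 2
  occ <- which(rowSums(mask) > 0)
  if (length(occ) == 0L) stop("no membrane signal found")
  tip_of <- function(i) {
    js <- which(mask[i, ])
    c(ml = (i - 1) * spacing[1], dv = (mean(js) - 1) * spacing[2])
  }
  left <- tip_of(min(occ)); right <- tip_of(max(occ))
  ctr <- round(mean(range(occ)))
  cand <- ctr + c(0, as.vector(rbind(1:20, -(1:20))))  # nearest occupied col
  cand <- cand[cand >= 1 & cand <= nrow(mask)]
  mid_i <- cand[rowSums(mask)[cand] > 0][1]
  mid <- tip_of(mid_i)
  list(ventral_apical_midline = mid, fold_tips = rbind(left, right))
}

#' Generate a pre/post laser-ablation frame pair with programmed widening
#'
#' Renders two frames of a neuropore-like opening: two bright neural-fold
#' edges whose separation at the rostral canthus (zippering-point level)
#' differs between the frames by the programmed widening (negative values
#' narrow the opening). The canthus level and exact widths are recorded in
#' ground truth.
#'
#' @param pre_width_um edge separation at the canthus before ablation (um).
#' @param widening_um programmed change in width (post - pre, um; may be
#'   negative).
#' @param seed integer seed (edge intensity jitter only).
#' @param length_um rostrocaudal extent of the rendered opening.
#' @param spacing um per pixel `(ml, rc)`.
#' @return list with `pre`, `post` (matrices), `spacing`, `truth`.
#' @export
generate_ablation_pair <- function(pre_width_um = 100, widening_um = 0,
                                   seed = 1L, length_um = 150,
                                   spacing = c(0.83, 0.83)) {
  stopifnot(pre_width_um >= 0, pre_width_um + widening_um >= 0)
  run_seeded(seed, {
    canthus_rc <- 20
    flare <- 0.4                       # caudal divergence of the folds
    Lx <- max(pre_width_um, pre_width_um + widening_um) +
      2 * flare * (length_um - canthus_rc) + 40
    nr <- round(Lx / spacing[1]) + 1L
    nc <- round(length_um / spacing[2]) + 1L
    mid <- Lx / 2
    render <- function(width) {
      img <- matrix(0, nr, nc)
      rc <- (seq_len(nc) - 1) * spacing[2]
      w <- width / 2 + flare * pmax(rc - canthus_rc, 0)
      sel <- rc >= canthus_rc - spacing[2] / 2
      for (side in c(-1, 1)) {
        ii <- round((mid + side * w[sel]) / spacing[1]) + 1L
        jj <- which(sel)
        ok <- ii >= 1 & ii <= nr
        img[cbind(ii[ok], jj[ok])] <- 100 + stats::runif(sum(ok), -5, 5)
      }
      img
    }
    list(pre = render(pre_width_um),
         post = render(pre_width_um + widening_um),
         spacing = spacing,
         truth = list(canthus_rc_um = canthus_rc,
                      pre_width_um = pre_width_um,
                      post_width_um = pre_width_um + widening_um,
                      programmed_widening_um = widening_um))
  })
}

#' Measure the neuropore width of a rendered frame at a rostrocaudal level
#'
#' Finds the bright edge pixels in the row at the requested level, splits them
#' into a left and a right cluster and returns the distance between the
#' cluster centres in micrometres.
#'
#' @param image matrix `(ml, rc)` from [generate_ablation_pair()].
#' @param rc_level_um rostrocaudal level at which to measure (um).
#' @param spacing um per pixel `(ml, rc)`.
#' @return width in um.
#' @export
measure_frame_width <- function(image, rc_level_um, spacing = c(0.83, 0.83)) {
  j <- round(rc_level_um / spacing[2]) + 1L
  col <- image[, j]
  pos <- which(col > max(image) / 2)
  if (length(pos) < 2L) stop("fewer than two edge pixels at the requested level")
  gap <- which.max(diff(pos))
  left <- mean(pos[seq_len(gap)]); right <- mean(pos[(gap + 1):length(pos)])
  (right - left) * spacing[1]
}
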