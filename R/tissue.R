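polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Construct a posterior neuropore outline
#'
#' @param zippering_point um coordinate (length 2) of the rostral fusion
#'   point.
#' @param caudal_extreme um coordinate of the caudal end of the neuropore.
#' @param edge_left,edge_right ordered (rostral to caudal) um point matrices
#'   tracing the two neural fold edges.
#' @param somite_stage,embryo_id,genotype optional metadata.
#' @return list of class `pnp_outline`.
#' @export
pnp_outline <- function(zippering_point, caudal_extreme,
                        edge_left, edge_right,
                        somite_stage = NA, embryo_id = NA, genotype = NA) {
  edge_left <- as.matrix(edge_left); edge_right <- as.matrix(edge_right)
  if (nrow(edge_left) != nrow(edge_right))
    stop("fold edges must be sampled with the same number of points")
  structure(list(zippering_point = as.numeric(zippering_point),
                 caudal_extreme = as.numeric(caudal_extreme),
                 edge_left = edge_left, edge_right = edge_right,
                 somite_stage = somite_stage, embryo_id = embryo_id,
                 genotype = genotype),
            class = "pnp_outline")
}

#' Posterior neuropore length and maximum width
#'
#' Length is the arc distance from the zippering point to the caudal extreme
#' along the midline (the mean of paired edge points); maximum width is the
#' largest separation between paired edge points measured perpendicular to
#' the local midline tangent.
#'
#' @param outline a [pnp_outline()].
#' @return named numeric `c(length_um, max_width_um)`.
#' @export
pnp_dimensions <- function(outline) {
  stopifnot(inherits(outline, "pnp_outline"))
  L <- outline$edge_left; R <- outline$edge_right
  if (nrow(L) == 0L) {
    len <- polyline_length(rbind(outline$zippering_point,
                                 outline$caudal_extreme))
    return(c(length_um = len, max_width_um = 0))
  }
  mid <- (L + R) / 2
  path <- rbind(outline$zippering_point, mid, outline$caudal_extreme)
  len <- polyline_length(path)
  # perpendicular separation relative to the local midline tangent
  widths <- vapply(seq_len(nrow(mid)), function(i) {
    i0 <- max(1L, i - 1L); i1 <- min(nrow(path), i + 2L)
    tang <- path[i1, ] - path[i0, ]
    tl <- sqrt(sum(tang^2))
    d <- R[i, ] - L[i, ]
    if (tl == 0) return(sqrt(sum(d^2)))
    tang <- tang / tl
    abs(d[1] * (-tang[2]) + d[2] * tang[1])
  }, numeric(1))
  c(length_um = len, max_width_um = max(widths))
}

#' Landmarks of an optical cross-section at a fractional neuropore position
#'
#' @param ventral_apical_midline um point `(ml, dv)` of the apical surface at
#'   the midline (median hinge point).
#' @param fold_tips two-row um point matrix of the neural fold tips.
#' @param fraction_of_length fractional position along the neuropore,
#'   in (0, 1) (commonly 0.25, 0.50, 0.75 from the zippering point).
#' @param apical_curve,basal_curve optional ordered um point lists tracing the
#'   apical and basal neuroepithelial surfaces.
#' @return list of class `section_landmarks`.
#' @export
section_landmarks <- function(ventral_apical_midline, fold_tips,
                              fraction_of_length = NA,
                              apical_curve = NULL, basal_curve = NULL) {
  if (!is.na(fraction_of_length) &&
      (fraction_of_length <= 0 || fraction_of_length >= 1))
    stop("fraction_of_length must lie in (0, 1)")
  structure(list(ventral_apical_midline = as.numeric(ventral_apical_midline),
                 fold_tips = as.matrix(fold_tips),
                 fraction_of_length = fraction_of_length,
                 apical_curve = apical_curve, basal_curve = basal_curve),
            class = "section_landmarks")
}

#' Signed neural-fold elevation
#'
#' Mean dorsoventral offset of the two fold tips relative to the ventral
#' apical midline point. Positive values mean the folds are elevated
#' (dorsal to the apical surface); negative values indicate eversion (tips
#' below the apical surface).
#'
#' @param landmarks a [section_landmarks()] (dv is the second coordinate).
#' @return signed elevation in um.
#' @export
fold_elevation <- function(landmarks) {
  stopifnot(inherits(landmarks, "section_landmarks"))
  mean(landmarks$fold_tips[, 2]) - landmarks$ventral_apical_midline[2]
}

#' Basal : apical neuroepithelial length ratio
#'
#' Ratio of the polyline arc length of the basal surface curve to that of the
#' apical surface curve. Values below 1 mean the apical domain is longer than
#' the basal one (the pattern of apical expansion).
#'
#' @param landmarks a [section_landmarks()] with both curves (>= 3 points
#'   each).
#' @return dimensionless ratio.
#' @export
basal_apical_ratio <- function(landmarks) {
  stopifnot(inherits(landmarks, "section_landmarks"))
  a <- landmarks$apical_curve; b <- landmarks$basal_curve
  if (is.null(a) || is.null(b) || nrow(as.matrix(a)) < 3L ||
      nrow(as.matrix(b)) < 3L)
    stop("both apical and basal curves with >= 3 points are required")
  polyline_length(b) / polyline_length(a)
}

#' Neuropore widening after zippering-point laser ablation
#'
#' The change in neuropore width between a pre- and a post-ablation frame,
#' both measured at the pre-ablation zippering-point level (the ablation
#' destroys the landmark, so the pre-ablation level anchors both
#' measurements). Negative values (narrowing) are preserved.
#'
#' @param pre,post widths in um, or rendered frames (matrices) when
#'   `rc_level_um` and `spacing` are supplied.
#' @param rc_level_um pre-ablation zippering-point level (um), for frame
#'   input.
#' @param spacing um per pixel, for frame input.
#' @param somite_stage,embryo_id,genotype optional metadata.
#' @return list of class `ablation_measurement`: `pre_width`, `post_width`,
#'   `widening` (um) plus metadata.
#' @export
ablation_widening <- function(pre, post, rc_level_um = NULL,
                              spacing = c(0.83, 0.83),
                              somite_stage = NA, embryo_id = NA,
                              genotype = NA) {
  if (is.matrix(pre)) {
    if (is.null(rc_level_um))
      stop("frame input requires the pre-ablation zippering level")
    pre_w <- measure_frame_width(pre, rc_level_um, spacing)
    post_w <- measure_frame_width(post, rc_level_um, spacing)
  } else {
    pre_w <- as.numeric(pre); post_w <- as.numeric(post)
  }
  if (pre_w < 0 || post_w < 0) stop("widths must be non-negative")
  structure(list(pre_width = pre_w, post_width = post_w,
                 widening = post_w - pre_w, somite_stage = somite_stage,
                 embryo_id = embryo_id, genotype = genotype),
            class = "ablation_measurement")
}
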