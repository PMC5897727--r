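# neighbourhood offsets (8-connectivity, plus centre)
NBHD9 <- cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))

# labels of the 3x3 neighbourhood of every pixel: matrix n_px x 9, NA outside
neighbour_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- matrix(NA_integer_, nr * nc, 9L)
  for (k in 1:9) {
    dr <- NBHD9[k, 1]; dc <- NBHD9[k, 2]
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    sub <- matrix(NA_integer_, nr, nc)
    sub[ok_r, ok_c] <- labels[rs[ok_r], cs[ok_c]]
    out[, k] <- sub
  }
  out
}

#' Build the cell-adjacency border graph of a segmented epithelium
#'
#' Identifies, for every pair of neighbouring cells, the set of border pixels
#' (pixels whose 8-connected neighbourhood contains exactly those two labels)
#' and the vertices where three or more cells meet. The graph is the substrate
#' for junctional intensity measurements and supracellular profile tracing.
#'
#' @param labels integer matrix (dim 1 = mediolateral, dim 2 = rostrocaudal,
#'   0 = background).
#' @param spacing um per pixel for the two axes.
#' @return object of class `border_graph`: `edges` (list of
#'   `list(id, cells, pixels)` with pixels as an (i, j) matrix; only edges
#'   with at least 2 pixels are kept), `edge_table` (data.frame), `cell_edges`
#'   (edge ids per label), `edge_vertices`/`vertex_edges` (incidence with the
#'   >= 3-cell meeting points), `boundary_labels` (cells touching the image
#'   edge), `labels`, `spacing`.
#' @export
build_border_graph <- function(labels, spacing = c(1, 1)) {
  stopifnot(is.matrix(labels))
  nr <- nrow(labels); nc <- ncol(labels)
  nb <- neighbour_labels(labels)
  own <- as.vector(labels)

  # candidate pixels: some neighbour differs from the pixel's own label
  differs <- rowSums(nb != own, na.rm = TRUE) > 0
  cand <- which(differs & own > 0)

  edge_key <- character(length(cand))
  is_vertex <- logical(length(cand))
  for (q in seq_along(cand)) {
    labs <- nb[cand[q], ]
    labs <- unique(labs[!is.na(labs) & labs > 0])
    if (length(labs) == 2L) {
      edge_key[q] <- paste(min(labs), max(labs), sep = "|")
    } else if (length(labs) >= 3L) {
      is_vertex[q] <- TRUE
    }
  }

  to_ij <- function(idx) cbind(i = (idx - 1L) %% nr + 1L,
                               j = (idx - 1L) %/% nr + 1L)

  keys <- edge_key[edge_key != ""]
  px_by_edge <- split(cand[edge_key != ""], keys)
  px_by_edge <- px_by_edge[lengths(px_by_edge) >= 2L]   # edges need >= 2 px

  edges <- vector("list", length(px_by_edge))
  edge_map <- matrix(0L, nr, nc)                        # pixel -> edge id
  if (length(px_by_edge)) {
    pairs <- do.call(rbind, strsplit(names(px_by_edge), "|", fixed = TRUE))
    for (e in seq_along(px_by_edge)) {
      idx <- px_by_edge[[e]]
      edges[[e]] <- list(id = e,
                         cells = as.integer(pairs[e, ]),
                         pixels = to_ij(idx))
      edge_map[idx] <- e
    }
  }

  # vertices: connected clusters of >= 3-label meeting pixels
  vtx_idx <- cand[is_vertex]
  vertex_pixels <- to_ij(vtx_idx)
  vertex_edges <- list()
  edge_vertices <- rep(list(integer(0)), length(edges))
  if (length(vtx_idx)) {
    vmask <- matrix(0, nr, nc); vmask[vtx_idx] <- 1
    vlab <- EBImage::bwlabel(vmask)
    vids <- as.vector(vlab)[vtx_idx]
    for (v in sort(unique(vids))) {
      pix <- to_ij(vtx_idx[vids == v])
      inc <- integer(0)
      for (p in seq_len(nrow(pix))) {
        ri <- pmin(pmax(pix[p, 1] + (-1:1), 1L), nr)
        ci <- pmin(pmax(pix[p, 2] + (-1:1), 1L), nc)
        inc <- c(inc, edge_map[ri, ci])
      }
      inc <- sort(unique(inc[inc > 0]))
      vertex_edges[[length(vertex_edges) + 1L]] <- inc
      for (e in inc)
        edge_vertices[[e]] <- c(edge_vertices[[e]], length(vertex_edges))
    }
  }

  boundary_labels <- unique(c(labels[1, ], labels[nr, ],
                              labels[, 1], labels[, nc]))
  boundary_labels <- boundary_labels[boundary_labels > 0]

  cells_present <- sort(unique(own[own > 0]))
  cell_edges <- rep(list(integer(0)), length(cells_present))
  names(cell_edges) <- as.character(cells_present)
  for (e in seq_along(edges))
    for (cl in edges[[e]]$cells)
      cell_edges[[as.character(cl)]] <-
        c(cell_edges[[as.character(cl)]], e)

  edge_table <- if (length(edges)) data.frame(
    edge_id = vapply(edges, `[[`, integer(1), "id"),
    cell_a = vapply(edges, function(e) e$cells[1], integer(1)),
    cell_b = vapply(edges, function(e) e$cells[2], integer(1)),
    n_px = vapply(edges, function(e) nrow(e$pixels), integer(1)))
  else data.frame(edge_id = integer(0), cell_a = integer(0),
                  cell_b = integer(0), n_px = integer(0))

  structure(list(edges = edges, edge_table = edge_table,
                 cell_edges = cell_edges, edge_vertices = edge_vertices,
                 vertex_edges = vertex_edges, vertex_pixels = vertex_pixels,
                 boundary_labels = boundary_labels,
                 labels = labels, spacing = spacing),
            class = "border_graph")
}

#' @export
print.border_graph <- function(x, ...) {
  cat("<border_graph> ", length(x$cell_edges), " cells, ",
      length(x$edges), " shared borders, ",
      length(x$vertex_edges), " vertices\n", sep = "")
  invisible(x)
}

# dilate an (i,j) pixel set by one pixel (8-connectivity), clipped to the
# image; returns linear indices
dilate_px <- function(pixels, nr, nc) {
  i <- rep(pixels[, 1], each = 9L) + NBHD9[, 1]
  j <- rep(pixels[, 2], each = 9L) + NBHD9[, 2]
  ok <- i >= 1L & i <= nr & j >= 1L & j <= nc
  unique((j[ok] - 1L) * nr + i[ok])
}

#' Measure orientation, class and junctional intensity of every border
#'
#' Border orientation is the principal axis of the border pixel set, folded to
#' `[0, 90]`; the class is mediolateral (ML) when the orientation is below 45
#' degrees and rostrocaudal (RC) otherwise (exact 45-degree ties are RC).
#' Mean intensity is averaged over the border pixels dilated by one pixel, so
#' the few-pixel-wide junctional signal is captured even with slight
#' segmentation offsets. Pixels whose dilation zone is shared with another
#' border, and pixels around tricellular vertices, are excluded from the
#' average (standard practice in junctional polarity quantification: vertex
#' and shared-zone signal mixes the intensities of differently oriented
#' borders). For very short borders lying entirely between vertices the
#' exclusion is waived rather than returning an empty measurement.
#'
#' @param graph a [build_border_graph()] result.
#' @param intensity numeric matrix, same shape as the label map (e.g. the
#'   surface-subtracted maximum projection).
#' @return data.frame: `edge_id`, `cell_a`, `cell_b`, `orientation_deg`,
#'   `class` ("ML"/"RC"), `mean_intensity`, `length_um`, `n_px`.
#' @export
measure_borders <- function(graph, intensity) {
  stopifnot(inherits(graph, "border_graph"),
            identical(dim(intensity), dim(graph$labels)))
  nr <- nrow(intensity); nc <- ncol(intensity)
  sp <- graph$spacing
  pxv <- mean(sp^2) / 12
  vtx_zone <- if (nrow(graph$vertex_pixels) > 0)
    dilate_px(graph$vertex_pixels, nr, nc) else integer(0)
  cover <- integer(nr * nc)          # how many borders claim each pixel
  for (e in graph$edges) {
    px <- dilate_px(e$pixels, nr, nc)
    cover[px] <- cover[px] + 1L
  }
  contested <- which(cover > 1L)
  res <- lapply(graph$edges, function(e) {
    xy <- cbind((e$pixels[, 1] - 1) * sp[1], (e$pixels[, 2] - 1) * sp[2])
    pa <- principal_axis(xy, point_var = pxv)
    u <- c(cos(pa$orientation_deg * pi / 180),
           sin(pa$orientation_deg * pi / 180))
    proj <- xy %*% u
    px <- dilate_px(e$pixels, nr, nc)
    core <- setdiff(px, c(vtx_zone, contested))
    if (length(core) == 0L) core <- px
    data.frame(edge_id = e$id, cell_a = e$cells[1], cell_b = e$cells[2],
               orientation_deg = pa$orientation_deg,
               mean_intensity = mean(intensity[core]),
               length_um = diff(range(proj)) + mean(sp),
               n_px = nrow(e$pixels))
  })
  out <- do.call(rbind, res)
  out$class <- ifelse(out$orientation_deg < 45, "ML", "RC")
  out[, c("edge_id", "cell_a", "cell_b", "orientation_deg", "class",
          "mean_intensity", "length_um", "n_px")]
}

#' Per-cell mediolateral : rostrocaudal border-intensity ratios
#'
#' For each cell with at least one ML- and one RC-classified border, the ratio
#' of the length-weighted mean intensity of its ML borders to that of its RC
#' borders. Ratios above 1 indicate ML-enriched junctional signal. Cells
#' lacking one class are excluded (never reported as infinite ratios), as are
#' cells touching the image edge by default.
#'
#' @param graph a [build_border_graph()] result.
#' @param measures output of [measure_borders()].
#' @param exclude_boundary drop cells touching the image edge (default TRUE).
#' @param length_weighted weight border means by border length (default TRUE;
#'   unweighted means overweight short borders).
#' @return data.frame `label`, `n_ml`, `n_rc`, `ratio`; excluded cells are
#'   listed in `attr(, "excluded")`.
#' @export
cell_enrichment_ratios <- function(graph, measures, exclude_boundary = TRUE,
                                   length_weighted = TRUE) {
  labs <- as.integer(names(graph$cell_edges))
  if (exclude_boundary) labs <- setdiff(labs, graph$boundary_labels)
  rows <- list(); excluded <- integer(0)
  for (cl in labs) {
    eids <- graph$cell_edges[[as.character(cl)]]
    m <- measures[measures$edge_id %in% eids, , drop = FALSE]
    ml <- m[m$class == "ML", , drop = FALSE]
    rc <- m[m$class == "RC", , drop = FALSE]
    if (nrow(ml) == 0L || nrow(rc) == 0L) { excluded <- c(excluded, cl); next }
    w_ml <- if (length_weighted) ml$length_um else rep(1, nrow(ml))
    w_rc <- if (length_weighted) rc$length_um else rep(1, nrow(rc))
    rows[[length(rows) + 1L]] <- data.frame(
      label = cl, n_ml = nrow(ml), n_rc = nrow(rc),
      ratio = stats::weighted.mean(ml$mean_intensity, w_ml) /
              stats::weighted.mean(rc$mean_intensity, w_rc))
  }
  if (length(excluded))
    message(length(excluded),
            " cell(s) lacking an ML or RC border excluded: ",
            paste(excluded, collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), n_ml = integer(0), n_rc = integer(0),
               ratio = numeric(0))
  attr(out, "excluded") <- excluded
  out
}

#' Per-embryo F-actin enrichment score
#'
#' The enrichment score of an embryo is the median of its per-cell ML:RC
#' ratios; scores above 1 indicate mediolaterally polarised junctional
#' F-actin. A score is flagged invalid when fewer than `min_cells` cells
#' contributed (default 35, matching the >35 cells measured per embryo).
#'
#' @param ratios numeric vector of per-cell ratios, or the data.frame from
#'   [cell_enrichment_ratios()].
#' @param min_cells minimum number of cells for a valid score.
#' @return list of class `enrichment_result`: `embryo_score`, `n_cells`,
#'   `valid`.
#' @export
embryo_enrichment_score <- function(ratios, min_cells = 35L) {
  r <- if (is.data.frame(ratios)) ratios$ratio else as.numeric(ratios)
  if (any(r <= 0)) stop("ratios must be positive")
  structure(list(embryo_score = stats::median(r), n_cells = length(r),
                 valid = length(r) >= min_cells),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("embryo enrichment score %.3f (n = %d cells%s)\n",
              x$embryo_score, x$n_cells,
              if (x$valid) "" else "; below min_cells - not valid"))
  invisible(x)
}

#' Detect supracellular enriched-border profiles
#'
#' A border is "enriched" when its mean intensity exceeds `k` times the median
#' border intensity of the image. Profiles are maximal simple chains of
#' enriched borders that share vertices: starting from the brightest unused
#' enriched border, the chain is greedily extended at both ends, choosing at
#' each vertex the enriched continuation with the smallest change in
#' orientation. Every profile spans at least two cells (a single shared border
#' already does). Profile orientation is the folded principal axis of the
#' pooled chain pixels.
#'
#' @param graph a [build_border_graph()] result.
#' @param measures output of [measure_borders()].
#' @param k enrichment threshold multiplier (> 1); default 1.5.
#' @return data.frame `profile_id`, `n_edges`, `n_cells`, `orientation_deg`,
#'   `length_um`, with the edge chains in `attr(, "chains")`. Zero rows when
#'   nothing is enriched.
#' @export
detect_profiles <- function(graph, measures, k = 1.5) {
  stopifnot(k > 1)
  med <- stats::median(measures$mean_intensity)
  enr <- measures$edge_id[measures$mean_intensity > k * med]
  empty <- data.frame(profile_id = integer(0), n_edges = integer(0),
                      n_cells = integer(0), orientation_deg = numeric(0),
                      length_um = numeric(0))
  attr(empty, "chains") <- list()
  if (length(enr) == 0L) return(empty)

  ord <- enr[order(-measures$mean_intensity[match(enr, measures$edge_id)])]
  used <- logical(length(graph$edges))
  orient <- measures$orientation_deg[match(seq_along(graph$edges),
                                           measures$edge_id)]
  chains <- list()

  extend <- function(chain, vertices_seen) {
    repeat {
      grew <- FALSE
      for (end in c(1L, 2L)) {
        eid <- if (end == 1L) chain[1] else chain[length(chain)]
        for (v in setdiff(graph$edge_vertices[[eid]], vertices_seen)) {
          cand <- setdiff(graph$vertex_edges[[v]], chain)
          cand <- cand[cand %in% enr & !used[cand]]
          if (length(cand) == 0L) { vertices_seen <- c(vertices_seen, v); next }
          turn <- abs(orient[cand] - orient[eid])
          turn <- pmin(turn, 180 - turn)
          nxt <- cand[order(turn, cand)][1]
          chain <- if (end == 1L) c(nxt, chain) else c(chain, nxt)
          used[nxt] <<- TRUE
          vertices_seen <- c(vertices_seen, v)
          grew <- TRUE
          break
        }
        if (grew) break
      }
      if (!grew) return(chain)
    }
  }

  for (seed in ord) {
    if (used[seed]) next
    used[seed] <- TRUE
    chains[[length(chains) + 1L]] <- extend(seed, integer(0))
  }

  sp <- graph$spacing
  rows <- lapply(seq_along(chains), function(p) {
    ch <- chains[[p]]
    px <- do.call(rbind, lapply(graph$edges[ch], `[[`, "pixels"))
    xy <- cbind((px[, 1] - 1) * sp[1], (px[, 2] - 1) * sp[2])
    cells <- unique(unlist(lapply(graph$edges[ch], `[[`, "cells")))
    data.frame(profile_id = p, n_edges = length(ch), n_cells = length(cells),
               orientation_deg =
                 principal_axis(xy, mean(sp^2) / 12)$orientation_deg,
               length_um =
                 sum(measures$length_um[match(ch, measures$edge_id)]))
  })
  out <- do.call(rbind, rows)
  attr(out, "chains") <- chains
  out
}
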