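#' Write an image stack as a multi-page TIFF with a spacing sidecar
#'
#' Voxel data go to a 32-bit float multi-page TIFF (one page per dorsoventral
#' slice after reslicing to canonical order); spacing and axis roles go to a
#' YAML sidecar `<path>.yaml`, so a write/read round trip restores the stack
#' exactly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  s <- reslice_canonical(stack)
  # TIFF storage is defined on [0, 1]; intensities are arbitrary units, so
  # normalise by the recorded scale and restore it on read
  scale <- max(s$voxels, 1e-12)
  pages <- lapply(seq_len(dim(s$voxels)[3]),
                  function(k) s$voxels[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(spacing_um = as.list(s$spacing),
                        axis_roles = as.list(s$axis_roles),
                        intensity_scale = scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.yaml` must hold the spacing metadata.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path))
    stop("missing spacing sidecar ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  if (!is.null(meta$intensity_scale)) vol <- vol * meta$intensity_scale
  image_stack(vol, unlist(meta$spacing_um), unlist(meta$axis_roles))
}

#' Write / read an integer cell label map as 16-bit TIFF
#'
#' @param labels integer matrix (values below 65536).
#' @param path TIFF path.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  mf <- tiff::readTIFF(path)          # normalised to [0,1]
  v <- mf * 65535
  if (max(abs(v - round(v))) > 1e-3)
    stop("label TIFF holds floating-point values; cell label maps must be ",
         "integer-valued - re-export the segmentation as 8/16-bit integer")
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

ANNOTATION_COLUMNS <- c("embryo_id", "role", "ml_um")

#' Read a landmark/annotation table
#'
#' Annotation CSVs carry one landmark point per row with at least the columns
#' `embryo_id`, `role` (e.g. "zippering_point", "fold_tip", "midline") and
#' coordinates in um (`ml_um` plus `rc_um` and/or `dv_um`). Missing required
#' columns raise a schema error naming the column.
#'
#' @param path CSV path.
#' @param required_roles role tags that must be present.
#' @return data.frame.
#' @export
read_annotations <- function(path, required_roles = character(0)) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols))
    stop("annotation schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  missing_roles <- setdiff(required_roles, unique(df$role))
  if (length(missing_roles))
    stop("annotation schema error: missing role tag(s) ",
         paste(missing_roles, collapse = ", "))
  df
}

#' Write an output table with provenance header
#'
#' Every output CSV starts with comment lines recording the package version
#' and a hash of the run configuration, so results stay attributable to the
#' exact settings that produced them.
#'
#' @param df data.frame.
#' @param path output CSV path.
#' @param config configuration object to hash (may be NULL).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pnpolarity %s",
                     as.character(utils::packageVersion("pnpolarity"))), con)
  writeLines(sprintf("# config_hash %s", config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Hash a run configuration
#'
#' @param config any R object (NULL hashes to the empty-config hash).
#' @return character hash.
#' @export
config_hash <- function(config) rlang::hash(config)
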