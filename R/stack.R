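AXIS_ROLES <- c("mediolateral", "rostrocaudal", "dorsoventral")
LATERAL_ROLES <- c("mediolateral", "rostrocaudal")

#' Construct a 3D image stack with physical spacing and anatomical axis roles
#'
#' A stack is a 3D intensity array in which each array dimension is labelled
#' with an embryonic axis role (mediolateral, rostrocaudal, dorsoventral) and a
#' physical voxel spacing in micrometres. Along the dorsoventral axis, index 1
#' is the most dorsal slice by convention; depths are measured ventrally from
#' it.
#'
#' @param voxels numeric 3D array of intensities.
#' @param spacing numeric length-3 vector, micrometres per voxel along each
#'   array dimension (must be strictly positive).
#' @param axis_roles character length-3 vector assigning one of
#'   `"mediolateral"`, `"rostrocaudal"`, `"dorsoventral"` to each array
#'   dimension; each role must appear exactly once.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing, axis_roles) {
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (um/voxel)")
  axis_roles <- as.character(axis_roles)
  if (length(axis_roles) != 3L || !setequal(axis_roles, AXIS_ROLES) ||
      anyDuplicated(axis_roles))
    stop("`axis_roles` must assign each of ", paste(AXIS_ROLES, collapse = ", "),
         " to exactly one axis")
  structure(list(voxels = voxels, spacing = spacing, axis_roles = axis_roles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<image_stack> ", paste(d, collapse = " x "), " voxels\n", sep = "")
  for (i in 1:3)
    cat(sprintf("  dim %d: %-13s %d voxels @ %.3g um\n",
                i, x$axis_roles[i], d[i], x$spacing[i]))
  invisible(x)
}

axis_index <- function(stack, role) {
  i <- match(role, stack$axis_roles)
  if (is.na(i)) stop("no axis with role '", role, "'")
  i
}

#' Digitally reslice a stack to a new axis order
#'
#' Transposes the voxel grid so that its dimensions carry the requested axis
#' roles in the requested order, updating spacing accordingly. Reslicing is a
#' pure permutation: reslicing back to the original order restores the stack
#' bit for bit.
#'
#' @param stack an [image_stack()].
#' @param new_axis_roles character length-3: the desired role of each output
#'   dimension; must be a permutation of the stack's roles.
#' @return the resliced `image_stack`.
#' @export
reslice <- function(stack, new_axis_roles) {
  stopifnot(inherits(stack, "image_stack"))
  new_axis_roles <- as.character(new_axis_roles)
  if (!setequal(new_axis_roles, stack$axis_roles) ||
      length(new_axis_roles) != 3L || anyDuplicated(new_axis_roles))
    stop("`new_axis_roles` must be a permutation of the stack's axis roles")
  perm <- match(new_axis_roles, stack$axis_roles)
  image_stack(aperm(stack$voxels, perm), stack$spacing[perm], new_axis_roles)
}

# canonical order used internally: (ml, rc, dv)
reslice_canonical <- function(stack) reslice(stack, AXIS_ROLES)
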