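#' SUV volume, binary mask and labelled mask containers
#'
#' An `suv_volume` is a 3D scalar grid of standardized uptake values (SUV,
#' dimensionless, g/mL-normalized) together with its world geometry: the
#' voxel spacing in mm per axis (possibly anisotropic) and the world
#' coordinates (mm) of the centre of voxel `(1,1,1)`. Voxel centres sit at
#' `origin + (index - 1) * spacing`. Masks derived from a volume carry the
#' identical geometry so that mesh coordinates are well defined.
#'
#' @param values 3D numeric array of SUV values (finite, non-negative).
#' @param spacing numeric length-3, mm per axis, all positive.
#' @param origin numeric length-3, mm world coordinates of the first voxel
#'   centre. Default `c(0, 0, 0)`.
#' @return An object of class `suv_volume`.
#' @examples
#' v <- suv_volume(array(1, c(8, 8, 8)), spacing = c(1, 1, 3))
#' dim(v$values)
#' @export
suv_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("SUV values must be finite and >= 0.")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm).")
  }
  if (length(origin) != 3L) abort("`origin` must have length 3.")
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "suv_volume"
  )
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<suv_volume> %d x %d x %d voxels, spacing %s mm, SUVmax %.3f\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    max(x$values)
  ))
  invisible(x)
}

new_mask <- function(values, geometry, class) {
  structure(
    list(values = values, spacing = geometry$spacing, origin = geometry$origin),
    class = class
  )
}

#' @export
print.suv_mask <- function(x, ...) {
  cat(sprintf(
    "<suv_mask> %s voxels, %d foreground\n",
    paste(dim(x$values), collapse = " x "), sum(x$values)
  ))
  invisible(x)
}

#' @export
print.lesion_labels <- function(x, ...) {
  cat(sprintf(
    "<lesion_labels> %s voxels, %d lesion(s)\n",
    paste(dim(x$values), collapse = " x "), n_lesions(x)
  ))
  invisible(x)
}

#' Number of labelled lesions in a labelled mask
#' @param labels a `lesion_labels` object.
#' @return Integer count of distinct lesion labels.
#' @export
n_lesions <- function(labels) {
  stopifnot(inherits(labels, "lesion_labels"))
  as.integer(max(labels$values))
}

#' World coordinates of voxel centres along each axis
#' @param x an `suv_volume` or mask object.
#' @return List of three numeric vectors (mm).
#' @keywords internal
axis_coords <- function(x) {
  d <- dim(x$values)
  lapply(1:3, function(a) x$origin[a] + (seq_len(d[a]) - 1) * x$spacing[a])
}

check_same_geometry <- function(a, b) {
  if (!isTRUE(all.equal(dim(a$values), dim(b$values))) ||
      !isTRUE(all.equal(a$spacing, b$spacing)) ||
      !isTRUE(all.equal(a$origin, b$origin))) {
    abort("Mask and volume geometries differ (dimensions, spacing or origin).")
  }
  invisible(TRUE)
}

#' Read / write SUV volumes as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()]. The
#' world frame is the stored sform: a diagonal spacing matrix with the origin
#' as offset, so voxel `(1,1,1)`'s centre maps to `origin`.
#'
#' @param path file path, conventionally ending in `.nii` or `.nii.gz`.
#' @param volume an `suv_volume`.
#' @return `read_suv_nifti()` returns an `suv_volume`; `write_suv_nifti()`
#'   returns `path` invisibly.
#' @export
read_suv_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  suv_volume(
    values = array(as.numeric(img), dim = dim(img)),
    spacing = abs(c(xf[1, 1], xf[2, 2], xf[3, 3])),
    origin = as.numeric(xf[1:3, 4])
  )
}

#' @rdname read_suv_nifti
#' @export
write_suv_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a labelled lesion mask as NIfTI (unsigned integer labels)
#' @param labels a `lesion_labels` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels_nifti <- function(labels, path) {
  stopifnot(inherits(labels, "lesion_labels"))
  img <- RNifti::asNifti(array(as.integer(labels$values), dim(labels$values)))
  RNifti::pixdim(img) <- labels$spacing
  aff <- diag(c(labels$spacing, 1))
  aff[1:3, 4] <- labels$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
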