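#' Threshold segmentation at a fraction of SUVmax
#'
#' Builds a binary lesion mask from an SUV volume by keeping voxels with
#' `SUV > fraction * SUVmax` (strict inequality). With
#' `reference = "global"` the single reference is the volume-wide SUVmax.
#' With `reference = "per_lesion"` a global pass is run first, the resulting
#' components are labelled, and each lesion is then re-segmented at
#' `fraction` of its *own* SUVmax by thresholding the volume at the local
#' level and keeping the connected region that contains the lesion — so dim
#' lesions grow out to their own 41% isocontour instead of the brightest
#' lesion's. Practice varies between the two conventions in the PET
#' literature, so both are provided.
#'
#' @param volume an [suv_volume()].
#' @param fraction proportion of SUVmax in (0, 1); default `0.41`, the common
#'   41% isocontour.
#' @param reference `"global"` (default) or `"per_lesion"`.
#' @param connectivity foreground connectivity (6, 18 or 26) used for the
#'   intermediate labelling in `per_lesion` mode.
#' @return An `suv_mask` (logical 3D grid with the volume's geometry).
#' @examples
#' v <- suv_volume(array(c(10, 5, 4.1, 4, rep(0, 4)), c(2, 2, 2)))
#' sum(threshold_segment(v)$values) # 2: threshold 4.1 is exclusive
#' @export
threshold_segment <- function(volume, fraction = 0.41,
                              reference = c("global", "per_lesion"),
                              connectivity = 26) {
  stopifnot(inherits(volume, "suv_volume"))
  reference <- match.arg(reference)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be a single number in (0, 1).")
  }
  suvmax <- max(volume$values)
  if (suvmax <= 0) {
    abort("All-zero volume: SUVmax = 0 makes the threshold degenerate.")
  }
  mask <- volume$values > fraction * suvmax
  if (reference == "per_lesion") {
    lab <- cc_label_cpp(as.logical(mask), dim(volume$values), connectivity)
    k <- attr(lab, "n_components")
    lab <- array(lab, dim(volume$values))
    keep <- array(mask, dim(volume$values))
    for (l in seq_len(k)) {
      sel <- lab == l
      local_max <- max(volume$values[sel])
      cand <- volume$values > fraction * local_max
      cl <- array(
        cc_label_cpp(as.logical(cand), dim(volume$values), connectivity),
        dim(volume$values)
      )
      grown <- cl %in% unique(cl[sel])
      keep <- keep | array(grown, dim(volume$values))
    }
    mask <- keep
  }
  new_mask(array(mask, dim(volume$values)), volume, "suv_mask")
}

#' Flood-fill connected-component labelling
#'
#' Assigns each foreground voxel to a connected component under the chosen
#' adjacency. Labels are consecutive `1..K`, ordered by the first voxel of
#' each component encountered in array scan order, so the labelling is
#' deterministic.
#'
#' @param mask an `suv_mask`.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' @return A `lesion_labels` object (integer 3D grid, 0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "suv_mask"))
  if (!connectivity %in% c(6, 18, 26)) {
    abort("`connectivity` must be 6, 18 or 26.")
  }
  lab <- cc_label_cpp(as.logical(mask$values), dim(mask$values),
                      as.integer(connectivity))
  out <- new_mask(array(as.integer(lab), dim(mask$values)), mask, "lesion_labels")
  out
}

#' Fill enclosed cavities inside labelled lesions
#'
#' Background voxels that cannot reach the grid boundary through background
#' (6-connectivity, the topological dual of 26-connected foreground) are
#' cavities and are assigned the label of their enclosing component. A cavity
#' touching voxels of more than one label is assigned to the label owning the
#' majority of its adjacent labelled voxels (ties break to the lower label)
#' and a warning is emitted. Idempotent: already-filled masks pass through
#' unchanged.
#'
#' @param labels a `lesion_labels` object.
#' @return A `lesion_labels` object with cavities filled; the per-cavity
#'   report is attached as attribute `"cavities"`.
#' @export
fill_holes <- function(labels) {
  stopifnot(inherits(labels, "lesion_labels"))
  res <- fill_holes_cpp(as.integer(labels$values), dim(labels$values))
  cav <- tibble::as_tibble(res$cavities)
  multi <- cav$n_adjacent_labels > 1
  if (any(multi)) {
    warn(sprintf(
      "%d cavity(ies) adjacent to multiple labels; assigned by majority vote (ties to lower label).",
      sum(multi)
    ))
  }
  out <- new_mask(array(as.integer(res$labels), dim(labels$values)),
                  labels, "lesion_labels")
  attr(out, "cavities") <- cav
  out
}

#' Segment hypermetabolic lesions from an SUV volume
#'
#' The full segmentation chain: fractional-SUVmax thresholding, flood-fill
#' component labelling, removal of components smaller than `min_voxels`
#' (labels re-compacted), and cavity filling. One log line per surviving
#' lesion (label, voxel count, SUVmax) is emitted via [message()] when
#' `verbose = TRUE`.
#'
#' @inheritParams threshold_segment
#' @inheritParams label_components
#' @param min_voxels minimum component size kept; default 2 suppresses
#'   single-voxel noise specks.
#' @param fill fill enclosed cavities (default `TRUE`).
#' @param verbose emit per-lesion log lines.
#' @return A `lesion_labels` object.
#' @examples
#' ph <- make_phantom(phantom_spec(
#'   grid_shape = c(24, 24, 24),
#'   lesions = list(lesion_sphere(center = c(11.5, 11.5, 11.5), radius = 6))
#' ))
#' n_lesions(segment_lesions(ph$volume, verbose = FALSE))
#' @export
segment_lesions <- function(volume, fraction = 0.41,
                            reference = c("global", "per_lesion"),
                            connectivity = 26, min_voxels = 2,
                            fill = TRUE, verbose = TRUE) {
  reference <- match.arg(reference)
  mask <- threshold_segment(volume, fraction, reference, connectivity)
  lab <- label_components(mask, connectivity)
  lab <- filter_small_components(lab, min_voxels)
  if (n_lesions(lab) == 0L) {
    warn("No components survive thresholding and size filtering; empty segmentation.")
    return(lab)
  }
  if (fill) lab <- fill_holes(lab)
  if (verbose) {
    for (l in seq_len(n_lesions(lab))) {
      sel <- lab$values == l
      message(sprintf(
        "lesion=%d voxels=%d suvmax=%.3f", l, sum(sel), max(volume$values[sel])
      ))
    }
  }
  lab
}

#' Drop small components and compact labels
#' @param labels a `lesion_labels` object.
#' @param min_voxels components with fewer voxels are removed.
#' @return A `lesion_labels` object with consecutive labels.
#' @export
filter_small_components <- function(labels, min_voxels = 2) {
  stopifnot(inherits(labels, "lesion_labels"))
  k <- n_lesions(labels)
  if (k == 0L) return(labels)
  counts <- tabulate(labels$values[labels$values > 0], nbins = k)
  keep <- which(counts >= min_voxels)
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  v <- labels$values
  fg <- v > 0
  v[fg] <- remap[v[fg]]
  new_mask(array(as.integer(v), dim(v)), labels, "lesion_labels")
}
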