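#' Lesion specifications for synthetic SUV phantoms
#'
#' Three lesion profiles are supported, each with an analytically known
#' fractional-SUVmax isocontour so that segmentation and mesh measurements
#' can be validated against closed forms:
#'
#' * `lesion_sphere()` — uniform SUV inside a sphere; the isocontour is the
#'   sphere itself (V = 4/3 pi r^3, S = 4 pi r^2).
#' * `lesion_ellipsoid()` — uniform SUV inside an axis-aligned ellipsoid
#'   (V = 4/3 pi abc; surface by the Thomsen approximation, accurate to
#'   about 1%).
#' * `lesion_gaussian()` — isotropic Gaussian profile
#'   `peak * exp(-d^2 / (2 sigma^2))`; the isocontour at a fraction `f` of
#'   the peak is a sphere of radius `r* = sigma * sqrt(2 * ln(1/f))`.
#'
#' @param center lesion centre in mm world coordinates (length 3).
#' @param radius sphere radius, mm.
#' @param semi_axes ellipsoid semi-axes, mm (length 3).
#' @param sigma Gaussian standard deviation, mm.
#' @param peak_suv peak SUV of the lesion profile.
#' @param side `"above_diaphragm"` or `"below_diaphragm"`; if `NULL`, derived
#'   from the centre against the phantom's diaphragm plane.
#' @param compartment `"nodal"` or `"extranodal"`.
#' @param organ_id opaque label used to count distinct extranodal sites.
#' @return A `lesion_spec` list.
#' @export
lesion_sphere <- function(center, radius, peak_suv = 5, side = NULL,
                          compartment = "nodal", organ_id = "node") {
  new_lesion_spec("sphere", center, peak_suv, side, compartment, organ_id,
                  radius = radius)
}

#' @rdname lesion_sphere
#' @export
lesion_ellipsoid <- function(center, semi_axes, peak_suv = 5, side = NULL,
                             compartment = "nodal", organ_id = "node") {
  new_lesion_spec("ellipsoid", center, peak_suv, side, compartment, organ_id,
                  semi_axes = semi_axes)
}

#' @rdname lesion_sphere
#' @export
lesion_gaussian <- function(center, sigma, peak_suv = 5, side = NULL,
                            compartment = "nodal", organ_id = "node") {
  new_lesion_spec("gaussian_blob", center, peak_suv, side, compartment,
                  organ_id, sigma = sigma)
}

new_lesion_spec <- function(shape, center, peak_suv, side, compartment,
                            organ_id, ...) {
  extra <- list(...)
  if (length(center) != 3) abort("`center` must have length 3 (mm).")
  if (peak_suv <= 0) abort("`peak_suv` must be > 0.")
  sizes <- unlist(extra)
  if (any(sizes <= 0)) abort("Lesion radius / semi-axes / sigma must be > 0.")
  if (!compartment %in% c("nodal", "extranodal")) {
    abort('`compartment` must be "nodal" or "extranodal".')
  }
  if (!is.null(side) && !side %in% c("above_diaphragm", "below_diaphragm")) {
    abort('`side` must be "above_diaphragm" or "below_diaphragm".')
  }
  structure(
    c(list(shape = shape, center = as.numeric(center),
           peak_suv = peak_suv, side = side, compartment = compartment,
           organ_id = organ_id), extra),
    class = "lesion_spec"
  )
}

#' Phantom specification
#'
#' Defines a synthetic SUV volume: grid shape, (possibly anisotropic) voxel
#' spacing, uniform background SUV, additive Gaussian noise (truncated at 0,
#' since SUV cannot be negative) and a list of lesion profiles. The
#' diaphragm is modelled as a z-plane in world coordinates; lesion side
#' labels default to centroid-vs-plane.
#'
#' @param grid_shape voxels per axis (length 3, each >= 8).
#' @param spacing mm per axis; default `c(1, 1, 1)`. PET reconstructions
#'   often have coarser slice spacing (e.g. 3 mm) than in-plane spacing.
#' @param origin world mm of the first voxel centre.
#' @param background_suv uniform background SUV (>= 0).
#' @param noise_sd additive Gaussian noise SD in SUV units (>= 0).
#' @param lesions list of [lesion_sphere()] / [lesion_ellipsoid()] /
#'   [lesion_gaussian()] specs.
#' @param diaphragm_z world z (mm) of the diaphragm plane; lesions with
#'   centre z above this are `above_diaphragm`. Default: grid mid-plane.
#' @param seed integer seed for the noise stream.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         background_suv = 0, noise_sd = 0, lesions = list(),
                         diaphragm_z = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    abort("`grid_shape` must be 3 integers, each >= 8.")
  }
  if (any(spacing <= 0)) abort("`spacing` must be positive.")
  if (background_suv < 0) abort("`background_suv` must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (is.null(diaphragm_z)) {
    diaphragm_z <- origin[3] + (grid_shape[3] - 1) * spacing[3] / 2
  }
  structure(
    list(grid_shape = grid_shape, spacing = as.numeric(spacing),
         origin = as.numeric(origin), background_suv = background_suv,
         noise_sd = noise_sd, lesions = lesions,
         diaphragm_z = diaphragm_z, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# analytic truth of the fraction*peak isocontour of one lesion profile
lesion_truth <- function(les, fraction) {
  switch(les$shape,
    sphere = {
      r <- les$radius
      list(volume = 4 / 3 * pi * r^3, surface = 4 * pi * r^2,
           diameter = 2 * r, extent = r)
    },
    ellipsoid = {
      ax <- sort(les$semi_axes, decreasing = TRUE)
      p <- 1.6075  # Thomsen exponent, max error ~1.06%
      s <- 4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
                        ax[2]^p * ax[3]^p) / 3)^(1 / p)
      list(volume = 4 / 3 * pi * prod(ax), surface = s,
           diameter = 2 * ax[1], extent = ax[1])
    },
    gaussian_blob = {
      rstar <- les$sigma * sqrt(2 * log(1 / fraction))
      list(volume = 4 / 3 * pi * rstar^3, surface = 4 * pi * rstar^2,
           diameter = 2 * rstar, extent = rstar)
    },
    abort(sprintf("Unknown lesion shape '%s'.", les$shape))
  )
}

#' Generate an SUV phantom with analytically known lesion geometry
#'
#' Superimposes each lesion's SUV profile on the uniform background, adds
#' truncated Gaussian noise from a seeded stream, and returns both the
#' volume and a ground-truth table carrying each lesion's analytic
#' isocontour volume, surface and diameter at `truth_fraction` of its peak.
#' For uniform shapes the truth is exact at any threshold below the lesion
#' plateau; for Gaussian blobs it assumes the background is negligible
#' relative to the peak.
#'
#' Lesions extending outside the voxel-centre bounding box are rejected, as
#' are overlapping lesions whose site annotations differ (their ground truth
#' would be ambiguous).
#'
#' @param spec a [phantom_spec()].
#' @param truth_fraction isocontour fraction used for the analytic truth;
#'   default 0.41 to match the default segmentation threshold.
#' @return A list with `volume` (an [suv_volume()]) and `truth` (tibble: one
#'   row per lesion with centre, site annotation, analytic `volume_mm3`,
#'   `surface_mm2`, `diameter_mm`).
#' @examples
#' ph <- make_phantom(phantom_spec(
#'   grid_shape = c(32, 32, 32),
#'   lesions = list(lesion_sphere(center = c(15.5, 15.5, 15.5), radius = 10))
#' ))
#' ph$truth$volume_mm3 # 4/3 * pi * 1000
#' @export
make_phantom <- function(spec, truth_fraction = 0.41) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ax <- lapply(1:3, function(a) spec$origin[a] + (seq_len(d[a]) - 1) * spec$spacing[a])
  lo <- vapply(ax, min, 0)
  hi <- vapply(ax, max, 0)

  truths <- purrr::map(spec$lesions, lesion_truth, fraction = truth_fraction)
  ext <- vapply(truths, function(t) t$extent, 0)
  for (i in seq_along(spec$lesions)) {
    ctr <- spec$lesions[[i]]$center
    if (any(ctr - ext[i] < lo) || any(ctr + ext[i] > hi)) {
      abort(sprintf(
        "Lesion %d (centre %s mm, extent %.1f mm) extends outside the grid.",
        i, paste(signif(ctr, 4), collapse = ", "), ext[i]
      ))
    }
  }
  if (length(spec$lesions) > 1) {
    for (i in seq_along(spec$lesions)) {
      for (j in seq_len(i - 1)) {
        li <- spec$lesions[[i]]; lj <- spec$lesions[[j]]
        dist <- sqrt(sum((li$center - lj$center)^2))
        if (dist < ext[i] + ext[j]) {
          same_site <- identical(site_of(li, spec), site_of(lj, spec))
          if (!same_site) {
            abort(sprintf(
              "Lesions %d and %d overlap but carry different site annotations; ground truth would be ambiguous.",
              j, i
            ))
          }
        }
      }
    }
  }

  vals <- array(spec$background_suv, dim = d)
  for (les in spec$lesions) {
    r_sup <- switch(les$shape,
      sphere = les$radius,
      ellipsoid = max(les$semi_axes),
      gaussian_blob = 4 * les$sigma
    )
    sub <- lapply(1:3, function(a) {
      which(abs(ax[[a]] - les$center[a]) <= r_sup + spec$spacing[a])
    })
    if (any(lengths(sub) == 0)) next
    dx <- ax[[1]][sub[[1]]] - les$center[1]
    dy <- ax[[2]][sub[[2]]] - les$center[2]
    dz <- ax[[3]][sub[[3]]] - les$center[3]
    prof <- switch(les$shape,
      sphere = {
        d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
        les$peak_suv * (d2 <= les$radius^2)
      },
      ellipsoid = {
        sa <- les$semi_axes
        d2 <- outer(outer((dx / sa[1])^2, (dy / sa[2])^2, `+`), (dz / sa[3])^2, `+`)
        les$peak_suv * (d2 <= 1)
      },
      gaussian_blob = {
        d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
        les$peak_suv * exp(-d2 / (2 * les$sigma^2))
      }
    )
    vals[sub[[1]], sub[[2]], sub[[3]]] <-
      vals[sub[[1]], sub[[2]], sub[[3]]] + prof
  }
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(
      spec$seed,
      array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
    )
    vals <- pmax(vals + noise, 0)
  }

  truth <- purrr::imap(spec$lesions, function(les, i) {
    t <- truths[[i]]
    tibble::tibble(
      lesion_id = i, shape = les$shape,
      center_x = les$center[1], center_y = les$center[2],
      center_z = les$center[3], peak_suv = les$peak_suv,
      side = site_of(les, spec)$side,
      compartment = les$compartment, organ_id = les$organ_id,
      volume_mm3 = t$volume, surface_mm2 = t$surface, diameter_mm = t$diameter
    )
  })
  list(
    volume = suv_volume(vals, spec$spacing, spec$origin),
    truth = dplyr::bind_rows(truth)
  )
}

site_of <- function(les, spec) {
  side <- les$side %||%
    if (les$center[3] > spec$diaphragm_z) "above_diaphragm" else "below_diaphragm"
  list(side = side, compartment = les$compartment, organ_id = les$organ_id)
}

#' Site annotations of a phantom's lesions, matched to segmentation labels
#'
#' Matches measured lesions to ground-truth lesions by nearest centroid and
#' returns the truth's site annotations keyed by segmentation label, ready
#' for [patient_indicators()] or [run_patient()].
#'
#' @param metrics lesion metrics tibble from [measure_lesions()].
#' @param truth truth tibble from [make_phantom()].
#' @return `metrics` with `side`, `compartment`, `organ_id` columns added.
#' @export
annotate_lesions <- function(metrics, truth) {
  if (nrow(metrics) == 0) {
    return(dplyr::mutate(metrics, side = character(), compartment = character(),
                         organ_id = character()))
  }
  idx <- vapply(seq_len(nrow(metrics)), function(i) {
    d2 <- (truth$center_x - metrics$centroid_x[i])^2 +
      (truth$center_y - metrics$centroid_y[i])^2 +
      (truth$center_z - metrics$centroid_z[i])^2
    which.min(d2)
  }, integer(1))
  dplyr::bind_cols(
    metrics,
    truth[idx, c("side", "compartment", "organ_id")]
  )
}
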