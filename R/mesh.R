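#' Watertight triangular mesh
#'
#' A `tri_mesh` holds vertices (n x 3 matrix, mm world coordinates) and faces
#' (m x 3 integer matrix of 1-based vertex indices) with consistent outward
#' orientation, so the divergence-theorem signed volume is positive.
#'
#' @param vertices numeric matrix, n x 3 (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @return A `tri_mesh` object.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    abort("Face indices out of range.")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "<tri_mesh> %d vertices, %d faces, volume %.2f mm^3, surface %.2f mm^2\n",
    nrow(x$vertices), nrow(x$faces), mesh_volume(x), mesh_surface(x)
  ))
  invisible(x)
}

#' Watertightness audit
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and, with consistent orientation, every directed edge appears
#' exactly once.
#'
#' @param mesh a `tri_mesh`.
#' @return A list with `watertight` (logical), `n_edges`,
#'   `n_edges_not_two_faces`, `n_directed_edges_repeated`.
#' @export
check_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  res <- edge_incidence_cpp(mesh$faces, nrow(mesh$vertices))
  res$watertight <- res$n_edges_not_two_faces == 0L &&
    res$n_directed_edges_repeated == 0L
  res
}

assert_watertight <- function(mesh, what = "mesh") {
  chk <- check_watertight(mesh)
  if (!chk$watertight) {
    abort(sprintf(
      "%s is not watertight: %d edge(s) not shared by exactly 2 faces, %d directed edge(s) repeated.",
      what, chk$n_edges_not_two_faces, chk$n_directed_edges_repeated
    ))
  }
  invisible(mesh)
}

#' Extract the iso-surface mesh of one labelled lesion
#'
#' Runs marching tetrahedra over the 0/1 indicator field of the requested
#' label at iso-level 0.5. The cube decomposition (six tetrahedra sharing a
#' common diagonal) is consistent across neighbouring cells, so the surface
#' is watertight by construction, including for components one voxel thin.
#' Vertices are mapped to world mm honouring anisotropic spacing and the
#' volume origin.
#'
#' @param labels a `lesion_labels` object (cavity-free; apply [fill_holes()]
#'   first so the mesh measures the filled region).
#' @param label which lesion to mesh.
#' @return A `tri_mesh` in world coordinates.
#' @export
voxels_to_mesh <- function(labels, label) {
  stopifnot(inherits(labels, "lesion_labels"))
  label <- as.integer(label)
  sel <- labels$values == label
  if (!any(sel)) abort(sprintf("Label %d not present in mask.", label))
  # crop to the bounding box (plus the implicit background border handled in C++)
  idx <- which(sel, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  sub <- sel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub <- array(sub, dim = hi - lo + 1L)
  res <- march_tets_cpp(as.logical(sub), dim(sub))
  v <- res$vertices
  # index (0-based, cropped frame) -> world mm
  for (a in 1:3) {
    v[, a] <- labels$origin[a] + (v[, a] + (lo[a] - 1)) * labels$spacing[a]
  }
  mesh <- tri_mesh(v, res$faces)
  assert_watertight(mesh, sprintf("Mesh of label %d", label))
  mesh
}

#' Taubin shrink-limited mesh smoothing
#'
#' Two-step positive/negative Laplacian relaxation: each iteration moves the
#' vertices by `lambda` towards the neighbour average and then by `mu`
#' (negative, slightly larger in magnitude) away from it, which removes
#' voxel jaggedness without the systematic shrinkage of plain Laplacian
#' smoothing. Connectivity is untouched, so watertightness is preserved.
#' Default parameters keep the volume of digitised convex bodies within a
#' couple of percent of the unsmoothed mesh.
#'
#' @param mesh a watertight `tri_mesh`.
#' @param iterations number of lambda/mu passes; 0 returns the input.
#' @param lambda positive relaxation factor, in (0, 1).
#' @param mu negative factor with `|mu| > lambda` (Taubin's pass band).
#' @param max_volume_change guard: if the smoothed volume departs from the
#'   input volume by more than this proportion the parameters are rejected.
#' @return A smoothed `tri_mesh`.
#' @export
smooth_mesh <- function(mesh, iterations = 100, lambda = 0.5, mu = -0.505,
                        max_volume_change = 0.10) {
  stopifnot(inherits(mesh, "tri_mesh"))
  assert_watertight(mesh, "Input to smooth_mesh")
  iterations <- as.integer(iterations)
  if (iterations == 0L) return(mesh)
  if (lambda <= 0 || lambda >= 1 || mu >= 0) {
    abort("Require 0 < lambda < 1 and mu < 0.")
  }
  n <- nrow(mesh$vertices)
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  adj <- Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
    x = 1, dims = c(n, n), use.last.ij = FALSE
  )
  adj@x[] <- 1  # duplicate edges collapse to unweighted adjacency
  deg <- Matrix::rowSums(adj)
  w <- adj / deg
  v0 <- mesh$vertices
  v <- v0
  for (i in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(w %*% v) - v)
    v <- v + mu * (as.matrix(w %*% v) - v)
  }
  out <- tri_mesh(v, mesh$faces)
  rel <- abs(mesh_volume(out) - mesh_volume(mesh)) / mesh_volume(mesh)
  if (rel > max_volume_change) {
    abort(sprintf(
      "Smoothing changed the mesh volume by %.1f%% (> %.0f%%); reduce iterations or |mu|-lambda.",
      100 * rel, 100 * max_volume_change
    ))
  }
  out
}

#' Mesh volume by the divergence theorem
#'
#' Signed volume `V = (1/6) * sum over faces of v0 . (v1 x v2)`; positive for
#' a watertight, outward-oriented mesh and invariant to translation.
#'
#' @param mesh a `tri_mesh`.
#' @param check verify watertightness first (default `TRUE`).
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh, check = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (check) assert_watertight(mesh)
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  cross <- cbind(
    b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
    b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
    b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  )
  sum(rowSums(a * cross)) / 6
}

#' Mesh surface area
#'
#' Sum over faces of half the cross-product magnitude.
#'
#' @inheritParams mesh_volume
#' @return Surface area in mm^2.
#' @export
mesh_surface <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  e1 <- v[mesh$faces[, 2], , drop = FALSE] - v[mesh$faces[, 1], , drop = FALSE]
  e2 <- v[mesh$faces[, 3], , drop = FALSE] - v[mesh$faces[, 1], , drop = FALSE]
  cross <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  sum(sqrt(rowSums(cross^2))) / 2
}

#' Maximum 3D diameter (Feret / caliper)
#'
#' Largest pairwise Euclidean distance between mesh vertices — the
#' orientation-independent 3D analogue of the longest axial diameter used to
#' call bulky disease. The maximum over all vertex pairs equals the maximum
#' over convex-hull vertices; it is computed exactly.
#'
#' @param mesh a `tri_mesh`.
#' @return Diameter in mm.
#' @export
max_diameter <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- unique(mesh$vertices)
  max_pair_dist_cpp(v)
}

#' Remove degenerate faces and duplicate vertices
#'
#' Vertices closer than `tol` collapse to one; zero-area faces and faces
#' with repeated vertices are dropped. Meshes produced by [voxels_to_mesh()]
#' are already clean; this is for externally supplied meshes.
#'
#' @param mesh a `tri_mesh`.
#' @param tol vertex merge tolerance in mm.
#' @return A cleaned `tri_mesh`.
#' @export
clean_mesh <- function(mesh, tol = 1e-9) {
  v <- round(mesh$vertices / tol) * tol
  key <- paste(v[, 1], v[, 2], v[, 3])
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  f <- matrix(map[mesh$faces], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[ok, , drop = FALSE]
  vv <- mesh$vertices[uk, , drop = FALSE]
  e1 <- vv[f[, 2], , drop = FALSE] - vv[f[, 1], , drop = FALSE]
  e2 <- vv[f[, 3], , drop = FALSE] - vv[f[, 1], , drop = FALSE]
  area2 <- rowSums((cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  ))^2)
  tri_mesh(vv, f[area2 > 0, , drop = FALSE])
}

#' Measure all lesions of a labelled mask
#'
#' For each label: extract the iso-surface mesh, smooth it, and record mesh
#' volume (mm^3), surface (mm^2), maximum 3D diameter (mm), SUVmax under the
#' label, world centroid and voxel count. Per-lesion failures are reported
#' and skipped without aborting the remaining lesions.
#'
#' @param labels a `lesion_labels` object.
#' @param volume the `suv_volume` the mask was derived from (for SUVmax);
#'   may be `NULL`, in which case `suvmax` is `NA`.
#' @param smooth_iterations,smooth_lambda,smooth_mu smoothing parameters
#'   passed to [smooth_mesh()].
#' @param keep_meshes attach the smoothed meshes as attribute `"meshes"`.
#' @return A tibble with one row per lesion: `label`, `voxel_count`,
#'   `volume_mm3`, `surface_mm2`, `suvmax`, `max_diameter_mm`,
#'   `centroid_x/y/z`.
#' @export
measure_lesions <- function(labels, volume = NULL, smooth_iterations = 100,
                            smooth_lambda = 0.5, smooth_mu = -0.505,
                            keep_meshes = FALSE) {
  stopifnot(inherits(labels, "lesion_labels"))
  if (!is.null(volume)) check_same_geometry(labels, volume)
  k <- n_lesions(labels)
  meshes <- vector("list", k)
  rows <- purrr::map(seq_len(k), function(l) {
    sel <- labels$values == l
    idx <- which(sel, arr.ind = TRUE)
    centroid <- labels$origin + (colMeans(idx) - 1) * labels$spacing
    res <- tryCatch({
      mesh <- voxels_to_mesh(labels, l)
      mesh <- smooth_mesh(mesh, smooth_iterations, smooth_lambda, smooth_mu)
      meshes[[l]] <<- mesh
      tibble::tibble(
        label = l,
        voxel_count = nrow(idx),
        volume_mm3 = mesh_volume(mesh),
        surface_mm2 = mesh_surface(mesh),
        suvmax = if (is.null(volume)) NA_real_ else max(volume$values[sel]),
        max_diameter_mm = max_diameter(mesh),
        centroid_x = centroid[1], centroid_y = centroid[2],
        centroid_z = centroid[3]
      )
    }, error = function(e) {
      warn(sprintf("Lesion %d could not be measured: %s", l, conditionMessage(e)))
      NULL
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  if (keep_meshes) attr(out, "meshes") <- meshes
  out
}

#' Export a mesh as ASCII STL or PLY
#'
#' One file per lesion mesh, suitable for 3D visualisation of segmented
#' tumour models.
#'
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lesion", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "    outer loop",
      sprintf("      vertex %g %g %g", v[f[i, 1:3], 1], v[f[i, 1:3], 2], v[f[i, 1:3], 3]),
      "    endloop",
      "  endfacet"
    ), con)
  }
  writeLines("endsolid lesion", con)
  invisible(path)
}

#' @rdname write_stl
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}
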