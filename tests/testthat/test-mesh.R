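test_that("divergence-theorem volume and surface agree with closed forms", {
  cm <- cube_mesh()
  expect_equal(mesh_volume(cm), 1)
  expect_equal(mesh_surface(cm), 6)
  expect_equal(max_diameter(cm), sqrt(3))

  tm <- tetra_mesh()
  expect_equal(mesh_volume(tm), 1 / 6)
  expect_equal(mesh_surface(tm), 1.5 + sqrt(3) / 2)

  # translation invariance of the closed-surface integral
  shifted <- tri_mesh(cm$vertices + rep(c(17, -4, 230), each = 8), cm$faces)
  expect_equal(mesh_volume(shifted), 1)
  expect_equal(mesh_surface(shifted), 6)
})

test_that("iso-surface of a single voxel is closed with positive volume <= the voxel cell", {
  m <- array(0L, c(8, 8, 8))
  m[4, 4, 4] <- 1L
  mesh <- voxels_to_mesh(mk_labels(m), 1)
  chk <- check_watertight(mesh)
  expect_true(chk$watertight)
  v <- mesh_volume(mesh)
  expect_gt(v, 0)
  expect_lte(v, 1)
})

test_that("a 10^3 voxel cube meshes to within 5% of 1000 mm^3", {
  m <- array(0L, c(14, 14, 14))
  m[3:12, 3:12, 3:12] <- 1L
  mesh <- voxels_to_mesh(mk_labels(m), 1)
  expect_true(check_watertight(mesh)$watertight)
  expect_equal(mesh_volume(mesh), 1000, tolerance = 0.05)
  expect_equal(mesh_volume(mesh), sum(m), tolerance = 0.05)  # voxel-count oracle
})

test_that("meshes honour anisotropic spacing and origin", {
  m <- array(0L, c(10, 10, 10))
  m[4:6, 4:6, 4:6] <- 1L
  sp <- c(1, 2, 3)
  mesh <- voxels_to_mesh(mk_labels(m, spacing = sp, origin = c(5, -2, 0)), 1)
  expect_equal(mesh_volume(mesh), 27 * prod(sp), tolerance = 0.25)
  expect_error(voxels_to_mesh(mk_labels(m), 2), "not present")
})

test_that("Taubin smoothing is identity at 0 iterations and near volume-preserving", {
  ph <- sphere_phantom(radius = 10)
  lab <- segment_lesions(ph$volume, verbose = FALSE)
  mesh <- voxels_to_mesh(lab, 1)
  expect_identical(smooth_mesh(mesh, iterations = 0), mesh)

  sm <- smooth_mesh(mesh)
  expect_true(check_watertight(sm)$watertight)
  expect_lt(abs(mesh_volume(sm) - mesh_volume(mesh)) / mesh_volume(mesh), 0.02)
  expect_equal(mesh_volume(sm), 4 / 3 * pi * 1000, tolerance = 0.03)
  expect_equal(mesh_surface(sm), 4 * pi * 100, tolerance = 0.05)
  expect_equal(max_diameter(sm), 20, tolerance = 0.03)
})

test_that("smoothing a digitised cube decreases surface area; runaway parameters are rejected", {
  m <- array(0L, c(14, 14, 14))
  m[3:12, 3:12, 3:12] <- 1L
  mesh <- voxels_to_mesh(mk_labels(m), 1)
  sm <- smooth_mesh(mesh)
  expect_lt(mesh_surface(sm), mesh_surface(mesh))

  # shrinking parameters (|mu| << lambda) destroy volume and must error
  expect_error(smooth_mesh(mesh, iterations = 300, lambda = 0.5, mu = -0.01),
               "volume")
})

test_that("caliper diameter equals the brute-force pairwise maximum", {
  ph <- sphere_phantom(radius = 4)
  lab <- segment_lesions(ph$volume, verbose = FALSE)
  mesh <- voxels_to_mesh(lab, 1)
  pts <- unique(mesh$vertices)[1:min(400, nrow(unique(mesh$vertices))), ]
  expect_equal(petlesion:::max_pair_dist_cpp(pts), max(stats::dist(pts)))
})

test_that("sphere volume error decreases monotonically with finer voxel spacing", {
  err <- vapply(c(2, 1, 0.5), function(sp) {
    ph <- sphere_phantom(radius = 10, spacing = sp)
    lab <- segment_lesions(ph$volume, verbose = FALSE)
    met <- measure_lesions(lab, ph$volume)
    abs(met$volume_mm3 - 4 / 3 * pi * 1000)
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("every measured lesion respects the isoperimetric bound", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(46, 24, 24),
    lesions = list(
      lesion_sphere(center = c(10, 11.5, 11.5), radius = 6),
      lesion_ellipsoid(center = c(32, 11.5, 11.5), semi_axes = c(9, 5, 4))
    )
  ))
  met <- measure_lesions(segment_lesions(ph$volume, verbose = FALSE), ph$volume)
  expect_true(all(
    met$surface_mm2 >= (36 * pi)^(1 / 3) * met$volume_mm3^(2 / 3) * 0.99
  ))
})

test_that("multi-lesion metrics equal each lesion measured in isolation", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(40, 20, 20),
    lesions = list(
      lesion_sphere(center = c(9, 9.5, 9.5), radius = 5),
      lesion_sphere(center = c(29, 9.5, 9.5), radius = 5)
    )
  ))
  lab <- segment_lesions(ph$volume, verbose = FALSE)
  joint <- measure_lesions(lab, ph$volume)
  # two equal spheres: volumes match within 1%
  expect_equal(joint$volume_mm3[1], joint$volume_mm3[2], tolerance = 0.01)
  for (l in 1:2) {
    iso <- mk_labels((lab$values == l) * 1L)
    alone <- measure_lesions(iso, ph$volume)
    expect_equal(joint$volume_mm3[l], alone$volume_mm3)
    expect_equal(joint$surface_mm2[l], alone$surface_mm2)
    expect_equal(joint$max_diameter_mm[l], alone$max_diameter_mm)
  }
})

test_that("shifting the volume origin moves centroids but not the measurements", {
  base <- sphere_phantom(radius = 6)
  lab1 <- segment_lesions(base$volume, verbose = FALSE)
  m1 <- measure_lesions(lab1, base$volume)
  moved <- suv_volume(base$volume$values, base$volume$spacing,
                      base$volume$origin + c(100, -50, 7))
  lab2 <- segment_lesions(moved, verbose = FALSE)
  m2 <- measure_lesions(lab2, moved)
  expect_equal(m2$volume_mm3, m1$volume_mm3)
  expect_equal(m2$surface_mm2, m1$surface_mm2)
  expect_equal(m2$max_diameter_mm, m1$max_diameter_mm)
  expect_equal(m2$centroid_x, m1$centroid_x + 100)
})

test_that("mesh cleaning collapses duplicate vertices and drops degenerate faces", {
  cm <- cube_mesh()
  v <- rbind(cm$vertices, cm$vertices[1, , drop = FALSE] + 1e-12)
  f <- rbind(cm$faces, c(1, 9, 2))  # face joining a duplicate vertex: degenerate
  cleaned <- clean_mesh(tri_mesh(v, f))
  expect_equal(nrow(cleaned$vertices), 8)
  expect_equal(nrow(cleaned$faces), 12)
  expect_equal(mesh_volume(cleaned), 1)
})

test_that("STL and PLY exports are well-formed text files", {
  mesh <- tetra_mesh()
  stl <- tempfile(fileext = ".stl")
  ply <- tempfile(fileext = ".ply")
  write_stl(mesh, stl)
  write_ply(mesh, ply)
  expect_equal(sum(grepl("facet normal", readLines(stl))), 4)
  plylines <- readLines(ply)
  expect_equal(plylines[1], "ply")
  expect_equal(sum(grepl("^3 ", plylines)), 4)
})
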