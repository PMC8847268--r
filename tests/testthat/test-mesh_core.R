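test_that("mesh I/O round-trips and validates across formats", {
  tet <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  tet <- orient_mesh(tet)
  expect_true(is_closed(tet))
  for (fmt in c("ply", "obj", "vtk")) {
    path <- file.path(tempdir(), paste0("tet.", fmt))
    write_mesh(tet, path)
    back <- read_mesh(path)
    expect_equal(nrow(back$vertices), 4L)
    expect_equal(nrow(back$triangles), 4L)
    expect_true(is_closed(back))
  }
  ico <- icosphere(2, radius = 7, center = c(1, 2, 3))
  path <- file.path(tempdir(), "ico.ply")
  write_mesh(ico, path)
  back <- read_mesh(path, check_closed = TRUE)
  expect_equal(back$vertices, ico$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$triangles, ico$triangles)
  # labels survive via the JSON sidecar
  lab <- ico
  lab$labels[1:10] <- "epi"
  write_mesh(lab, path)
  expect_identical(read_mesh(path)$labels, lab$labels)
})

test_that("non-manifold surfaces are rejected with the offending edge", {
  tet <- orient_mesh(trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(0, 0, 1)),
                             rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3),
                                   c(2, 3, 4))))
  dup <- tet
  dup$triangles <- rbind(dup$triangles, dup$triangles[1, ])
  path <- file.path(tempdir(), "dup.ply")
  write_mesh(dup, path)
  expect_error(read_mesh(path), "non-manifold.*edge")
  # open surface passes by default but fails for BEM use
  open <- tet
  open$triangles <- open$triangles[-1, , drop = FALSE]
  write_mesh(open, file.path(tempdir(), "open.ply"))
  expect_s3_class(read_mesh(file.path(tempdir(), "open.ply")), "trimesh")
  expect_error(read_mesh(file.path(tempdir(), "open.ply"),
                         check_closed = TRUE), "not closed")
})

test_that("solid angles obey the Gauss identities and the exact face value", {
  sph <- icosphere(3, radius = 10)
  expect_equal(sum(solid_angle(sph, c(0, 0, 0))), -4 * pi, tolerance = 1e-9)
  expect_equal(sum(solid_angle(sph, c(0.5, -1, 2))), -4 * pi, tolerance = 1e-9)
  expect_equal(sum(solid_angle(sph, c(25, 0, 0))), 0, tolerance = 1e-9)
  expect_error(solid_angle(sph, sph$vertices[1, ]), "on the surface")
  # half of a cube face seen from the cube centre subtends exactly
  # (4 pi / 6) / 2 by symmetry; an independent closed-form oracle
  half_face <- trimesh(rbind(c(1, -1, -1), c(1, 1, -1), c(1, 1, 1)),
                       matrix(c(1, 2, 3), 1))
  expect_equal(abs(solid_angle(half_face, c(0, 0, 0))), 4 * pi / 12,
               tolerance = 1e-12)
  # Monte-Carlo ray oracle on the same triangle (statistical tolerance)
  set.seed(1)
  n_mc <- 4e5
  u <- matrix(rnorm(3 * n_mc), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  # ray hits plane x = 1 at (1, y, z); inside the triangle y in [-1,1],
  # z in [-1, y]
  ok <- u[, 1] > 1e-9
  y <- u[ok, 2] / u[ok, 1]
  z <- u[ok, 3] / u[ok, 1]
  p_hit <- sum(abs(y) <= 1 & z >= -1 & z <= y) / n_mc
  expect_equal(4 * pi * p_hit, 4 * pi / 12, tolerance = 0.02)
})

test_that("umbrella Laplacian annihilates constants and flags spikes", {
  sph <- icosphere(2, radius = 10)
  L <- surface_laplacian(sph)
  expect_lt(max(abs(L %*% rep(3.3, nrow(sph$vertices)))), 1e-12)
  spike <- numeric(nrow(sph$vertices)); spike[5] <- 1
  resp <- as.numeric(L %*% spike)
  expect_lt(resp[5], 0)
  nb <- setdiff(which(resp != 0), 5L)
  expect_true(all(resp[nb] > 0))
  # linear field on a structured planar patch: interior response vanishes
  # and stays vanishing under refinement
  err <- vapply(c(11, 21), function(n) {
    sh <- sheet_mesh(n, n, 100, 100)
    Ls <- surface_laplacian(sh)
    lin <- 2 * sh$vertices[, 1] + 0.5 * sh$vertices[, 2]
    r <- abs(as.numeric(Ls %*% lin))
    interior <- sh$vertices[, 1] > 1e-9 & sh$vertices[, 1] < 100 - 1e-9 &
      sh$vertices[, 2] > 1e-9 & sh$vertices[, 2] < 100 - 1e-9
    max(r[interior])
  }, 1)
  expect_lt(err[2], 1e-10)
  expect_lte(err[2], err[1] + 1e-12)
})

test_that("the phantom is a valid nested world and a pure function of its spec", {
  ph <- test_phantom()
  for (nm in names(ph$meshes)) expect_true(is_closed(ph$meshes[[nm]]))
  myo <- ph$meshes$myocardium
  expect_gte(nrow(myo$vertices), 500)
  expect_lte(nrow(myo$vertices), 5000)
  expect_gt(mesh_volume(myo), 0) # outward winding
  expect_setequal(unique(myo$labels),
                  c("epi", "lv_endo", "rv_endo", "septum_lv", "septum_rv"))
  # determinism
  ph2 <- make_phantom(phantom_spec(resolution = 7, seed = 42L))
  expect_identical(ph2$meshes$myocardium$vertices, myo$vertices)
  expect_identical(ph2$meshes$thorax$triangles, ph$meshes$thorax$triangles)
  # ray-casting nesting oracle: blood pools live in the cavities (inside the
  # epicardial hull, outside the muscle shell); all surfaces inside the torso
  for (bp in c("blood_lv", "blood_rv")) {
    v <- ph$meshes[[bp]]$vertices
    expect_false(any(point_in_mesh(myo, v)))
    expect_true(all(rowSums(sweep(v, 2, c(45, 40, 75), "/")^2) <= 1 &
                      v[, 3] <= 1e-9))
    expect_true(all(point_in_mesh(ph$meshes$thorax, v)))
  }
  expect_true(all(point_in_mesh(ph$meshes$thorax, myo$vertices)))
  expect_false(any(point_in_mesh(ph$meshes$lung_left, myo$vertices)))
  # landmark regions: nine, non-empty, on their surfaces
  expect_length(ph$landmarks, 9L)
  expect_true(all(lengths(lapply(ph$landmarks, `[[`, "vertices")) >= 1))
  # fibers: unit, tangent
  fb <- ph$fibers
  expect_equal(sqrt(rowSums(fb^2)), rep(1, nrow(fb)), tolerance = 1e-9)
  vn <- vertex_normals(myo)
  expect_lt(max(abs(rowSums(fb * vn))), 1e-6)
  # too-coarse resolution errors
  expect_error(make_phantom(phantom_spec(resolution = 12)), "coarse")
})

test_that("orient_mesh repairs scrambled windings", {
  sph <- icosphere(2, radius = 5)
  bad <- sph
  flip <- seq(1, nrow(bad$triangles), by = 3)
  bad$triangles[flip, ] <- bad$triangles[flip, c(1, 3, 2)]
  fixed <- orient_mesh(bad)
  expect_true(is_closed(fixed))
  expect_equal(mesh_volume(fixed), mesh_volume(sph), tolerance = 1e-12)
  expect_equal(sum(solid_angle(fixed, c(0, 0, 0))), -4 * pi, tolerance = 1e-9)
})
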