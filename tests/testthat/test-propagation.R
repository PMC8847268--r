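test_that("velocity boost region obeys radius, degeneracy and union rules", {
  sh <- sheet_mesh(81, 3, 40, 1) # x spacing 0.5 mm
  focus <- 1L # corner (0, 0)
  vf0 <- build_velocity_field(sh, focus, boost_radius = 0)
  expect_true(all(vf0$speed == 0.85))
  vf <- build_velocity_field(sh, focus)
  x <- sh$vertices[, 1]
  row1 <- which(sh$vertices[, 2] == 0)
  expect_equal(vf$speed[row1][x[row1] == 14.5], 1.7)
  expect_equal(vf$speed[row1][x[row1] == 15.5], 0.85)
  # overlapping foci: boost applied once, region is the union
  vf2 <- build_velocity_field(sh, c(focus, focus, row1[x[row1] == 2]))
  expect_true(all(vf2$speed[vf$speed == 1.7] == 1.7))
  expect_true(all(vf2$speed %in% c(0.85, 1.7)))
  expect_error(build_velocity_field(trimesh(matrix(0, 0, 3),
                                            matrix(0L, 0, 3)), 1L), "empty")
})

test_that("fastest route reproduces closed-form arrivals on a strip", {
  sh <- sheet_mesh(11, 2, 10, 0.5) # straight 10 mm chain, 1 mm spacing
  n <- nrow(sh$vertices)
  vf <- build_velocity_field(sh, integer(0), base_speed = 1,
                             boost_radius = 0)
  sq <- fastest_route(sh, vf, NULL, list(list(vertices = 1L, t0 = 0)))
  far <- which(sh$vertices[, 1] == 10 & sh$vertices[, 2] == 0)
  expect_equal(sq$lat[far], 10, tolerance = 1e-12)
  expect_equal(min(sq$lat), 0)
  expect_error(fastest_route(sh, vf, NULL, list()), "at least one focus")
  expect_error(fastest_route(sh, vf, NULL,
                             list(list(vertices = 1L, t0 = -2))), ">= 0")
})

test_that("multi-source FRA equals the pointwise minimum and igraph Dijkstra", {
  ph <- test_phantom()
  mesh <- ph$meshes$myocardium
  vf <- build_velocity_field(mesh, integer(0), boost_radius = 0)
  foci <- list(list(vertices = 10L, t0 = 0), list(vertices = 400L, t0 = 7),
               list(vertices = 700L, t0 = 3))
  joint <- fastest_route(mesh, vf, ph$fibers, foci)
  per <- lapply(foci, function(f) fastest_route(mesh, vf, ph$fibers,
                                                list(f))$lat)
  expect_equal(joint$lat, do.call(pmin, per), tolerance = 1e-12)
  # independent oracle: igraph shortest paths on the same weighted graph
  et <- edlwave:::edge_travel_times(mesh, vf, ph$fibers)
  g <- igraph::graph_from_edgelist(et$edges, directed = FALSE)
  dm <- igraph::distances(g, v = c(10L, 400L, 700L), weights = et$w)
  oracle <- pmin(dm[1, ], dm[2, ] + 7, dm[3, ] + 3)
  expect_equal(joint$lat, unname(oracle), tolerance = 1e-9)
})

test_that("elliptical anisotropy yields a 2:1 arrival ratio on a fibered sheet", {
  sh <- sheet_mesh(41, 41, 80, 80)
  fibers <- cbind(1, 0, 0)[rep(1, nrow(sh$vertices)), ]
  vf <- build_velocity_field(sh, integer(0), base_speed = 1,
                             boost_radius = 0, anisotropy_ratio = 2)
  corner <- which(sh$vertices[, 1] == 0 & sh$vertices[, 2] == 0)
  sq <- fastest_route(sh, vf, fibers, list(list(vertices = corner, t0 = 0)))
  along <- sq$lat[sh$vertices[, 1] == 80 & sh$vertices[, 2] == 0]
  across <- sq$lat[sh$vertices[, 1] == 0 & sh$vertices[, 2] == 80]
  expect_equal(along, 80, tolerance = 0.01)
  expect_equal(across / along, 2, tolerance = 0.05)
})

test_that("durations, the QRS gate and the Lipschitz property behave", {
  expect_equal(total_duration(rep(4.2, 10)), 0)
  expect_equal(total_duration(0:90), 90)
  expect_true(duration_gate(c(0, 100), 100))
  expect_true(duration_gate(c(0, 85), 100))   # inclusive boundary
  expect_true(duration_gate(c(0, 115), 100))  # inclusive boundary
  expect_false(duration_gate(c(0, 84.9), 100))
  expect_false(duration_gate(c(0, 115.1), 100))
  # property: merged duration bound and monotonicity under added foci
  ph <- test_phantom()
  mesh <- ph$meshes$myocardium
  vf <- build_velocity_field(mesh, integer(0), boost_radius = 0)
  set.seed(11)
  for (rep in 1:3) {
    vs <- sample(nrow(mesh$vertices), 3)
    t0s <- c(0, runif(2, 0, 20))
    foci <- Map(function(v, t0) list(vertices = v, t0 = t0), vs, t0s)
    merged <- fastest_route(mesh, vf, ph$fibers, unname(foci))
    singles <- lapply(unname(foci), function(f)
      fastest_route(mesh, vf, ph$fibers, list(f)))
    expect_lte(total_duration(merged),
               max(vapply(singles, total_duration, 1)) + diff(range(t0s)))
    # adding a focus never increases any arrival time
    sub <- fastest_route(mesh, vf, ph$fibers, unname(foci[1:2]))
    expect_true(all(merged$lat <= sub$lat + 1e-12))
  }
})

test_that("activation export writes CSV and VTK", {
  ph <- test_phantom()
  mesh <- ph$meshes$myocardium
  sq <- activation_sequence(seq_len(nrow(mesh$vertices)) * 0.1)
  csv <- file.path(tempdir(), "lat.csv")
  write_activation(sq, csv)
  expect_equal(read.csv(csv)$lat_ms, sq$lat)
  vtk <- file.path(tempdir(), "lat.vtk")
  write_activation(sq, vtk, mesh = mesh)
  expect_true(any(grepl("SCALARS lat_ms", readLines(vtk))))
})
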