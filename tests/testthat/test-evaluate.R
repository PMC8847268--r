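test_that("BSPM match metrics obey their closed forms", {
  set.seed(5)
  V <- matrix(rnorm(6 * 40), 6)
  expect_equal(bspm_match(V, V), list(cc = 1, rd = 0))
  m2 <- bspm_match(V, 2 * V)
  expect_equal(m2$cc, 1)
  expect_equal(m2$rd, 1)
  m3 <- bspm_match(V, -V)
  expect_equal(m3$cc, -1)
  expect_equal(m3$rd, 2)
  expect_error(bspm_match(matrix(1, 3, 3), V[1:3, 1:3]), "zero-variance")
  expect_error(bspm_match(V, V[, 1:3]), "shapes differ")
})

test_that("rigid ICP recovers a known transform and refuses reflections", {
  ph <- test_phantom()
  mesh <- ph$meshes$myocardium
  set.seed(8)
  ang <- c(0.2, -0.15, 0.1)
  Rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                          c(0, sin(a), cos(a)))
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  R_true <- Rz(ang[3]) %*% Rx(ang[1])
  t_true <- c(4, -6, 9)
  # EAM cloud = transformed subset of mesh vertices (inverse transform:
  # ICP must map the cloud back onto the mesh)
  idx <- seq(1, nrow(mesh$vertices), by = 2)
  cloud <- sweep(mesh$vertices[idx, ] %*% t(R_true), 2, t_true, "+")
  eam <- eam_map(cloud, lat = rep(0, nrow(cloud)), surface = "epi")
  lm_idx <- c(10L, 300L, 500L, 700L)
  fit <- align_eam(eam, mesh,
                   landmarks_eam = sweep(mesh$vertices[lm_idx, ] %*%
                                           t(R_true), 2, t_true, "+"),
                   landmarks_mesh = mesh$vertices[lm_idx, ])
  expect_lt(fit$rms, 0.1)
  R_err <- fit$R %*% R_true
  expect_lt(acos(pmin(1, (sum(diag(R_err)) - 1) / 2)), 1e-3)
  expect_lt(max(abs(apply_rigid_test(cloud, fit) - mesh$vertices[idx, ])),
            0.5)
  # already aligned: identity within tolerance
  eam0 <- eam_map(mesh$vertices[idx, ], rep(0, length(idx)), surface = "epi")
  fit0 <- align_eam(eam0, mesh, mesh$vertices[lm_idx, ],
                    mesh$vertices[lm_idx, ])
  expect_lt(max(abs(fit0$R - diag(3))), 1e-6)
  expect_lt(max(abs(fit0$t)), 1e-3)
  # mirrored cloud: rigidity (det = +1) forbids a reflection fit
  mirror <- cloud %*% diag(c(-1, 1, 1))
  eam_m <- eam_map(mirror, rep(0, nrow(mirror)), surface = "epi")
  fit_m <- tryCatch(
    align_eam(eam_m, mesh, mirror[c(1, 50, 100, 200), ],
              mesh$vertices[idx[c(1, 50, 100, 200)], ]),
    error = function(e) e)
  if (!inherits(fit_m, "error")) {
    expect_equal(det(fit_m$R), 1, tolerance = 1e-9)
    # a proper rotation cannot undo a reflection: the residual stays far
    # above the exact-correspondence fit (which is at numerical zero)
    expect_gt(fit_m$rms, 0.2)
  }
})

test_that("EAM projection snaps, excludes and averages as specified", {
  ph <- test_phantom()
  mesh <- ph$meshes$myocardium
  vn <- vertex_normals(mesh)
  v1 <- 25L
  pts <- rbind(mesh$vertices[v1, ],                  # exactly on a vertex
               mesh$vertices[v1, ],                  # duplicate: averaging
               mesh$vertices[200L, ] + 10.1 * vn[200L, ]) # beyond 10 mm
  eam <- eam_map(pts, lat = c(10, 20, 99), voltage = c(1, 3, 5),
                 surface = "epi")
  pr <- project_eam(eam, mesh, max_dist = 10)
  expect_equal(pr$lat[v1], 15) # mean of 10 and 20
  expect_equal(pr$n_excluded, 1L)
  expect_false(200L %in% pr$mask)
  expect_true(all(pr$mask %in% which(!is.na(pr$lat))))
  # projection then inter-map on self-generated data is perfect
  idx <- seq(1, nrow(mesh$vertices), by = 3)
  lat_field <- mesh$vertices[, 3] / 4
  eam2 <- eam_map(mesh$vertices[idx, ], lat_field[idx], surface = "epi")
  pr2 <- project_eam(eam2, mesh)
  im <- inter_map(lat_field, pr2$lat)
  expect_equal(im$cc, 1, tolerance = 1e-9)
  expect_equal(im$mean_abs_diff, 0, tolerance = 1e-9)
})

test_that("inter-map statistics react to shifts and sign flips", {
  ref <- c(NA, 1, 2, 3, 4, NA, 6)
  est <- c(0, 1, 2, 3, 4, 0, 6)
  expect_equal(inter_map(est, ref), list(cc = 1, mean_abs_diff = 0))
  expect_equal(inter_map(est + 5, ref), list(cc = 1, mean_abs_diff = 5))
  ref0 <- ref - mean(ref, na.rm = TRUE)
  expect_equal(inter_map(-ref0, ref0)$cc, -1)
  expect_error(inter_map(est[1:3], ref[1:3]), "at least 3")
})

test_that("triangulation CV is exact on affine LAT fields", {
  set.seed(9)
  # planar wave at 1 mm/ms across arbitrary triangles
  for (rep in 1:5) {
    v <- matrix(rnorm(9, sd = 10), 3)
    tri <- trimesh(v, matrix(1:3, 1))
    g <- rnorm(3)
    lat <- as.numeric(v %*% g)
    cv <- triangulation_cv(tri, lat, exclude_above = Inf)
    # oracle: in-plane projection of the gradient
    e1 <- v[2, ] - v[1, ]; e2 <- v[3, ] - v[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    g_in <- g - sum(g * nrm) * nrm
    expect_equal(cv$raw_speed, 1 / sqrt(sum(g_in^2)), tolerance = 1e-9)
    expect_equal(abs(sum(cv$direction * g_in / sqrt(sum(g_in^2)))), 1,
                 tolerance = 1e-9)
  }
  # unit planar wave on a sheet: speed exactly 1 everywhere
  sh <- sheet_mesh(6, 6, 10, 10)
  cv <- triangulation_cv(sh, sh$vertices[, 1])
  expect_equal(cv$speed, rep(1, nrow(sh$triangles)))
  # simultaneous activation is masked
  cv0 <- triangulation_cv(sh, rep(3, nrow(sh$vertices)))
  expect_true(all(is.na(cv0$speed)))
})

test_that("breakthrough counting finds distinct early regions", {
  ph <- test_phantom()
  mesh <- ph$meshes$myocardium
  vf <- build_velocity_field(mesh, integer(0), boost_radius = 0)
  one <- fastest_route(mesh, vf, ph$fibers, list(list(vertices = 50L, t0 = 0)))
  expect_equal(count_breakthroughs(mesh, one$lat), 1L)
  # two far-apart foci with similar onset
  v2 <- which.max(one$lat) # farthest point from focus 1
  two <- fastest_route(mesh, vf, ph$fibers,
                       list(list(vertices = 50L, t0 = 0),
                            list(vertices = v2, t0 = 2)))
  expect_equal(count_breakthroughs(mesh, two$lat), 2L)
  expect_equal(count_breakthroughs(mesh, rep(7, nrow(mesh$vertices))), 0L)
})
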