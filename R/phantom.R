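# Synthetic biventricular torso phantom.
#
# The ventricular source surface is a single closed mesh: an epicardial
# half-ellipsoid (base plane z = 0, apex at -z) plus two cavity
# half-ellipsoids (LV at +x, RV at -x), joined at the base by a
# zipper-triangulated annulus with two holes.  Papillary / moderator-band
# insertions are marked vertex sets, not protruding geometry.  Everything is
# a pure function of the spec (the seed only drives a small parametric
# jitter that breaks the exact symmetry of the ellipsoids).

#' Phantom specification
#'
#' @param torso_axes length-3 half-axes of the torso ellipsoid (mm).
#' @param wall_thickness minimal ventricular wall thickness (mm).
#' @param resolution target edge length of the ventricular mesh (mm).
#' @param electrode_count number of body-surface electrodes (>= 9).
#' @param seed integer seed for the symmetry-breaking mesh jitter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(torso_axes = c(140, 100, 230),
                         wall_thickness = 10,
                         resolution = 5,
                         electrode_count = 67,
                         seed = 1L) {
  stopifnot(length(torso_axes) == 3, all(torso_axes > 0),
            wall_thickness > 0, resolution > 0)
  if (electrode_count < 9) stop("electrode_count must be >= 9")
  structure(list(torso_axes = as.numeric(torso_axes),
                 wall_thickness = as.numeric(wall_thickness),
                 resolution = as.numeric(resolution),
                 electrode_count = as.integer(electrode_count),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# open half-ellipsoid grid: rim row at z = 0, apex at z = -axes[3]
half_shell <- function(center, axes, h, jitter = 0) {
  circ <- 2 * pi * sqrt((axes[1]^2 + axes[2]^2) / 2)
  n_u <- 4L * max(3L, round(circ / (4 * h)))
  arc <- (pi / 2) * sqrt((axes[3]^2 + (axes[1] + axes[2])^2 / 4) / 2)
  n_v <- max(4L, round(arc / h))
  uu <- matrix(rep(2 * pi * (seq_len(n_u) - 1) / n_u, n_v), n_v, n_u, byrow = TRUE)
  ff <- matrix(rep((seq_len(n_v) - 1) / n_v, n_u), n_v, n_u)
  if (jitter > 0) {
    ju <- matrix(runif(n_v * n_u, -jitter, jitter), n_v, n_u) * (2 * pi / n_u)
    jf <- matrix(runif(n_v * n_u, -jitter, jitter), n_v, n_u) * (1 / n_v)
    uu <- uu + ju
    ff[-1, ] <- ff[-1, ] + jf[-1, ] # rim row stays at z = 0
  }
  phi <- ff * (pi / 2)
  x <- center[1] + axes[1] * cos(uu) * cos(phi)
  y <- center[2] + axes[2] * sin(uu) * cos(phi)
  z <- center[3] - axes[3] * sin(phi)
  verts <- cbind(as.vector(t(x)), as.vector(t(y)), as.vector(t(z)))
  apex <- c(center[1], center[2], center[3] - axes[3])
  verts <- rbind(verts, apex)
  idx <- function(i, k) (i - 1L) * n_u + ((k - 1L) %% n_u) + 1L
  tris <- matrix(0L, 0, 3)
  quads <- vector("list", n_v - 1L)
  for (i in seq_len(n_v - 1L)) {
    k <- seq_len(n_u)
    quads[[i]] <- rbind(cbind(idx(i, k), idx(i, k + 1L), idx(i + 1L, k + 1L)),
                        cbind(idx(i, k), idx(i + 1L, k + 1L), idx(i + 1L, k)))
  }
  tris <- do.call(rbind, quads)
  ap <- n_u * n_v + 1L
  k <- seq_len(n_u)
  tris <- rbind(tris, cbind(idx(n_v, k), idx(n_v, k + 1L), rep(ap, n_u)))
  list(verts = verts, tris = tris, n_u = n_u, n_v = n_v,
       rim = idx(1L, seq_len(n_u)), apex = ap,
       u = c(as.vector(t(uu)), 0), f = c(as.vector(t(ff)), 1))
}

# greedy strip triangulation between two aligned open polylines; the end
# edges (p[1], q[1]) and (p[last], q[last]) close the strip
zipper <- function(verts, p, q) {
  i <- 1L; j <- 1L
  tris <- matrix(0L, 0, 3)
  d <- function(a, b) sum((verts[a, ] - verts[b, ])^2)
  while (i < length(p) || j < length(q)) {
    adv_p <- j == length(q) ||
      (i < length(p) && d(p[i + 1L], q[j]) <= d(p[i], q[j + 1L]))
    if (adv_p) {
      tris <- rbind(tris, c(p[i], p[i + 1L], q[j]))
      i <- i + 1L
    } else {
      tris <- rbind(tris, c(p[i], q[j + 1L], q[j]))
      j <- j + 1L
    }
  }
  tris
}

# arc of rim indices from angle index a to b (inclusive), wrapping
rim_arc <- function(rim, from, to) {
  n <- length(rim)
  if (from <= to) rim[from:to] else rim[c(from:n, 1:to)]
}

build_ventricles <- function(spec) {
  h <- spec$resolution
  wall <- spec$wall_thickness
  epi_ax <- c(45, 40, 75)
  sept <- max(wall, 1.2 * wall) # septal wall target
  a_cav <- (40 - sept) / 2     # cavity x half-axes given centres at +/-20
  lv_c <- c(20, 0, 0); lv_ax <- c(a_cav, 16, epi_ax[3] - 1.5 * wall)
  rv_c <- c(-20, 0, 0); rv_ax <- c(a_cav, 20, 0.65 * epi_ax[3])
  if (a_cav < 6 || 45 - (lv_c[1] + lv_ax[1]) < 0.8 * wall)
    stop("wall thickness incompatible with the phantom ventricle layout")
  if (h > 8) stop("resolution too coarse to honour the wall thickness")
  set.seed(spec$seed)
  epi <- half_shell(c(0, 0, 0), epi_ax, h, jitter = 0.15)
  lv <- half_shell(lv_c, lv_ax, h, jitter = 0.15)
  rv <- half_shell(rv_c, rv_ax, h, jitter = 0.15)
  if (min(lv$n_u, rv$n_u, epi$n_u) < 8)
    stop("resolution too coarse for the cavity rims")

  off_lv <- nrow(epi$verts)
  off_rv <- off_lv + nrow(lv$verts)
  verts <- rbind(epi$verts, lv$verts, rv$verts)
  tris <- rbind(epi$tris, lv$tris + off_lv, rv$tris + off_rv)

  # base cap: epi rim split at u = pi/2 (j1) and 3pi/2 (j2)
  eJ1 <- epi$n_u / 4L + 1L; eJ2 <- 3L * epi$n_u / 4L + 1L
  lJ1 <- lv$n_u / 4L + 1L;  lJ2 <- 3L * lv$n_u / 4L + 1L
  rJ1 <- rv$n_u / 4L + 1L;  rJ2 <- 3L * rv$n_u / 4L + 1L
  e_right <- rim_arc(epi$rim, eJ2, eJ1)               # -pi/2 -> +pi/2 via 0
  e_left  <- rim_arc(epi$rim, eJ1, eJ2)               # +pi/2 -> 3pi/2
  l_outer <- rim_arc(lv$rim, lJ2, lJ1) + off_lv
  l_inner <- rim_arc(lv$rim, lJ1, lJ2) + off_lv
  r_outer <- rim_arc(rv$rim, rJ1, rJ2) + off_rv
  r_inner <- rev(rim_arc(rv$rim, rJ2, rJ1)) + off_rv  # +pi/2 -> -pi/2

  cap <- rbind(zipper(verts, e_right, l_outer),
               zipper(verts, e_left, r_outer),
               zipper(verts, l_inner, r_inner),
               c(epi$rim[eJ1], lv$rim[lJ1] + off_lv, rv$rim[rJ1] + off_rv),
               c(epi$rim[eJ2], lv$rim[lJ2] + off_lv, rv$rim[rJ2] + off_rv))
  tris <- rbind(tris, cap)

  labels <- c(rep("epi", nrow(epi$verts)),
              ifelse(cos(lv$u) < -0.5, "septum_lv", "lv_endo"),
              ifelse(cos(rv$u) > 0.5, "septum_rv", "rv_endo"))
  mesh <- orient_mesh(trimesh(verts, tris, labels))
  nv <- nrow(mesh$vertices)
  list(mesh = mesh, lv_c = lv_c, lv_ax = lv_ax, rv_c = rv_c, rv_ax = rv_ax,
       epi_ax = epi_ax,
       lv_ids = off_lv + seq_len(nrow(lv$verts)),
       rv_ids = off_rv + seq_len(nrow(rv$verts)))
}

# analytic point on a cavity wall at angle u and depth fraction f
cavity_point <- function(center, axes, u, f) {
  phi <- f * pi / 2
  c(center[1] + axes[1] * cos(u) * cos(phi),
    center[2] + axes[2] * sin(u) * cos(phi),
    center[3] - axes[3] * sin(phi))
}

nearest_labeled_vertex <- function(mesh, point, label) {
  ok <- which(mesh$labels %in% label)
  if (!length(ok)) stop("no vertices with label ", paste(label, collapse = "/"))
  d2 <- rowSums((mesh$vertices[ok, , drop = FALSE] -
                   matrix(point, length(ok), 3, byrow = TRUE))^2)
  ok[which.min(d2)]
}

patch_around <- function(mesh, center_id, radius, label = NULL) {
  d2 <- rowSums((mesh$vertices -
                   matrix(mesh$vertices[center_id, ], nrow(mesh$vertices), 3,
                          byrow = TRUE))^2)
  ids <- which(d2 <= radius^2)
  if (!is.null(label)) ids <- ids[mesh$labels[ids] %in% label]
  sort(unique(c(center_id, ids)))
}

place_landmarks <- function(vent) {
  mesh <- vent$mesh
  lm <- list()
  # endocardial structures: insertion vertex sets on the free wall
  stru <- list(
    lv_ant_papillary  = list(c = vent$lv_c, a = vent$lv_ax, u = pi / 3,  f = 0.5,
                             lab = "lv_endo"),
    lv_post_papillary = list(c = vent$lv_c, a = vent$lv_ax, u = -pi / 3, f = 0.5,
                             lab = "lv_endo"),
    rv_moderator_band = list(c = vent$rv_c, a = vent$rv_ax, u = pi,      f = 0.65,
                             lab = "rv_endo"))
  for (nm in names(stru)) {
    s <- stru[[nm]]
    ctr <- nearest_labeled_vertex(mesh, cavity_point(s$c, s$a, s$u, s$f), s$lab)
    lm[[nm]] <- list(kind = "structure", center = ctr,
                     vertices = patch_around(mesh, ctr, 5, s$lab))
  }
  # septal region centres (10 mm regions are resolved by locate_foci_groups)
  sept <- list(
    lv_sept_1    = list(c = vent$lv_c, a = vent$lv_ax, u = pi,       f = 0.70,
                        lab = "septum_lv"),
    lv_sept_2    = list(c = vent$lv_c, a = vent$lv_ax, u = 3 * pi / 4, f = 0.20,
                        lab = "septum_lv"),
    lv_sept_3    = list(c = vent$lv_c, a = vent$lv_ax, u = 0.9 * pi, f = 0.37,
                        lab = "septum_lv"),
    lv_sept_4    = list(c = vent$lv_c, a = vent$lv_ax, u = pi,       f = 0.53,
                        lab = "septum_lv"),
    rv_sept_apex = list(c = vent$rv_c, a = vent$rv_ax, u = 0,        f = 0.80,
                        lab = "septum_rv"),
    rv_sept_mid  = list(c = vent$rv_c, a = vent$rv_ax, u = 0,        f = 0.50,
                        lab = "septum_rv"))
  for (nm in names(sept)) {
    s <- sept[[nm]]
    ctr <- nearest_labeled_vertex(mesh, cavity_point(s$c, s$a, s$u, s$f), s$lab)
    lm[[nm]] <- list(kind = "septal", center = ctr, vertices = ctr)
  }
  lm
}

#' Rule-based circumferential fiber field
#'
#' Unit fiber directions tangent to the surface, circumferential about the
#' given long axis (cross product of the axis with the outward vertex
#' normal); falls back to an arbitrary tangent where the normal is parallel
#' to the axis (apex poles).
#'
#' @param mesh ventricular [trimesh()].
#' @param axis long-axis direction, default +z.
#' @return n x 3 matrix of unit vectors orthogonal to the vertex normals.
#' @export
make_fibers <- function(mesh, axis = c(0, 0, 1)) {
  n <- vertex_normals(mesh)
  ax <- matrix(axis / sqrt(sum(axis^2)), nrow(n), 3, byrow = TRUE)
  f <- cbind(ax[, 2] * n[, 3] - ax[, 3] * n[, 2],
             ax[, 3] * n[, 1] - ax[, 1] * n[, 3],
             ax[, 1] * n[, 2] - ax[, 2] * n[, 1])
  len <- sqrt(rowSums(f^2))
  bad <- len < 1e-6
  if (any(bad)) {
    alt <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
    nb <- n[bad, , drop = FALSE]
    f[bad, ] <- cbind(alt[, 2] * nb[, 3] - alt[, 3] * nb[, 2],
                      alt[, 3] * nb[, 1] - alt[, 1] * nb[, 3],
                      alt[, 1] * nb[, 2] - alt[, 2] * nb[, 1])
    len <- sqrt(rowSums(f^2))
  }
  f <- f / len
  # exact re-orthogonalization against the vertex normal
  f <- f - n * rowSums(f * n)
  f / sqrt(rowSums(f^2))
}

# farthest-point sampling of k vertices, deterministic start
farthest_points <- function(verts, k, start = 1L) {
  n <- nrow(verts)
  k <- min(k, n)
  sel <- integer(k)
  sel[1] <- start
  d2 <- rowSums((verts - matrix(verts[start, ], n, 3, byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    nxt <- which.max(d2)
    sel[i + 1L] <- nxt
    nd <- rowSums((verts - matrix(verts[nxt, ], n, 3, byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  sel
}

#' Generate the synthetic biventricular torso phantom
#'
#' Builds the nested closed surfaces (thorax, two lungs, LV/RV blood pools,
#' ventricular myocardium), the circumferential fiber field, the electrode
#' set and the nine His-Purkinje landmark regions.  Pure function of the
#' spec: the same spec yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `vc` (a [volume_conductor()]), `fibers`,
#'   `landmarks` (named list of nine landmark vertex sets on the
#'   myocardium), and `meshes` (named list of all surfaces).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  vent <- build_ventricles(spec)
  mesh <- vent$mesh
  nv <- nrow(mesh$vertices)
  if (nv < 500 || nv > 5000)
    stop("phantom resolution gives ", nv,
         " myocardial vertices (want 500..5000); adjust spec$resolution")
  set.seed(spec$seed + 1L)
  torso <- icosphere(3, radius = spec$torso_axes, center = c(0, -15, -55))
  lungs_r <- icosphere(2, radius = c(36, 62, 110), center = c(88, -15, -60))
  lungs_l <- icosphere(2, radius = c(36, 62, 110), center = c(-88, -15, -60))
  blood_lv <- capped_half_ellipsoid(vent$lv_c + c(0, 0, -2),
                                    0.82 * vent$lv_ax, 1.6 * spec$resolution)
  blood_rv <- capped_half_ellipsoid(vent$rv_c + c(0, 0, -2),
                                    0.82 * vent$rv_ax, 1.6 * spec$resolution)
  electrodes <- farthest_points(torso$vertices, spec$electrode_count)
  vc <- volume_conductor(
    surfaces = list(thorax = torso, lung_left = lungs_l, lung_right = lungs_r,
                    blood_lv = blood_lv, blood_rv = blood_rv,
                    myocardium = mesh),
    conductivity_inside = c(0.2, 0.04, 0.04, 0.6, 0.6, 0.2),
    conductivity_outside = c(0, 0.2, 0.2, 0.2, 0.2, 0.2),
    electrode_vertex_ids = electrodes,
    source = "myocardium")
  list(vc = vc, fibers = make_fibers(mesh), landmarks = place_landmarks(vent),
       meshes = vc$surfaces, spec = spec, vent = vent)
}

# closed surface: half ellipsoid (apex down) + flat base disk fan
capped_half_ellipsoid <- function(center, axes, h) {
  hs <- half_shell(center, axes, h)
  top <- c(center[1], center[2], center[3])
  verts <- rbind(hs$verts, top)
  topi <- nrow(verts)
  n_u <- hs$n_u
  k <- seq_len(n_u)
  fan <- cbind(hs$rim[k], hs$rim[c(k[-1], 1L)], rep(topi, n_u))
  orient_mesh(trimesh(verts, rbind(hs$tris, fan)))
}
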