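# Quantitative comparison machinery: BSPM match metrics, EAM alignment and
# projection, inter-map statistics, triangulation conduction velocity and
# breakthrough counting.

#' Electro-anatomical map point cloud
#'
#' @param points m x 3 positions (mm).
#' @param lat local activation times (ms).
#' @param voltage bipolar voltages (mV), optional.
#' @param surface one of `epi`, `rv_endo`, `lv_endo`.
#' @return object of class `eam_map`.
#' @export
eam_map <- function(points, lat, voltage = NULL,
                    surface = c("epi", "rv_endo", "lv_endo")) {
  points <- as.matrix(points)
  surface <- match.arg(surface)
  if (ncol(points) != 3) stop("points must be m x 3")
  if (length(lat) != nrow(points)) stop("lat must match points")
  if (!all(is.finite(points)) || !all(is.finite(lat)))
    stop("non-finite positions or LAT")
  if (is.null(voltage)) voltage <- rep(NA_real_, nrow(points))
  structure(list(points = points, lat = as.numeric(lat),
                 voltage = as.numeric(voltage), surface = surface),
            class = "eam_map")
}

#' Read/write the EAM CSV schema (x,y,z,lat_ms,bipolar_mV,surface)
#' @param x an [eam_map()].
#' @param path CSV path.
#' @export
write_eam <- function(x, path) {
  write.csv(data.frame(x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
                       lat_ms = x$lat, bipolar_mV = x$voltage,
                       surface = x$surface),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eam
#' @export
read_eam <- function(path) {
  df <- read.csv(path)
  eam_map(cbind(df$x, df$y, df$z), df$lat_ms, df$bipolar_mV,
          surface = df$surface[1])
}

#' BSPM match metrics: Pearson correlation and relative difference
#'
#' `cc` is the Pearson correlation over the concatenated entries; `rd` is
#' the Frobenius norm of the difference divided by the Frobenius norm of
#' the recorded map.
#'
#' @param V recorded [bspm()] (or matrix).
#' @param phi computed [bspm()] (or matrix) of identical shape.
#' @return list `(cc, rd)`.
#' @export
bspm_match <- function(V, phi) {
  Vm <- if (inherits(V, "bspm")) V$potentials else as.matrix(V)
  Pm <- if (inherits(phi, "bspm")) phi$potentials else as.matrix(phi)
  if (!all(dim(Vm) == dim(Pm))) stop("BSPM shapes differ")
  if (sd(as.vector(Vm)) == 0 || sd(as.vector(Pm)) == 0)
    stop("zero-variance input: correlation undefined")
  list(cc = stats::cor(as.vector(Vm), as.vector(Pm)),
       rd = norm(Vm - Pm, "F") / norm(Vm, "F"))
}

# Kabsch: least-squares rotation+translation mapping x onto y (det(R) = +1)
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  H <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.numeric(R %*% cx)
  list(R = R, t = t)
}

apply_rigid <- function(points, tf) {
  sweep(points %*% t(tf$R), 2, tf$t, "+")
}

#' Align an EAM point cloud to the imaging-based geometry
#'
#' Landmark-initialized rigid iterative closest point: the landmark pairs
#' give the starting rotation/translation (Kabsch, no scaling, det(R)=+1
#' enforced), then ICP alternates closest-point-on-surface projection with
#' rigid least squares until the RMS distance converges.
#'
#' @param eam an [eam_map()].
#' @param mesh target [trimesh()].
#' @param landmarks_eam,landmarks_mesh matched landmark coordinates
#'   (k x 3 each, k >= 3, non-collinear).
#' @param max_iterations ICP cap, default 50.
#' @param tol RMS-change convergence threshold (mm), default 1e-6.
#' @return list with `R`, `t`, `rms` (final RMS point-to-surface distance,
#'   mm) and `iterations`.
#' @export
align_eam <- function(eam, mesh, landmarks_eam, landmarks_mesh,
                      max_iterations = 50, tol = 1e-6) {
  landmarks_eam <- as.matrix(landmarks_eam)
  landmarks_mesh <- as.matrix(landmarks_mesh)
  if (nrow(landmarks_eam) < 3 || nrow(landmarks_mesh) != nrow(landmarks_eam))
    stop("need >= 3 matched landmark pairs")
  sv <- svd(sweep(landmarks_eam, 2, colMeans(landmarks_eam)))
  if (sv$d[2] < 1e-9 * sv$d[1]) stop("landmarks are collinear")
  tf <- kabsch(landmarks_eam, landmarks_mesh)
  pts <- eam$points
  rms_prev <- Inf
  n_increase <- 0L
  for (it in seq_len(max_iterations)) {
    moved <- apply_rigid(pts, tf)
    cp <- .closest_point_cpp(moved, mesh$vertices, mesh$triangles - 1L)
    rms <- sqrt(mean(cp$dist^2))
    if (rms > rms_prev + 1e-12) {
      n_increase <- n_increase + 1L
      if (n_increase >= 3L) stop("ICP diverged: RMS increased 3 times")
    } else n_increase <- 0L
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
    tf <- kabsch(pts, cp$point)
  }
  list(R = tf$R, t = tf$t, rms = rms, iterations = it)
}

#' Project EAM points onto the ventricular geometry
#'
#' Each (aligned) point snaps to its nearest triangle; points farther than
#' `max_dist` are excluded.  LAT and voltage are averaged per vertex over
#' the points assigned to the vertex's incident triangles.
#'
#' @param eam an aligned [eam_map()].
#' @param mesh target [trimesh()].
#' @param max_dist exclusion distance (mm), default 10.
#' @return list with per-vertex `lat` and `voltage` (NA where no data),
#'   `mask` (vertices receiving data), `coverage` (fraction of vertices),
#'   `n_used`, `n_excluded`.
#' @export
project_eam <- function(eam, mesh, max_dist = 10) {
  cp <- .closest_point_cpp(eam$points, mesh$vertices, mesh$triangles - 1L)
  keep <- cp$dist <= max_dist
  if (!any(keep)) warning("no EAM point within ", max_dist, " mm of the mesh")
  n <- nrow(mesh$vertices)
  lat <- rep(NA_real_, n); volt <- rep(NA_real_, n)
  if (any(keep)) {
    tri <- cp$triangle[keep]
    vids <- mesh$triangles[tri, , drop = FALSE] # 3 candidate vertices
    # each point feeds the nearest vertex of its snapped triangle
    proj <- cp$point[keep, , drop = FALSE]
    d2 <- vapply(1:3, function(j)
      rowSums((mesh$vertices[vids[, j], , drop = FALSE] - proj)^2),
      numeric(sum(keep)))
    vv <- vids[cbind(seq_len(nrow(vids)), max.col(-d2))]
    lat_sum <- tabulate2(vv, eam$lat[keep], n)
    cnt <- tabulate(vv, nbins = n)
    got <- cnt > 0
    lat[got] <- lat_sum[got] / cnt[got]
    pv <- eam$voltage[keep]
    if (!all(is.na(pv))) {
      volt_sum <- tabulate2(vv, ifelse(is.na(pv), 0, pv), n)
      volt[got] <- volt_sum[got] / cnt[got]
    }
  }
  mask <- which(!is.na(lat))
  list(lat = lat, voltage = volt, mask = mask,
       coverage = length(mask) / n, n_used = sum(keep),
       n_excluded = sum(!keep))
}

#' Inter-map comparison: Pearson CC and mean absolute LAT difference
#'
#' @param estimate per-vertex LAT (ms).
#' @param reference per-vertex LAT (ms), NA where unmapped.
#' @param mask vertex ids with reference data (default: non-NA reference).
#' @return list `(cc, mean_abs_diff)`.
#' @export
inter_map <- function(estimate, reference, mask = which(!is.na(reference))) {
  if (length(mask) < 3) stop("inter_map needs at least 3 masked vertices")
  e <- estimate[mask]; r <- reference[mask]
  list(cc = stats::cor(e, r), mean_abs_diff = mean(abs(e - r)))
}

#' Triangulation-based conduction velocity
#'
#' Per triangle, solves the in-plane LAT gradient from the two edge
#' equations under the locally-planar wavefront assumption; speed is the
#' inverse gradient magnitude and direction the in-plane unit gradient
#' (pointing in the travel direction).  Speeds above the exclusion
#' threshold (wavefronts arriving almost simultaneously, e.g. at
#' breakthrough sites) are masked as NA.
#'
#' @param mesh a [trimesh()].
#' @param lat per-vertex LAT (ms).
#' @param exclude_above speed exclusion threshold (mm/ms); 5 by default,
#'   use 3 to also suppress apparent speeds around simultaneous
#'   breakthroughs.
#' @return list with `speed` (per triangle, mm/ms, NA when masked),
#'   `direction` (k x 3 unit vectors) and `raw_speed` (unmasked).
#' @export
triangulation_cv <- function(mesh, lat, exclude_above = 5) {
  tr <- mesh$triangles
  if (length(lat) != nrow(mesh$vertices)) stop("lat must be per-vertex")
  p1 <- mesh$vertices[tr[, 1], , drop = FALSE]
  e1 <- mesh$vertices[tr[, 2], , drop = FALSE] - p1
  e2 <- mesh$vertices[tr[, 3], , drop = FALSE] - p1
  dt1 <- lat[tr[, 2]] - lat[tr[, 1]]
  dt2 <- lat[tr[, 3]] - lat[tr[, 1]]
  # solve g = a e1 + b e2 with g.e1 = dt1, g.e2 = dt2
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  det <- a11 * a22 - a12^2
  a <- (dt1 * a22 - dt2 * a12) / det
  b <- (dt2 * a11 - dt1 * a12) / det
  g <- e1 * a + e2 * b
  gn <- sqrt(rowSums(g^2))
  speed <- ifelse(gn > 1e-12, 1 / gn, Inf)
  dir <- g / pmax(gn, 1e-300)
  masked <- speed
  masked[!is.finite(speed) | speed > exclude_above] <- NA_real_
  list(speed = masked, direction = dir, raw_speed = speed)
}

#' Count activation breakthroughs on a surface
#'
#' A breakthrough is a distinct region of locally earliest activation:
#' vertices whose LAT does not exceed that of any vertex within graph
#' distance `radius`, clustered by adjacency, and retained only when the
#' cluster minimum is at least `prominence` below the surrounding LAT just
#' outside the radius.
#'
#' @param mesh a [trimesh()].
#' @param lat per-vertex LAT (ms); NA vertices are ignored.
#' @param mask vertex ids defining the surface of interest (default: all).
#' @param radius neighbourhood radius (mm), default 10.
#' @param prominence minimal depth below the surround (ms), default 5.
#' @return number of breakthrough regions.
#' @export
count_breakthroughs <- function(mesh, lat, mask = seq_along(lat),
                                radius = 10, prominence = 5) {
  mask <- intersect(mask, which(!is.na(lat)))
  if (!length(mask)) return(0L)
  edges <- unique_edges(mesh)
  keep <- edges[, 1] %in% mask & edges[, 2] %in% mask
  edges <- edges[keep, , drop = FALSE]
  w <- edge_lengths(mesh, edges)
  n <- nrow(mesh$vertices)
  inmask <- logical(n); inmask[mask] <- TRUE
  # local minima within the graph-distance radius
  is_min <- logical(n)
  for (v in mask) {
    d <- .dijkstra_cpp(n, edges[, 1] - 1L, edges[, 2] - 1L, w, v - 1L, 0)
    near <- which(d <= radius & inmask)
    ring <- which(d > radius & d <= 2 * radius & inmask)
    if (all(lat[v] <= lat[near])) {
      surround <- if (length(ring)) min(lat[ring]) else
        max(lat[near])
      if (surround - lat[v] >= prominence) is_min[v] <- TRUE
    }
  }
  mins <- which(is_min)
  if (!length(mins)) return(0L)
  # cluster minima within the radius of each other
  cluster <- integer(0)
  labels <- rep(0L, n)
  nxt <- 0L
  for (v in mins) {
    if (labels[v] > 0L) next
    nxt <- nxt + 1L
    d <- .dijkstra_cpp(n, edges[, 1] - 1L, edges[, 2] - 1L, w, v - 1L, 0)
    grp <- mins[d[mins] <= radius]
    labels[grp[labels[grp] == 0L]] <- nxt
  }
  length(unique(labels[mins]))
}

#' Per-surface metrics report
#'
#' Bundles the inter-map statistics, median triangulation conduction
#' velocity and breakthrough count for an estimated LAT map against a
#' reference on one surface.
#'
#' @param mesh ventricular [trimesh()].
#' @param estimate per-vertex estimated LAT (ms).
#' @param reference per-vertex reference LAT (NA where unmapped).
#' @param surface label selecting the surface (`epi`, `rv_endo`, ...), or
#'   `NULL` for all vertices.
#' @param cv_exclude speed exclusion threshold (mm/ms), default 5.
#' @return list with `cc`, `mean_abs_diff`, `median_cv`, `n_breakthroughs`,
#'   `coverage`.
#' @export
surface_metrics <- function(mesh, estimate, reference, surface = NULL,
                            cv_exclude = 5) {
  ids <- if (is.null(surface)) seq_len(nrow(mesh$vertices)) else
    which(mesh$labels %in% surface)
  mask <- intersect(ids, which(!is.na(reference)))
  # time-reference: align earliest masked LAT
  est <- estimate - min(estimate[mask]) + min(reference[mask])
  im <- inter_map(est, reference, mask)
  tri_on <- which(rowSums(matrix(mesh$triangles %in% ids,
                                 ncol = 3)) == 3L)
  cv <- triangulation_cv(mesh, estimate, exclude_above = cv_exclude)
  list(cc = im$cc, mean_abs_diff = im$mean_abs_diff,
       median_cv = median(cv$speed[tri_on], na.rm = TRUE),
       n_breakthroughs = count_breakthroughs(mesh, estimate, mask = ids),
       coverage = length(mask) / length(ids))
}
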