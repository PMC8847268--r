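# Fastest-route activation simulation: anisotropic earliest-arrival times on
# the ventricular surface graph.

#' Conduction velocity field
#'
#' Per-vertex longitudinal (along-fiber) speed with a fixed anisotropy
#' ratio.  Vertices within `boost_radius` (graph travel distance along the
#' surface, not chord distance) of any focus get `boost_speed`, emulating
#' the fast sub-endocardial layer near Purkinje-myocardial junctions.
#'
#' @param mesh ventricular [trimesh()].
#' @param focus_set integer vertex ids of foci (may be empty).
#' @param base_speed longitudinal speed elsewhere (mm/ms), default 0.85.
#' @param boost_radius radius of the fast region (mm), default 15.
#' @param boost_speed speed inside the fast region (mm/ms), default 1.7.
#' @param anisotropy_ratio longitudinal:transverse ratio (>= 1), default 2.
#' @return object of class `velocity_field`: list with `speed` (per vertex,
#'   mm/ms) and `anisotropy_ratio`.
#' @export
build_velocity_field <- function(mesh, focus_set = integer(0),
                                 base_speed = 0.85, boost_radius = 15,
                                 boost_speed = 1.7, anisotropy_ratio = 2) {
  if (nrow(mesh$vertices) == 0) stop("empty mesh")
  stopifnot(base_speed > 0, boost_speed > 0, boost_radius >= 0,
            anisotropy_ratio >= 1)
  speed <- rep(base_speed, nrow(mesh$vertices))
  focus_set <- unique(as.integer(focus_set))
  if (length(focus_set) && boost_radius > 0) {
    d <- surface_distances(mesh, focus_set)
    speed[d < boost_radius] <- boost_speed
  }
  structure(list(speed = speed, anisotropy_ratio = anisotropy_ratio),
            class = "velocity_field")
}

#' Activation sequence
#'
#' Local activation time (LAT, ms) per ventricular vertex together with the
#' foci that generated it.
#'
#' @param lat numeric LAT per vertex (ms).
#' @param foci list of `list(vertices =, t0 =)` entries.
#' @return object of class `activation_sequence`.
#' @export
activation_sequence <- function(lat, foci = list()) {
  structure(list(lat = as.numeric(lat), foci = foci),
            class = "activation_sequence")
}

#' @export
print.activation_sequence <- function(x, ...) {
  cat(sprintf("activation_sequence: %d nodes, %d foci, duration %.1f ms\n",
              length(x$lat), length(x$foci), total_duration(x)))
  invisible(x)
}

# augmented FRA graph: mesh edges plus second-ring shortcuts (each interior
# edge contributes the edge between the two opposite triangle vertices),
# reducing the metrication error of graph geodesics
fra_graph <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2, 3)], tr[, c(2, 3, 1)], tr[, c(3, 1, 2)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sp <- split(e[, 3], key)
  opp <- sp[lengths(sp) == 2L]
  shortcut <- do.call(rbind, unname(opp[vapply(opp, function(x)
    x[1] != x[2], TRUE)]))
  base <- unique_edges(mesh)
  edges <- rbind(base, shortcut)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges[!duplicated(edges), , drop = FALSE]
}

edge_lengths <- function(mesh, edges) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
    mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

# isotropic unit-speed graph distance from a source set (mesh edges +
# shortcuts); used for the boost region
surface_distances <- function(mesh, sources) {
  edges <- fra_graph(mesh)
  w <- edge_lengths(mesh, edges)
  .dijkstra_cpp(nrow(mesh$vertices), edges[, 1] - 1L, edges[, 2] - 1L, w,
                as.integer(sources) - 1L, rep(0, length(sources)))
}

# anisotropic edge travel times: elliptical group-velocity law with
# v_t = v_l / ratio and theta the angle between the edge and the local fiber
edge_travel_times <- function(mesh, field, fibers, edges = fra_graph(mesh)) {
  len <- edge_lengths(mesh, edges)
  v_l <- (field$speed[edges[, 1]] + field$speed[edges[, 2]]) / 2
  r <- field$anisotropy_ratio
  if (is.null(fibers) || r == 1) return(list(edges = edges, w = len / v_l))
  dvec <- mesh$vertices[edges[, 2], , drop = FALSE] -
    mesh$vertices[edges[, 1], , drop = FALSE]
  dvec <- dvec / pmax(len, 1e-300)
  f1 <- fibers[edges[, 1], , drop = FALSE]
  f2 <- fibers[edges[, 2], , drop = FALSE]
  # sign-corrected mean of endpoint fibers (fibers are axes, not vectors)
  flip <- rowSums(f1 * f2) < 0
  f2[flip, ] <- -f2[flip, , drop = FALSE]
  fm <- f1 + f2
  fm <- fm / pmax(sqrt(rowSums(fm^2)), 1e-300)
  cth <- pmin(1, abs(rowSums(dvec * fm)))
  sth2 <- 1 - cth^2
  v_t <- v_l / r
  v <- v_l * v_t / sqrt(v_t^2 * cth^2 + v_l^2 * sth2)
  list(edges = edges, w = len / v)
}

#' Fastest route algorithm: earliest-arrival activation times
#'
#' Multi-source shortest travel times on the augmented surface graph (mesh
#' edges plus second-ring shortcuts).  Edge speed follows the elliptical
#' anisotropy law `v(theta) = v_l v_t / sqrt(v_t^2 cos^2 + v_l^2 sin^2)`
#' with `theta` measured from the local fiber direction and
#' `v_t = v_l / ratio`.  Multi-source merging is exactly the pointwise
#' minimum over foci of `t0 + travel time`.
#'
#' @param mesh ventricular [trimesh()].
#' @param field a [build_velocity_field()] result.
#' @param fibers n x 3 unit fiber directions, or `NULL` for isotropic.
#' @param foci list of `list(vertices =, t0 =)`; vertex sets share one `t0`.
#' @return an [activation_sequence()].
#' @export
fastest_route <- function(mesh, field, fibers, foci) {
  if (!length(foci)) stop("at least one focus required")
  foci <- lapply(foci, function(f) {
    if (is.null(f$t0)) f$t0 <- 0
    f$vertices <- as.integer(f$vertices)
    f
  })
  if (any(vapply(foci, function(f) f$t0 < 0, TRUE)))
    stop("focus initial times must be >= 0")
  et <- edge_travel_times(mesh, field, fibers)
  src <- unlist(lapply(foci, `[[`, "vertices"))
  t0 <- unlist(lapply(foci, function(f) rep(f$t0, length(f$vertices))))
  lat <- .dijkstra_cpp(nrow(mesh$vertices), et$edges[, 1] - 1L,
                       et$edges[, 2] - 1L, et$w, src - 1L, t0)
  if (any(!is.finite(lat)))
    stop("disconnected component unreached from the foci: vertices ",
         paste(head(which(!is.finite(lat)), 5), collapse = ", "),
         if (sum(!is.finite(lat)) > 5) ", ..." else "")
  activation_sequence(lat, foci)
}

#' Total activation duration (ms)
#' @param seq an [activation_sequence()] or numeric LAT vector.
#' @export
total_duration <- function(seq) {
  lat <- if (inherits(seq, "activation_sequence")) seq$lat else as.numeric(seq)
  max(lat) - min(lat)
}

#' QRS-duration gate for candidate activation sequences
#'
#' Candidates whose total activation duration lies outside 85..115% of the
#' measured QRS duration are excluded (boundaries inclusive: the exclusion
#' rule is strict, so a candidate at exactly 85% or 115% passes).
#'
#' @param seq an [activation_sequence()] or numeric LAT vector.
#' @param qrs_ms measured QRS duration (ms), > 0.
#' @return `TRUE` (pass) or `FALSE` (excluded).
#' @export
duration_gate <- function(seq, qrs_ms) {
  stopifnot(qrs_ms > 0)
  d <- total_duration(seq)
  eps <- 1e-9 * qrs_ms # boundary values pass despite rounding
  d >= 0.85 * qrs_ms - eps && d <= 1.15 * qrs_ms + eps
}

#' Export an activation sequence
#'
#' CSV (`vertex_id, lat_ms`) or VTK point data for visualization.
#' @param seq an [activation_sequence()].
#' @param path destination (`.csv` or `.vtk`).
#' @param mesh required for VTK output.
#' @return invisibly `path`.
#' @export
write_activation <- function(seq, path, mesh = NULL) {
  if (grepl("\\.csv$", path)) {
    write.csv(data.frame(vertex_id = seq_along(seq$lat), lat_ms = seq$lat),
              path, row.names = FALSE)
  } else if (grepl("\\.vtk$", path)) {
    if (is.null(mesh)) stop("VTK export needs the mesh")
    write_mesh(mesh, path, format = "vtk", point_data = list(lat_ms = seq$lat))
  } else stop("unsupported extension for activation export: ", path)
  invisible(path)
}
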