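#' @useDynLib edlwave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft median quantile rnorm runif sd setNames spline
#' @importFrom utils head read.csv write.csv
NULL

VERTEX_LABELS <- c("lv_endo", "rv_endo", "epi", "septum_lv", "septum_rv", "other")

#' Triangulated surface mesh
#'
#' Creates a `trimesh`: a triangulated surface with vertex positions in
#' millimetres and an optional per-vertex surface label.  All geometry in the
#' package (volume conductor surfaces, the ventricular source surface) is
#' carried in this container.
#'
#' @param vertices numeric matrix, n x 3, positions in mm.
#' @param triangles integer matrix, k x 3, 1-based vertex indices.
#' @param labels character vector of length n with values in
#'   `lv_endo`, `rv_endo`, `epi`, `septum_lv`, `septum_rv`, `other`;
#'   defaults to `"other"`.
#' @return object of class `trimesh` with elements `vertices`, `triangles`,
#'   `labels`.
#' @export
trimesh <- function(vertices, triangles, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be a k x 3 matrix")
  n <- nrow(vertices)
  if (nrow(triangles) > 0 && (min(triangles) < 1L || max(triangles) > n))
    stop("triangle indices out of range [1, ", n, "]")
  if (any(triangles[, 1] == triangles[, 2] | triangles[, 2] == triangles[, 3] |
          triangles[, 1] == triangles[, 3]))
    stop("degenerate triangle: repeated vertex index")
  if (is.null(labels)) labels <- rep("other", n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have one entry per vertex")
  bad <- setdiff(unique(labels), VERTEX_LABELS)
  if (length(bad)) stop("unknown vertex labels: ", paste(bad, collapse = ", "))
  structure(list(vertices = vertices, triangles = triangles, labels = labels),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is_closed(x)) " (closed)" else ""))
  tab <- table(x$labels)
  if (!identical(names(tab), "other"))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# ---- topology -------------------------------------------------------------

# all (sorted) edges with multiplicity; rows of the k x 3 triangle matrix
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# unique undirected edges (two-column matrix) with lengths
unique_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  e <- e[!duplicated(e), , drop = FALSE]
  e
}

edge_use_count <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  table(key)
}

#' Is every edge of the mesh shared by exactly two triangles?
#'
#' Closedness (edge-manifoldness with no boundary) is a precondition for
#' boundary element surfaces and for solid-angle identities.
#' @param mesh a [trimesh()].
#' @return logical scalar.
#' @export
is_closed <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(FALSE)
  all(edge_use_count(mesh) == 2L)
}

#' Assert BEM-usability of a surface
#'
#' Errors with the offending edges when the surface is open or non-manifold,
#' or when degenerate (zero-area) triangles are present.
#' @param mesh a [trimesh()].
#' @param name surface name used in error messages.
#' @return invisibly `TRUE`.
#' @export
assert_closed <- function(mesh, name = "surface") {
  cnt <- edge_use_count(mesh)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad))
    stop(sprintf("%s is not closed/manifold: %d edge(s) not shared by exactly 2 triangles (e.g. %s)",
                 name, length(bad), paste(head(bad, 3), collapse = "; ")))
  ar <- triangle_areas(mesh)
  if (any(ar <= 1e-12))
    stop(sprintf("%s has %d degenerate (zero-area) triangle(s)", name, sum(ar <= 1e-12)))
  invisible(TRUE)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangle_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  if (normalize) n / pmax(sqrt(rowSums(n^2)), 1e-300) else n
}

triangle_centroids <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

#' Area-weighted outward vertex normals
#' @param mesh a [trimesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  tn <- triangle_normals(mesh, normalize = FALSE) # area-weighted
  n <- matrix(0, nrow(mesh$vertices), 3)
  tr <- mesh$triangles
  for (j in 1:3) {
    n[, 1] <- n[, 1] + tabulate2(tr[, j], tn[, 1], nrow(n))
    n[, 2] <- n[, 2] + tabulate2(tr[, j], tn[, 2], nrow(n))
    n[, 3] <- n[, 3] + tabulate2(tr[, j], tn[, 3], nrow(n))
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# sum w by integer bin (dense result of length nbins)
tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  tmp <- rowsum(w, bin)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

#' Signed volume enclosed by a closed surface
#' @param mesh a closed [trimesh()]; positive for outward winding.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]; b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Orient a closed mesh consistently with outward normals
#'
#' Propagates a consistent winding across shared edges (breadth-first) and
#' then flips globally so the signed volume is positive (outward normals).
#' @param mesh a closed, connected [trimesh()].
#' @return re-wound `trimesh`.
#' @export
orient_mesh <- function(mesh) {
  tr <- mesh$triangles
  k <- nrow(tr)
  # map directed edges -> triangle
  ekey <- function(a, b) paste(a, b)
  tri_of <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_len(k)) {
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      key <- ekey(min(tr[t, e[1]], tr[t, e[2]]), max(tr[t, e[1]], tr[t, e[2]]))
      tri_of[[key]] <- c(tri_of[[key]], t)
    }
  }
  visited <- rep(FALSE, k)
  flip <- rep(FALSE, k)
  queue <- 1L; visited[1] <- TRUE
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    ot <- if (flip[t]) tr[t, c(1, 3, 2)] else tr[t, ]
    dir_edges <- list(ot[c(1, 2)], ot[c(2, 3)], ot[c(3, 1)])
    for (de in dir_edges) {
      key <- ekey(min(de), max(de))
      for (u in tri_of[[key]]) {
        if (u == t || visited[u]) next
        ou <- tr[u, ]
        # neighbor must traverse the shared edge in the opposite direction
        has_same_dir <- any(
          (ou[c(1, 2, 3)] == de[1] & ou[c(2, 3, 1)] == de[2]))
        flip[u] <- has_same_dir
        visited[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  if (!all(visited)) stop("orient_mesh: mesh is not edge-connected")
  tr[flip, ] <- tr[flip, c(1, 3, 2), drop = FALSE]
  out <- mesh
  out$triangles <- tr
  if (mesh_volume(out) < 0) out$triangles <- tr[, c(1, 3, 2)]
  out
}

# ---- solid angles ---------------------------------------------------------

#' Signed per-triangle solid angles
#'
#' Computes the signed solid angle (steradians) subtended by every triangle
#' of `mesh` as seen from `point`, by the van Oosterom-Strackee formula.
#' With outward winding the angles of a closed surface sum to `-4*pi` from
#' an interior point and `0` from an exterior point.
#'
#' @param mesh a [trimesh()].
#' @param point numeric length-3 position (mm), not on the surface.
#' @param tol distance below which the point is considered to lie on the
#'   surface (singularity guard), in mm.
#' @return numeric vector, one signed solid angle per triangle.
#' @export
solid_angle <- function(mesh, point, tol = 1e-9) {
  point <- as.numeric(point)
  if (length(point) != 3) stop("point must be a 3-vector")
  cp <- .closest_point_cpp(matrix(point, 1, 3), mesh$vertices, mesh$triangles - 1L)
  if (cp$dist[1] < tol)
    stop("solid_angle: point lies on the surface (distance ",
         format(cp$dist[1]), " mm)")
  drop(.solid_angle_matrix_cpp(matrix(point, 1, 3), mesh$vertices,
                               mesh$triangles - 1L))
}

# solid angles of many triangles from many points, no singularity guard
solid_angle_matrix <- function(points, mesh) {
  .solid_angle_matrix_cpp(as.matrix(points), mesh$vertices, mesh$triangles - 1L)
}

#' Point-in-mesh test by winding number
#' @param mesh closed [trimesh()] with outward normals.
#' @param points m x 3 matrix.
#' @return logical vector: `TRUE` when inside.
#' @export
point_in_mesh <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  om <- solid_angle_matrix(points, mesh)
  abs(rowSums(om) + 4 * pi) < 2 * pi # inside ~ -4pi, outside ~ 0
}

# ---- surface Laplacian ----------------------------------------------------

#' Umbrella surface Laplacian operator
#'
#' Sparse nodes x nodes operator with uniform ("umbrella") weights:
#' `(L d)[i] = mean(d[neighbours(i)]) - d[i]`.  Rows sum to zero, so the
#' operator annihilates constants; it is the smoothness penalty used by the
#' Levenberg-Marquardt refinement.
#'
#' @param mesh a [trimesh()] without isolated vertices.
#' @return a `dgCMatrix`.
#' @export
surface_laplacian <- function(mesh) {
  e <- unique_edges(mesh)
  n <- nrow(mesh$vertices)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  if (any(deg == 0)) stop("surface_laplacian: isolated vertex present")
  i <- c(e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1])
  x <- 1 / deg[i]
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  A - Matrix::Diagonal(n)
}

# vertex adjacency list (list of integer vectors)
vertex_adjacency <- function(mesh) {
  e <- unique_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  sp <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  adj[as.integer(names(sp))] <- lapply(sp, as.integer)
  adj
}
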