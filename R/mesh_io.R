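# Plain-text mesh I/O: ASCII PLY, Wavefront OBJ and legacy ASCII VTK
# POLYDATA.  Labels travel in an optional JSON sidecar (<file>.labels.json)
# because none of the three formats has a standard per-vertex string channel.

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         ply = "ply", obj = "obj", vtk = "vtk",
         stop("cannot infer mesh format from extension of ", path))
}

#' Read a triangulated surface mesh
#'
#' Supports ASCII PLY, OBJ and legacy ASCII VTK POLYDATA.  Per-vertex labels
#' are restored from a `<file>.labels.json` sidecar when present, otherwise
#' all vertices are labelled `"other"`.  Non-manifold edges (shared by more
#' than two triangles, e.g. a duplicated triangle) are always an error;
#' open surfaces are an error only when `check_closed = TRUE` (BEM use).
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"` or `"vtk"`; inferred from the extension
#'   by default.
#' @param check_closed require a closed surface.
#' @return a [trimesh()].
#' @export
read_mesh <- function(path, format = guess_format(path), check_closed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- switch(format,
                   ply = read_ply(path),
                   obj = read_obj(path),
                   vtk = read_vtk(path),
                   stop("unsupported mesh format: ", format))
  labels <- NULL
  sidecar <- paste0(path, ".labels.json")
  if (file.exists(sidecar)) {
    labels <- as.character(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  mesh <- trimesh(parsed$vertices, parsed$triangles, labels)
  cnt <- edge_use_count(mesh)
  over <- names(cnt)[cnt > 2L]
  if (length(over))
    stop(sprintf("non-manifold surface in %s: edge(s) shared by >2 triangles: %s",
                 path, paste(head(over, 5), collapse = "; ")))
  if (check_closed) assert_closed(mesh, path)
  mesh
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "ply") stop("not a PLY file: ", path)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("PLY parse failure: missing end_header in ", path)
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("PLY parse failure: missing elements in ", path)
  body <- lines[(hdr_end + 1):length(lines)]
  vl <- body[seq_len(nv)]
  verts <- matrix(scan(text = vl, quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- body[nv + seq_len(nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("PLY: only triangular faces supported")
    x[2:4] + 1L
  }))
  list(vertices = verts, triangles = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("OBJ parse failure in ", path)
  verts <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  faces <- do.call(rbind, lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*$", "", x))
    if (length(idx) != 3L) stop("OBJ: only triangular faces supported")
    idx
  }))
  list(vertices = verts, triangles = faces)
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pi_ <- grep("^POINTS", lines)
  if (!length(pi_)) stop("VTK parse failure: no POINTS in ", path)
  nv <- as.integer(strsplit(lines[pi_], "\\s+")[[1]][2])
  nums <- numeric(0)
  i <- pi_ + 1L
  while (length(nums) < 3 * nv) {
    nums <- c(nums, scan(text = lines[i], quiet = TRUE))
    i <- i + 1L
  }
  verts <- matrix(nums[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  fi <- grep("^POLYGONS", lines)
  if (!length(fi)) stop("VTK parse failure: no POLYGONS in ", path)
  nf <- as.integer(strsplit(lines[fi], "\\s+")[[1]][2])
  fl <- lines[fi + seq_len(nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("VTK: only triangular polygons supported")
    x[2:4] + 1L
  }))
  list(vertices = verts, triangles = faces)
}

#' Write a triangulated surface mesh
#'
#' Writes ASCII PLY, OBJ or legacy ASCII VTK POLYDATA, plus a
#' `<file>.labels.json` sidecar when the mesh carries non-trivial labels.
#'
#' @param mesh a [trimesh()].
#' @param path destination path.
#' @param format `"ply"`, `"obj"` or `"vtk"`; inferred from the extension.
#' @param point_data optional named list of per-vertex numeric vectors,
#'   written as POINT_DATA scalars (VTK only).
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path, format = guess_format(path),
                       point_data = NULL) {
  v <- mesh$vertices; tr <- mesh$triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  fmt_rows <- function(m) apply(m, 1, paste, collapse = " ")
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(tr)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(fmt_rows(v), con)
    writeLines(paste(3, fmt_rows(tr)), con)
  } else if (format == "obj") {
    writeLines(paste("v", fmt_rows(v)), con)
    writeLines(paste("f", fmt_rows(tr + 1L)), con)
  } else if (format == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", "edlwave surface", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(v))), con)
    writeLines(fmt_rows(v), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4 * nrow(tr)), con)
    writeLines(paste(3, fmt_rows(tr)), con)
    if (!is.null(point_data)) {
      writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
      for (nm in names(point_data)) {
        writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(format(point_data[[nm]], digits = 9), con)
      }
    }
  } else stop("unsupported mesh format: ", format)
  if (!all(mesh$labels == "other"))
    jsonlite::write_json(mesh$labels, paste0(path, ".labels.json"))
  invisible(path)
}

# ---- simple generators used by tests and the phantom ----------------------

#' Icosphere
#'
#' Subdivided icosahedron projected onto a sphere; the workhorse closed
#' test surface (lungs, torso oracle spheres).
#' @param subdiv number of 4-to-1 subdivisions (0 = icosahedron).
#' @param radius sphere radius (mm), or length-3 half-axes for an ellipsoid.
#' @param center length-3 centre.
#' @return closed [trimesh()] with outward normals.
#' @export
icosphere <- function(subdiv = 2, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    midcache <- new.env(hash = TRUE, parent = emptyenv())
    nf <- matrix(0L, 0, 3)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      m <- midcache[[key]]
      if (is.null(m)) {
        p <- v[a, ] + v[b, ]
        p <- p / sqrt(sum(p^2))
        v <<- rbind(v, p)
        m <- nrow(v)
        midcache[[key]] <- m
      }
      m
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  radius <- rep(as.numeric(radius), length.out = 3)
  v <- sweep(sweep(v, 2, radius, "*"), 2, as.numeric(center), "+")
  orient_mesh(trimesh(v, f))
}

#' Flat rectangular sheet mesh in the xy-plane
#'
#' Open surface used for anisotropy and Laplacian refinement tests.
#' @param nx,ny grid points along x and y.
#' @param lx,ly side lengths (mm).
#' @return [trimesh()] (open), vertices on a regular grid at z = 0.
#' @export
sheet_mesh <- function(nx = 21, ny = 21, lx = 100, ly = 100) {
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  f <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    f <- rbind(f,
               c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  trimesh(v, f)
}
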