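# Equivalent double layer forward model: boundary element volume conductor
# and activation-time -> body-surface-potential computation.

#' Volume conductor model
#'
#' Ordered set of closed surfaces with inside/outside conductivities and the
#' electrode vertex ids on the outermost (thorax) surface.  The source
#' surface (ventricular myocardium) is part of the list; when its inside and
#' outside conductivities are equal it is not a conductivity interface and
#' contributes only as the equivalent double layer.
#'
#' @param surfaces named list of closed [trimesh()] objects; the first must
#'   be the outermost (thorax) surface.
#' @param conductivity_inside,conductivity_outside S/m per surface; the
#'   thorax outside conductivity is 0 (air).
#' @param electrode_vertex_ids vertex indices on the thorax mesh.
#' @param source name of the source surface (default `"myocardium"`).
#' @return object of class `volume_conductor`.
#' @export
volume_conductor <- function(surfaces, conductivity_inside,
                             conductivity_outside, electrode_vertex_ids,
                             source = "myocardium") {
  stopifnot(is.list(surfaces), length(surfaces) >= 1,
            length(conductivity_inside) == length(surfaces),
            length(conductivity_outside) == length(surfaces))
  if (is.null(names(surfaces)) || any(names(surfaces) == ""))
    stop("surfaces must be a named list")
  if (!source %in% names(surfaces)) stop("source surface '", source, "' missing")
  if (any(conductivity_inside <= 0)) stop("inside conductivities must be > 0")
  if (any(conductivity_outside < 0)) stop("conductivities must be >= 0")
  if (conductivity_outside[1] != 0)
    stop("outermost surface must have outside conductivity 0 (air)")
  for (nm in names(surfaces)) assert_closed(surfaces[[nm]], nm)
  nthx <- nrow(surfaces[[1]]$vertices)
  ids <- as.integer(electrode_vertex_ids)
  if (any(ids < 1L | ids > nthx)) stop("electrode vertex ids out of range")
  structure(list(surfaces = surfaces,
                 conductivity_inside = as.numeric(conductivity_inside),
                 conductivity_outside = as.numeric(conductivity_outside),
                 electrode_vertex_ids = ids,
                 source = source),
            class = "volume_conductor")
}

#' @export
print.volume_conductor <- function(x, ...) {
  cat("volume_conductor:\n")
  for (i in seq_along(x$surfaces))
    cat(sprintf("  %-12s %5d vertices  sigma %.2f/%.2f S/m%s\n",
                names(x$surfaces)[i], nrow(x$surfaces[[i]]$vertices),
                x$conductivity_inside[i], x$conductivity_outside[i],
                if (names(x$surfaces)[i] == x$source) "  [source]" else ""))
  cat(sprintf("  %d electrodes on %s\n", length(x$electrode_vertex_ids),
              names(x$surfaces)[1]))
  invisible(x)
}

# lumped linear solid-angle weights: points x vertices matrix with each
# triangle's angle split equally over its three vertices
lumped_omega <- function(points, mesh) {
  om <- solid_angle_matrix(points, mesh) # points x triangles
  tr <- mesh$triangles
  n <- nrow(mesh$vertices)
  Lmp <- Matrix::sparseMatrix(i = as.vector(tr), j = rep(seq_len(nrow(tr)), 3),
                              x = 1 / 3, dims = c(n, nrow(tr)))
  as.matrix(Matrix::tcrossprod(Matrix::Matrix(om, sparse = FALSE), Lmp))
}

#' Solve the piecewise-homogeneous BEM system for given primary potentials
#'
#' Low-level solver behind [build_transfer_matrix()], exposed so that the
#' volume conductor can be validated against analytic sources (e.g. a dipole
#' in a homogeneous sphere).  Collocates at every vertex of every
#' conductivity interface, fixes the principal-value diagonal through the
#' closed-surface solid-angle identity, and deflates the singular outer
#' (insulated) boundary operator by rank-one subtraction.
#'
#' @param vc a [volume_conductor()].
#' @param phi_inf matrix (or vector) of infinite-medium potentials at the
#'   interface collocation vertices (stacked in surface order), one column
#'   per independent source.
#' @param sigma_source conductivity of the source medium (S/m).
#' @return list with `potentials` (same shape as `phi_inf`; interface
#'   potentials, thorax block zero-meaned), `interface_index` (data frame
#'   mapping collocation rows to surface/vertex), and `condition` (estimated
#'   reciprocal condition number of the deflated system).
#' @export
bem_solve <- function(vc, phi_inf, sigma_source) {
  ifc <- which(vc$conductivity_inside != vc$conductivity_outside)
  if (!1L %in% ifc) stop("outer surface must be a conductivity interface")
  meshes <- vc$surfaces[ifc]
  s_in <- vc$conductivity_inside[ifc]
  s_out <- vc$conductivity_outside[ifc]
  nv <- vapply(meshes, function(m) nrow(m$vertices), 1L)
  offs <- cumsum(c(0L, nv))
  ntot <- offs[length(offs)]
  pts <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  phi_inf <- as.matrix(phi_inf)
  if (nrow(phi_inf) != ntot)
    stop("phi_inf must have one row per interface vertex (", ntot, ")")

  M <- matrix(0, ntot, ntot)
  for (l in seq_along(meshes)) {
    cols <- offs[l] + seq_len(nv[l]) # global columns of surface l
    N <- -lumped_omega(pts, meshes[[l]]) / (4 * pi) # ntot x nv[l]
    # self-surface principal value: row over own surface must sum to 1/2
    sub <- N[cols, , drop = FALSE]
    diag(sub) <- 0
    diag(sub) <- 0.5 - rowSums(sub)
    N[cols, ] <- sub
    for (k in seq_along(meshes)) {
      rk <- offs[k] + seq_len(nv[k])
      a_kl <- 2 * (s_in[l] - s_out[l]) / (s_in[k] + s_out[k])
      M[rk, cols] <- M[rk, cols] + a_kl * N[rk, , drop = FALSE]
    }
  }
  b <- rep(2 * sigma_source / (s_in + s_out), times = nv)
  A <- diag(ntot) - M + 1 / ntot # rank-one deflation of the constant mode
  x <- solve(A, phi_inf * b)
  rc <- rcond(A)
  if (rc < 1e-12)
    stop(sprintf("BEM system singular beyond deflation (rcond = %.2e)", rc))
  thorax_rows <- offs[1] + seq_len(nv[1])
  x <- sweep(x, 2, colMeans(x[thorax_rows, , drop = FALSE]))
  idx <- data.frame(surface = rep(names(meshes), nv),
                    vertex = unlist(lapply(nv, seq_len)), row.names = NULL)
  list(potentials = x, interface_index = idx, condition = rc)
}

#' Build the EDL transfer matrix
#'
#' Linear map `A` from nodal double-layer source strength on the ventricular
#' surface (one unit = the waveform amplitude at full depolarization) to
#' potentials at the body-surface electrodes, solving the
#' piecewise-homogeneous BEM system.  Electrode potentials are referenced to
#' zero mean over the thorax surface.
#'
#' @param vc a [volume_conductor()] whose source surface has equal inside
#'   and outside conductivities (it then acts purely as the double layer).
#' @return object of class `transfer_matrix`: list with `A`
#'   (electrodes x source nodes, mV per unit strength), `electrode_vertex_ids`,
#'   `source`, `provenance`.
#' @export
build_transfer_matrix <- function(vc) {
  si <- match(vc$source, names(vc$surfaces))
  if (vc$conductivity_inside[si] != vc$conductivity_outside[si])
    stop("source surface with unequal conductivities is not supported; ",
         "set both to the myocardial value")
  sigma_s <- vc$conductivity_inside[si]
  src <- vc$surfaces[[si]]
  ifc <- which(vc$conductivity_inside != vc$conductivity_outside)
  meshes <- vc$surfaces[ifc]
  pts <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  # primary (infinite-medium) potential of a unit nodal double layer
  G <- -lumped_omega(pts, src) / (4 * pi)
  sol <- bem_solve(vc, G, sigma_source = sigma_s)
  nthx <- nrow(vc$surfaces[[1]]$vertices)
  A <- sol$potentials[vc$electrode_vertex_ids, , drop = FALSE]
  structure(list(A = A,
                 electrode_vertex_ids = vc$electrode_vertex_ids,
                 source = vc$source,
                 condition = sol$condition,
                 provenance = conductor_hash(vc)),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix: %d electrodes x %d source nodes (hash %s)\n",
              nrow(x$A), ncol(x$A), x$provenance))
  invisible(x)
}

# cheap deterministic provenance hash of geometry + conductivities
conductor_hash <- function(vc) {
  acc <- 0
  for (i in seq_along(vc$surfaces)) {
    v <- vc$surfaces[[i]]$vertices
    acc <- acc + sum(v * rep_len(c(0.7548776662, 0.5698402910, 0.3287493546),
                                 length(v))) +
      i * sum(vc$surfaces[[i]]$triangles)
  }
  acc <- acc + sum(vc$conductivity_inside * 1e3) +
    sum(vc$conductivity_outside * 7e2) + sum(vc$electrode_vertex_ids)
  sprintf("%08x", as.integer(round(abs(acc) * 1e3) %% 2^31))
}

#' Transmembrane potential upstroke waveform
#'
#' Logistic depolarization upstroke `s(u) = amplitude / (1 + exp(-u / tau))`.
#' Only the upstroke matters within the QRS window, so repolarization is
#' omitted.
#'
#' @param amplitude action-potential amplitude (mV), default 100.
#' @param tau upstroke time constant (ms), default 1.
#' @return object of class `tmp_waveform` with fields and evaluators
#'   `s(u)` and `ds(u)` (derivative).
#' @export
tmp_waveform <- function(amplitude = 100, tau = 1) {
  stopifnot(amplitude > 0, tau > 0)
  structure(list(amplitude = amplitude, tau = tau,
                 s = function(u) amplitude / (1 + exp(-u / tau)),
                 ds = function(u) {
                   e <- exp(-u / tau)
                   amplitude * e / (tau * (1 + e)^2)
                 }),
            class = "tmp_waveform")
}

#' Compute body-surface potentials from an activation sequence
#'
#' `phi(t) = A s(t - delta)`, sampled at `rate` over `window`, then average
#' referenced per sample over the electrodes.
#'
#' @param tm a [transfer_matrix()].
#' @param seq an [activation_sequence()] (or plain numeric vector of LAT, ms).
#' @param wf a [tmp_waveform()].
#' @param window numeric `c(start, end)` in ms.
#' @param rate sampling rate (Hz), default 1000.
#' @param check require the window to cover `max(delta) + 5 * tau` (set
#'   `FALSE` when scoring candidates on a fixed recorded window).
#' @return a [bspm()].
#' @export
compute_bspm <- function(tm, seq, wf = tmp_waveform(), window, rate = 1000,
                         check = TRUE) {
  lat <- if (inherits(seq, "activation_sequence")) seq$lat else as.numeric(seq)
  if (length(lat) != ncol(tm$A))
    stop("activation sequence length does not match the transfer matrix")
  if (length(window) != 2 || window[2] <= window[1]) stop("bad window")
  if (check && window[2] < max(lat) + 5 * wf$tau)
    stop(sprintf("window too short: ends at %.1f ms, need %.1f ms",
                 window[2], max(lat) + 5 * wf$tau))
  ts <- seq(window[1], window[2], by = 1000 / rate)
  # S[node, sample] = s(t - delta_n) / amplitude (unit strength)
  S <- wf$s(outer(-lat, ts, "+")) / wf$amplitude
  phi <- tm$A %*% S * wf$amplitude
  phi <- sweep(phi, 2, colMeans(phi))
  bspm(phi, rate, qrs_window = c(1L, ncol(phi)),
       lead_ids = paste0("E", seq_len(nrow(phi))), t0 = window[1])
}
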