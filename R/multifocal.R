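# Multi-focal initial estimation (baseline): single-focus search over the
# whole myocardium with QRS-matched uniform velocity, then greedy addition
# of up to six foci.

#' Fundamental single-focus search
#'
#' For each candidate vertex the uniform conduction velocity is tuned so
#' that the total activation duration matches the measured QRS duration
#' (travel times scale as 1/v, so one unit-speed fastest-route run per
#' candidate suffices), capped at 2.5 mm/ms.  The candidate maximizing the
#' Pearson correlation between computed and recorded BSPM wins.
#'
#' @param mesh,fibers ventricular geometry and fiber field.
#' @param tm a [build_transfer_matrix()] result.
#' @param wf a [tmp_waveform()].
#' @param recorded QRS-windowed [bspm()].
#' @param qrs_ms measured QRS duration (ms).
#' @param candidates candidate vertex ids; default every vertex on meshes
#'   with at most 2000 nodes, else a farthest-point subsample of 500.
#' @param anisotropy_ratio longitudinal:transverse ratio, default 2.
#' @param velocity_cap maximal tuned velocity (mm/ms), default 2.5.
#' @param sample_stride score on every k-th recorded sample.
#' @return object of class `multifocal_state`: `foci` (list of
#'   `list(vertices =, t0 =)`), `velocity` (mm/ms), `lat`, `correlation`,
#'   plus the unit-speed distance field of the fundamental focus.
#' @export
fundamental_search <- function(mesh, fibers, tm, wf, recorded, qrs_ms,
                               candidates = NULL, anisotropy_ratio = 2,
                               velocity_cap = 2.5, sample_stride = 1L) {
  stopifnot(inherits(recorded, "bspm"), qrs_ms > 0)
  n <- nrow(mesh$vertices)
  if (is.null(candidates)) {
    candidates <- if (n <= 2000) seq_len(n) else
      farthest_points(mesh$vertices, 500)
  }
  rt <- recorded_times(recorded, sample_stride)
  field1 <- structure(list(speed = rep(1, n),
                           anisotropy_ratio = anisotropy_ratio),
                      class = "velocity_field")
  et <- edge_travel_times(mesh, field1, fibers)
  best <- NULL
  for (v in candidates) {
    d <- .dijkstra_cpp(n, et$edges[, 1] - 1L, et$edges[, 2] - 1L, et$w,
                       v - 1L, 0)
    vel <- min(velocity_cap, (max(d) - min(d)) / qrs_ms)
    lat <- d / vel
    cc <- score_candidate(tm, lat, wf, recorded, rt)
    if (is.null(best) || cc > best$correlation)
      best <- list(vertex = v, velocity = vel, lat = lat, correlation = cc,
                   dist = d)
  }
  structure(list(foci = list(list(vertices = best$vertex, t0 = 0)),
                 velocity = best$velocity, lat = best$lat,
                 correlation = best$correlation,
                 fundamental_dist = best$dist,
                 anisotropy_ratio = anisotropy_ratio),
            class = "multifocal_state")
}

#' @export
print.multifocal_state <- function(x, ...) {
  cat(sprintf("multifocal_state: %d focus/foci, v = %.2f mm/ms, cc = %.4f\n",
              length(x$foci), x$velocity, x$correlation))
  invisible(x)
}

#' Greedy additive multi-foci search
#'
#' Starting from the fundamental state, iteratively adds the focus (over a
#' candidate vertex grid and initial timings 0..QRS in steps of `t0_step`)
#' that most increases the correlation between computed and recorded BSPM.
#' The fundamental's tuned velocity is retained for added foci; merging is
#' the pointwise minimum of arrival times (exact for a uniform velocity
#' field).  Stops when no candidate improves the correlation by more than
#' `improve_eps` or when `max_added` foci have been added.
#'
#' @param state a [fundamental_search()] result.
#' @param mesh,fibers,tm,wf,recorded,qrs_ms as in [fundamental_search()].
#' @param max_added maximal number of added foci, default 6.
#' @param t0_step timing grid step (ms), default 5.
#' @param improve_eps minimal correlation improvement, default 1e-4.
#' @param candidates candidate vertex ids (default as in
#'   [fundamental_search()], capped at 200 by farthest-point subsampling).
#' @param sample_stride score on every k-th recorded sample.
#' @return updated `multifocal_state` (at most 7 foci in total).
#' @export
additive_search <- function(state, mesh, fibers, tm, wf, recorded, qrs_ms,
                            max_added = 6, t0_step = 5, improve_eps = 1e-4,
                            candidates = NULL, sample_stride = 1L) {
  stopifnot(inherits(state, "multifocal_state"))
  n <- nrow(mesh$vertices)
  if (is.null(candidates))
    candidates <- farthest_points(mesh$vertices, min(200, n))
  rt <- recorded_times(recorded, sample_stride)
  field1 <- structure(list(speed = rep(1, n),
                           anisotropy_ratio = state$anisotropy_ratio),
                      class = "velocity_field")
  et <- edge_travel_times(mesh, field1, fibers)
  # unit-speed distance field per candidate, converted once to travel time
  D <- matrix(0, length(candidates), n)
  for (i in seq_along(candidates))
    D[i, ] <- .dijkstra_cpp(n, et$edges[, 1] - 1L, et$edges[, 2] - 1L, et$w,
                            candidates[i] - 1L, 0) / state$velocity
  t0s <- seq(0, qrs_ms, by = t0_step)
  for (it in seq_len(max_added)) {
    best <- list(correlation = state$correlation)
    for (i in seq_along(candidates)) {
      for (t0 in t0s) {
        lat <- pmin(state$lat, D[i, ] + t0)
        cc <- score_candidate(tm, lat, wf, recorded, rt)
        if (cc > best$correlation)
          best <- list(correlation = cc, lat = lat, vertex = candidates[i],
                       t0 = t0)
      }
    }
    if (is.null(best$lat) || best$correlation - state$correlation <= improve_eps)
      break
    state$lat <- best$lat
    state$correlation <- best$correlation
    state$foci <- c(state$foci, list(list(vertices = best$vertex,
                                          t0 = best$t0)))
  }
  state
}

#' Multi-focal initial estimation (one call)
#'
#' [fundamental_search()] followed by [additive_search()].
#' @inheritParams additive_search
#' @inheritParams fundamental_search
#' @param fundamental_candidates,additive_candidates candidate vertex sets
#'   for the two stages (defaults as in the stage functions).
#' @return a `multifocal_state`.
#' @export
estimate_multifocal <- function(mesh, fibers, tm, wf, recorded,
                                qrs_ms = qrs_duration(recorded),
                                max_added = 6, t0_step = 5,
                                improve_eps = 1e-4,
                                fundamental_candidates = NULL,
                                additive_candidates = NULL,
                                anisotropy_ratio = 2,
                                sample_stride = 1L) {
  st <- fundamental_search(mesh, fibers, tm, wf, recorded, qrs_ms,
                           candidates = fundamental_candidates,
                           anisotropy_ratio = anisotropy_ratio,
                           sample_stride = sample_stride)
  additive_search(st, mesh, fibers, tm, wf, recorded, qrs_ms,
                  max_added = max_added, t0_step = t0_step,
                  improve_eps = improve_eps,
                  candidates = additive_candidates,
                  sample_stride = sample_stride)
}
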