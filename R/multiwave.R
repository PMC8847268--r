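# Multi-wave initial estimation: nine His-Purkinje foci groups, per-group
# timing sweeps, exhaustive subset search over all 511 non-empty
# combinations, QRS-duration gating and correlation ranking.

FOCI_GROUP_IDS <- c("lv_ant_papillary", "lv_post_papillary",
                    "rv_moderator_band", "lv_sept_1", "lv_sept_2",
                    "lv_sept_3", "lv_sept_4", "rv_sept_apex", "rv_sept_mid")

group_surface_label <- function(id) {
  switch(substr(id, 1, 7),
         lv_sept = "septum_lv",
         rv_sept = "septum_rv",
         lv_ant_ = "lv_endo", lv_post = "lv_endo", rv_mode = "rv_endo")
}

#' Locate the nine His-Purkinje candidate-origin regions
#'
#' Structure groups (the two LV papillary-muscle insertions and the RV
#' moderator-band insertion) take their landmark vertex sets directly: all
#' nodes connecting the structure to the wall act as one focus with a shared
#' initial timing.  Septal groups are 10 mm-radius vertex sets around the
#' landmark centres on the labelled septal surfaces: four on the LV septum
#' (inferior third, superior antero-septal third, two between) and two on
#' the RV septum (near the apex and mid-wall).
#'
#' @param mesh labelled ventricular [trimesh()].
#' @param landmarks named list as produced by [make_phantom()] (entries
#'   `kind`, `center`, `vertices`).
#' @param septal_radius region radius for septal groups (mm), default 10.
#' @param t0_range_structure,t0_range_septal timing sweep ranges (ms).
#' @return named list of nine `foci_group` objects with fields `id`,
#'   `kind`, `candidates` (vertex ids; for structures a single set),
#'   `t0_range`.
#' @export
locate_foci_groups <- function(mesh, landmarks, septal_radius = 10,
                               t0_range_structure = c(0, 35),
                               t0_range_septal = c(0, 25)) {
  missing <- setdiff(FOCI_GROUP_IDS, names(landmarks))
  if (length(missing))
    stop("missing landmark(s) for foci group(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(FOCI_GROUP_IDS, function(id) {
    lm <- landmarks[[id]]
    lab <- group_surface_label(id)
    if (identical(lm$kind, "structure")) {
      cand <- as.integer(lm$vertices)
      rng <- t0_range_structure
    } else {
      ctr <- mesh$vertices[lm$center, ]
      d2 <- rowSums((mesh$vertices -
                       matrix(ctr, nrow(mesh$vertices), 3, byrow = TRUE))^2)
      cand <- which(d2 <= septal_radius^2 & mesh$labels == lab)
      rng <- t0_range_septal
    }
    if (!length(cand)) stop("empty candidate set for foci group ", id)
    structure(list(id = id, kind = lm$kind, candidates = cand,
                   t0_range = rng, label = lab),
              class = "foci_group")
  })
  names(out) <- FOCI_GROUP_IDS
  out
}

# Pearson correlation between two equally shaped potential matrices over
# concatenated entries (both already average-referenced)
bspm_correlation <- function(V, P) {
  v <- as.vector(V); p <- as.vector(P)
  if (sd(v) == 0 || sd(p) == 0) return(-Inf)
  stats::cor(v, p)
}

# sample times (ms) of a recorded windowed bspm
recorded_times <- function(rec, stride = 1L) {
  idx <- seq(1L, ncol(rec$potentials), by = stride)
  list(t = rec$t0 + (idx - 1) / rec$sampling_rate * 1000, idx = idx)
}

# simulate candidate potentials on the recorded sample grid and correlate
score_candidate <- function(tm, lat, wf, rec, rt) {
  S <- wf$s(outer(-lat, rt$t, "+")) / wf$amplitude
  phi <- tm$A %*% S * wf$amplitude
  phi <- sweep(phi, 2, colMeans(phi))
  bspm_correlation(rec$potentials[, rt$idx, drop = FALSE], phi)
}

#' Propagation settings shared by the estimators
#'
#' Collects the conduction parameters with the standard defaults: base
#' speed 0.85 mm/ms, 1.7 mm/ms within 15 mm of a focus, anisotropy ratio 2.
#' @param base_speed,boost_speed,boost_radius,anisotropy_ratio see
#'   [build_velocity_field()].
#' @return list of settings.
#' @export
propagation_settings <- function(base_speed = 0.85, boost_speed = 1.7,
                                 boost_radius = 15, anisotropy_ratio = 2) {
  list(base_speed = base_speed, boost_speed = boost_speed,
       boost_radius = boost_radius, anisotropy_ratio = anisotropy_ratio)
}

# FRA for a foci list under the settings, boosting around the union of foci
fra_with_boost <- function(mesh, fibers, foci, ps,
                           boost_dist = NULL) {
  src <- unique(unlist(lapply(foci, `[[`, "vertices")))
  speed <- rep(ps$base_speed, nrow(mesh$vertices))
  if (ps$boost_radius > 0) {
    d <- if (is.null(boost_dist)) surface_distances(mesh, src) else boost_dist
    speed[d < ps$boost_radius] <- ps$boost_speed
  }
  field <- structure(list(speed = speed,
                          anisotropy_ratio = ps$anisotropy_ratio),
                     class = "velocity_field")
  fastest_route(mesh, field, fibers, foci)
}

#' Select the best single-focus sequence per foci group
#'
#' For every group, sweeps the candidate foci against the initial-timing
#' grid (structures 0-35 ms, septal regions 0-25 ms, step `timing_step`),
#' simulates the single-focus activation sequence (with the velocity boost
#' around the candidate focus), computes the BSPM through the transfer
#' matrix on the recorded sample grid, and keeps the candidate with the
#' highest Pearson correlation against the recorded BSPM.
#'
#' @param groups result of [locate_foci_groups()].
#' @param mesh,fibers ventricular geometry and fiber field.
#' @param tm a [build_transfer_matrix()] result.
#' @param wf a [tmp_waveform()].
#' @param recorded QRS-windowed [bspm()].
#' @param timing_step sweep step (ms), default 5.
#' @param settings a [propagation_settings()] list.
#' @param max_candidates cap on septal candidate vertices per group
#'   (subsampled deterministically), default 25.
#' @param sample_stride score on every k-th recorded sample, default 1.
#' @return named list of nine chosen candidates: `vertices`, `t0`, `lat`,
#'   `correlation`, `boost_dist` (unit-speed surface distance field from the
#'   chosen focus, reused by the subset search).
#' @export
best_single_focus_per_group <- function(groups, mesh, fibers, tm, wf,
                                        recorded, timing_step = 5,
                                        settings = propagation_settings(),
                                        max_candidates = 25,
                                        sample_stride = 1L) {
  stopifnot(inherits(recorded, "bspm"))
  rt <- recorded_times(recorded, sample_stride)
  lapply(groups, function(g) {
    t0s <- seq(g$t0_range[1], g$t0_range[2], by = timing_step)
    if (!length(t0s)) stop("empty timing grid for group ", g$id)
    fsets <- if (g$kind == "structure") {
      list(g$candidates)
    } else {
      cand <- g$candidates
      if (length(cand) > max_candidates)
        cand <- cand[round(seq(1, length(cand), length.out = max_candidates))]
      as.list(cand)
    }
    best <- NULL
    for (fs in fsets) {
      bd <- surface_distances(mesh, fs)
      # t0 only shifts the sequence: run the FRA once at t0 = 0
      seq0 <- fra_with_boost(mesh, fibers, list(list(vertices = fs, t0 = 0)),
                             settings, boost_dist = bd)
      for (t0 in t0s) {
        cc <- score_candidate(tm, seq0$lat + t0, wf, recorded, rt)
        if (is.null(best) || cc > best$correlation)
          best <- list(vertices = fs, t0 = t0, lat = seq0$lat + t0,
                       correlation = cc, boost_dist = bd)
      }
    }
    best
  })
}

subset_id <- function(active) paste(FOCI_GROUP_IDS[active], collapse = "+")

#' Exhaustive subset (permutation) search over the nine chosen foci
#'
#' Enumerates all `2^9 - 1 = 511` non-empty subsets of the nine per-group
#' chosen single-focus candidates.  Each subset's merged activation
#' sequence is recomputed by a joint fastest-route run whose velocity boost
#' covers the union of the active foci.  Subsets whose total activation
#' duration falls outside 85..115% of the measured QRS duration are
#' discarded; among the survivors the subset with the highest correlation
#' between computed and recorded BSPM wins (ties: fewer active foci, then
#' lexicographic group order).  If every subset is gated out, the
#' best-correlation candidate is returned ungated with a warning.
#'
#' @param chosen result of [best_single_focus_per_group()].
#' @param mesh,fibers,tm,wf,recorded as in [best_single_focus_per_group()].
#' @param qrs_ms measured QRS duration (ms).
#' @param settings a [propagation_settings()] list.
#' @param sample_stride score on every k-th recorded sample.
#' @return object of class `candidate_estimate`: `subset` (group ids),
#'   `foci`, `sequence` ([activation_sequence()]), `correlation`,
#'   `duration`, `gated` (did the winner pass the gate), and `candidates`
#'   (data frame of all 511 subsets with correlation, duration, gate).
#' @export
permutation_search <- function(chosen, mesh, fibers, tm, wf, recorded,
                               qrs_ms, settings = propagation_settings(),
                               sample_stride = 1L) {
  stopifnot(length(chosen) == 9, qrs_ms > 0)
  rt <- recorded_times(recorded, sample_stride)
  n_subsets <- as.integer(2^9 - 1)
  bd <- do.call(cbind, lapply(chosen, `[[`, "boost_dist")) # n x 9
  res <- vector("list", n_subsets)
  seqs <- vector("list", n_subsets)
  for (mask in seq_len(n_subsets)) {
    active <- which(bitwAnd(mask, bitwShiftL(1L, 0:8)) != 0L)
    foci <- lapply(chosen[active], function(ch)
      list(vertices = ch$vertices, t0 = ch$t0))
    dmin <- if (length(active) == 1L) bd[, active] else
      do.call(pmin, as.data.frame(bd[, active, drop = FALSE]))
    sq <- fra_with_boost(mesh, fibers, foci, settings, boost_dist = dmin)
    dur <- total_duration(sq)
    cc <- score_candidate(tm, sq$lat, wf, recorded, rt)
    res[[mask]] <- data.frame(mask = mask, n_foci = length(active),
                              subset = subset_id(active),
                              correlation = cc, duration = dur,
                              pass = duration_gate(sq, qrs_ms))
    seqs[[mask]] <- sq
  }
  cand <- do.call(rbind, res)
  pick_best <- function(df) {
    df <- df[order(-df$correlation, df$n_foci, df$mask), , drop = FALSE]
    df$mask[1]
  }
  surv <- cand[cand$pass, , drop = FALSE]
  gated <- nrow(surv) > 0
  if (!gated) {
    warning("all 511 subsets failed the QRS-duration gate; ",
            "returning the ungated best-correlation candidate")
    surv <- cand
  }
  w <- pick_best(surv)
  active <- which(bitwAnd(w, bitwShiftL(1L, 0:8)) != 0L)
  structure(list(subset = FOCI_GROUP_IDS[active],
                 foci = lapply(chosen[active], function(ch)
                   list(vertices = ch$vertices, t0 = ch$t0)),
                 sequence = seqs[[w]],
                 correlation = cand$correlation[w],
                 duration = cand$duration[w],
                 gated = gated,
                 n_enumerated = n_subsets,
                 n_surviving = sum(cand$pass),
                 candidates = cand),
            class = "candidate_estimate")
}

#' @export
print.candidate_estimate <- function(x, ...) {
  cat(sprintf(paste0("candidate_estimate: %d/%d subsets passed the gate\n",
                     "  winner: {%s}  cc = %.4f  duration = %.1f ms%s\n"),
              x$n_surviving, x$n_enumerated,
              paste(x$subset, collapse = ", "),
              x$correlation, x$duration,
              if (x$gated) "" else "  [gate fallback]"))
  invisible(x)
}

#' Multi-wave initial estimation (one call)
#'
#' Convenience wrapper: [locate_foci_groups()] then
#' [best_single_focus_per_group()] then [permutation_search()].
#'
#' @inheritParams best_single_focus_per_group
#' @inheritParams permutation_search
#' @param landmarks nine-entry landmark list (see [make_phantom()]).
#' @param qrs_ms measured QRS duration (ms); default from the recorded
#'   window.
#' @return a `candidate_estimate` (see [permutation_search()]) with the
#'   per-group chosen foci attached as `$chosen`.
#' @export
estimate_multiwave <- function(mesh, fibers, landmarks, tm, wf, recorded,
                               qrs_ms = qrs_duration(recorded),
                               timing_step = 5,
                               settings = propagation_settings(),
                               max_candidates = 25, sample_stride = 1L) {
  groups <- locate_foci_groups(mesh, landmarks)
  chosen <- best_single_focus_per_group(groups, mesh, fibers, tm, wf,
                                        recorded, timing_step, settings,
                                        max_candidates, sample_stride)
  est <- permutation_search(chosen, mesh, fibers, tm, wf, recorded, qrs_ms,
                            settings, sample_stride)
  est$chosen <- chosen
  est
}
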