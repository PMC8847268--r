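# Shared fixtures, built once per test run.  The test phantom is a coarse
# (resolution 7 mm) version of the default phantom so the whole suite stays
# within a small single-CPU budget; geometry invariants do not depend on
# resolution.

.fixtures <- new.env(parent = emptyenv())

test_phantom <- function() {
  if (is.null(.fixtures$ph))
    .fixtures$ph <- make_phantom(phantom_spec(resolution = 7, seed = 42L))
  .fixtures$ph
}

test_transfer_matrix <- function() {
  if (is.null(.fixtures$tm))
    .fixtures$tm <- build_transfer_matrix(test_phantom()$vc)
  .fixtures$tm
}

test_groups <- function() {
  if (is.null(.fixtures$groups)) {
    ph <- test_phantom()
    .fixtures$groups <- locate_foci_groups(ph$meshes$myocardium, ph$landmarks)
  }
  .fixtures$groups
}

# representative focus of a group: the whole insertion set for structures,
# the candidate nearest the region centroid for septal groups
group_focus <- function(g, mesh) {
  if (g$kind == "structure") return(g$candidates)
  cv <- mesh$vertices[g$candidates, , drop = FALSE]
  g$candidates[which.min(rowSums(
    (cv - matrix(colMeans(cv), nrow(cv), 3, byrow = TRUE))^2))]
}

# noiseless recorded BSPM simulated from a subset of foci groups
simulate_recording <- function(truth_ids, t0s = rep(0, length(truth_ids)),
                               ph = test_phantom(),
                               tm = test_transfer_matrix(),
                               wf = tmp_waveform()) {
  mesh <- ph$meshes$myocardium
  groups <- test_groups()
  foci <- Map(function(id, t0)
    list(vertices = group_focus(groups[[id]], mesh), t0 = t0),
    truth_ids, t0s)
  sq <- edlwave:::fra_with_boost(mesh, ph$fibers, unname(foci),
                                 propagation_settings())
  rec <- compute_bspm(tm, sq, wf, window = c(0, max(sq$lat) + 5))
  rec$qrs_window <- c(1L, ncol(rec$potentials))
  list(recorded = rec, sequence = sq, foci = foci)
}

apply_rigid_test <- function(points, tf) {
  sweep(points %*% t(tf$R), 2, tf$t, "+")
}
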