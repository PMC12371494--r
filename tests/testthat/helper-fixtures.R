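# Shared fixtures: small, seeded, built in code at test time.

# A noise-free single-frame trajectory holding the pocket plus one pose
# template; convenient for geometry-level checks.
template_trajectory <- function(pose = "A", n_frames = 1L,
                                replicate_id = "rep1") {
  topo <- make_pocket_topology()
  lig <- pose_template(pose)
  atoms <- rbind(
    topo[, c("name", "resid", "elety", "role", "donor", "acceptor")],
    cbind(lig[, c("name", "elety", "role", "donor", "acceptor")],
          resid = "LIG")[, c("name", "resid", "elety", "role", "donor",
                             "acceptor")]
  )
  frame <- c(as.vector(t(as.matrix(topo[, c("x", "y", "z")]))),
             as.vector(t(as.matrix(lig[, c("x", "y", "z")]))))
  xyz <- matrix(rep(frame, n_frames), nrow = n_frames, byrow = TRUE)
  trajectory(atoms, xyz, times = seq_len(n_frames),
             replicate_id = replicate_id)
}

# Standard small ensemble for pipeline-level tests (two replicates keep
# the suite fast; acceptance tests use the full eight).
small_ensemble <- function(pose_weight_A = 0.55, seed = 1, n_frames = 100L,
                           n_replicates = 4L, unbound_fraction = 0.1,
                           noise = 0.3) {
  generate_trajectory(trajectory_gen_spec(
    n_replicates = n_replicates, n_frames_per_replicate = n_frames,
    pose_weight_A = pose_weight_A, positional_noise_sd = noise,
    unbound_fraction = unbound_fraction, seed = seed))
}

# Apply one rigid transformation (rotation + translation) to every frame
# of a trajectory.
rigid_transform_trajectory <- function(traj, angle = 0.7,
                                       axis = c(1, 1, 0),
                                       shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  R <- diag(3) + s_ * K + (1 - c_) * (K %*% K)
  n_at <- nrow(traj$atoms)
  xyz <- traj$xyz
  for (f in seq_len(nrow(xyz))) {
    co <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    co <- co %*% t(R)
    co <- sweep(co, 2L, shift, "+")
    xyz[f, ] <- as.vector(t(co))
  }
  trajectory(traj$atoms, xyz, traj$times, traj$replicate_id,
             traj$ground_truth)
}
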