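#' Reference frame for RMSD calculation
#'
#' @param traj a `trajectory`.
#' @param frame frame index (default 1, the starting structure).
#' @return An object of class `reference_frame` holding the atom table
#'   and coordinates of that frame.
#' @export
reference_frame <- function(traj, frame = 1L) {
  structure(list(atoms = traj$atoms, xyz = traj$xyz[frame, ]),
            class = "reference_frame")
}

# xyz indices (into the flat 3N vector) of the superposition anchors:
# protein C-alpha atoms when present, otherwise every protein-role atom
# (the stylised pocket has no full backbone).
anchor_xyz_inds <- function(atoms) {
  ca <- which(atoms$role == "protein" & atoms$elety == "CA")
  i <- if (length(ca) >= 3L) ca else which(atoms$role == "protein")
  if (length(i) < 3L) stop("need at least 3 protein anchor atoms for superposition")
  as.vector(vapply(i, function(j) (3L * (j - 1L)) + 1:3, integer(3)))
}

ligand_heavy_inds <- function(atoms) {
  i <- which(atoms$role == "ligand" & atoms$elety != "H")
  if (length(i) == 0L) stop("no ligand heavy atoms in topology")
  i
}

#' Ligand RMSD time series after protein superposition
#'
#' Every frame is rigidly superposed onto the reference using the protein
#' C-alpha atoms (or, for the stylised pocket, all protein anchor atoms);
#' the RMSD is then computed over the ligand heavy atoms with no
#' re-fitting on the ligand.  For an ensemble, the median and one median
#' absolute deviation (unscaled) across replicates are reported at each
#' time point — the statistics plotted as a band around the median RMSD.
#'
#' @param trajectories a `trajectory` or `trajectory_set`; replicates
#'   must share the time grid.
#' @param reference a [reference_frame()] with the same atom table.
#' @return An object of class `rmsd_series`: list with `times` (ns),
#'   `per_replicate_rmsd` (replicates x time points, Angstrom), `median`,
#'   and `mad` per time point.
#' @export
ligand_rmsd <- function(trajectories, reference) {
  if (inherits(trajectories, "trajectory")) {
    trajectories <- structure(list(trajectories), class = "trajectory_set")
  }
  times <- trajectories[[1L]]$times
  for (tr in trajectories) {
    if (!identical(tr$atoms$name, reference$atoms$name)) {
      stop("trajectory and reference disagree on atoms (count or names)")
    }
    if (!isTRUE(all.equal(tr$times, times))) {
      stop("replicates must share the same time grid")
    }
  }
  anchor <- anchor_xyz_inds(reference$atoms)
  lig <- ligand_heavy_inds(reference$atoms)
  lig_xyz <- as.vector(vapply(lig, function(j) (3L * (j - 1L)) + 1:3, integer(3)))
  per_rep <- t(vapply(trajectories, function(tr) {
    moved <- bio3d::fit.xyz(fixed = reference$xyz, mobile = tr$xyz,
                            fixed.inds = anchor, mobile.inds = anchor)
    if (is.null(dim(moved))) moved <- matrix(moved, nrow = 1L)
    diff2 <- (moved[, lig_xyz, drop = FALSE] -
                matrix(reference$xyz[lig_xyz], nrow(moved), length(lig_xyz),
                       byrow = TRUE))^2
    # mean over atoms: sum the squared x,y,z residuals per atom
    sqrt(rowSums(diff2) / length(lig))
  }, numeric(length(times))))
  if (length(times) == 1L) per_rep <- matrix(per_rep, ncol = 1L)
  structure(
    list(times = times,
         per_replicate_rmsd = per_rep,
         median = apply(per_rep, 2L, stats::median),
         mad = apply(per_rep, 2L, stats::mad, constant = 1)),
    class = "rmsd_series"
  )
}

#' Compare the stability of two pose ensembles by ligand RMSD
#'
#' Reports the time-averaged median RMSD of each series and declares the
#' pose with the lower value "more stable".  This is a descriptive
#' comparison; no significance claim is attached.
#'
#' @param series_a,series_b `rmsd_series` objects on the same time grid.
#' @param labels names of the two poses (default `c("A", "B")`).
#' @return A list with `mean_median_rmsd` (named, Angstrom),
#'   `difference` (a minus b), and `more_stable` (`"A"`, `"B"`, or
#'   `"tie"`).
#' @export
compare_pose_stability <- function(series_a, series_b, labels = c("A", "B")) {
  if (!isTRUE(all.equal(series_a$times, series_b$times))) {
    stop("RMSD series are on different time grids")
  }
  m <- c(mean(series_a$median), mean(series_b$median))
  names(m) <- labels
  diff <- m[1L] - m[2L]
  more_stable <- if (abs(diff) < sqrt(.Machine$double.eps)) {
    "tie"
  } else if (diff < 0) labels[1L] else labels[2L]
  list(mean_median_rmsd = m, difference = unname(diff),
       more_stable = more_stable)
}

#' Write an RMSD series as CSV
#'
#' @param series an `rmsd_series`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_rmsd_series <- function(series, file) {
  df <- data.frame(time_ns = series$times,
                   median_rmsd = series$median,
                   mad_rmsd = series$mad)
  reps <- as.data.frame(t(series$per_replicate_rmsd))
  names(reps) <- paste0("rep", seq_len(ncol(reps)))
  utils::write.csv(cbind(df, reps), file, row.names = FALSE)
  invisible(file)
}
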