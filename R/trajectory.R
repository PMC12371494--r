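#' Trajectory container
#'
#' A `trajectory` holds an ordered set of frames over a fixed atom table.
#' Coordinates follow the bio3d convention: a numeric matrix with one row
#' per frame and three columns (x, y, z) per atom, in atom-table order.
#'
#' @param atoms `data.frame` with columns `name` (unique), `resid`,
#'   `elety`, `role` (`"protein"`, `"ligand"`, or `"water"`), `donor`,
#'   `acceptor`.
#' @param xyz numeric matrix, frames x (3 * n_atoms), in Angstrom.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param replicate_id identifier of the replicate run.
#' @param ground_truth optional `data.frame` (one row per frame) carrying
#'   generator labels such as `pose` and `bound`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, times, replicate_id = "rep1",
                       ground_truth = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("xyz must have 3 columns per atom (", nrow(atoms), " atoms, got ",
         ncol(xyz), " columns)")
  }
  if (length(times) != nrow(xyz)) {
    stop("length(times) must equal the number of frames")
  }
  if (nrow(xyz) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing within a replicate")
  }
  if (anyDuplicated(atoms$name)) {
    stop("atom names must be unique")
  }
  if (!is.null(ground_truth) && nrow(ground_truth) != nrow(xyz)) {
    stop("ground_truth must have one row per frame")
  }
  structure(
    list(atoms = atoms, xyz = xyz, times = as.numeric(times),
         replicate_id = replicate_id, ground_truth = ground_truth),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", n_frames(x), " frames, ", nrow(x$atoms), " atoms, ",
      "replicate ", x$replicate_id, "\n", sep = "")
  cat("  time span: ", min(x$times), " - ", max(x$times), " ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

# Column indices of atom i (or named atom) within the xyz matrix.
xyz_cols <- function(traj, atom) {
  if (is.character(atom)) {
    i <- match(atom, traj$atoms$name)
    if (anyNA(i)) {
      stop("atom(s) not present in topology: ",
           paste(atom[is.na(i)], collapse = ", "))
    }
  } else {
    i <- atom
  }
  as.vector(vapply(i, function(j) (3L * (j - 1L)) + 1:3, integer(3)))
}

# Coordinates of one frame as an n_atoms x 3 matrix.
frame_coords <- function(traj, frame) {
  matrix(traj$xyz[frame, ], ncol = 3L, byrow = TRUE,
         dimnames = list(traj$atoms$name, c("x", "y", "z")))
}

# Subset frames, keeping atoms and ground truth aligned.
subset_frames <- function(traj, keep) {
  gt <- if (is.null(traj$ground_truth)) NULL else traj$ground_truth[keep, , drop = FALSE]
  trajectory(traj$atoms, traj$xyz[keep, , drop = FALSE], traj$times[keep],
             replicate_id = traj$replicate_id, ground_truth = gt)
}

# Per-frame distance between two named atoms.
atom_distance <- function(traj, atom_a, atom_b) {
  ca <- traj$xyz[, xyz_cols(traj, atom_a), drop = FALSE]
  cb <- traj$xyz[, xyz_cols(traj, atom_b), drop = FALSE]
  sqrt(rowSums((ca - cb)^2))
}

#' Subsample a trajectory on a time window and interval
#'
#' Retains frames whose time lies in `[t_start, t_end]` (both ends
#' included) on a regular grid of the stated interval anchored at
#' `t_start`.  The defaults reproduce the analysis convention of
#' discarding the first half of each run — allowing the ligand to relax in
#' the pocket — and then keeping one frame per nanosecond: for a 200 ns
#' run sampled every 1 ns the window `[100, 200]` retains 101 frames.
#'
#' @param traj a `trajectory`.
#' @param t_start window start in ns; default: half of the trajectory span.
#' @param t_end window end in ns; default: last frame time.
#' @param interval grid spacing in ns (default 1).
#' @return The subsampled `trajectory`.
#' @export
subsample <- function(traj, t_start = NULL, t_end = NULL, interval = 1) {
  if (is.null(t_start)) t_start <- min(traj$times) + diff(range(traj$times)) / 2
  if (is.null(t_end)) t_end <- max(traj$times)
  if (t_start >= t_end) stop("t_start must be smaller than t_end")
  if (t_end > max(traj$times) + 1e-9) {
    stop("t_end exceeds the trajectory span (", max(traj$times), " ns)")
  }
  # snap the default (half-span) start up to an actual frame time so the
  # interval grid is anchored on the sampling grid
  if (!any(abs(traj$times - t_start) < 1e-6) && any(traj$times >= t_start)) {
    t_start <- min(traj$times[traj$times >= t_start])
  }
  if (t_start > t_end) {
    stop("subsampling selected no frames in the requested window")
  }
  grid <- seq(t_start, t_end, by = interval)
  keep <- which(vapply(traj$times, function(t) {
    any(abs(grid - t) < 1e-6)
  }, logical(1)))
  if (length(keep) == 0L) {
    stop("subsampling selected no frames in [", t_start, ", ", t_end, "] ns")
  }
  subset_frames(traj, keep)
}

#' Select bound frames by the sulfur-to-C433 distance criterion
#'
#' A frame counts as bound when the distance between the ligand's
#' exocyclic sulfur and the C433 backbone nitrogen is strictly below the
#' threshold (default 5 Angstrom).  A frame at exactly the threshold is
#' excluded.
#'
#' @param traj a `trajectory` whose topology contains atoms `s_atom` and
#'   `n_atom`.
#' @param threshold bound-frame cutoff in Angstrom (default 5.0).
#' @param s_atom,n_atom atom labels of the exocyclic sulfur and the C433
#'   backbone nitrogen.
#' @return A list with elements `trajectory` (bound frames only) and
#'   `bound_mask` (logical, aligned to the input frames).
#' @export
select_bound <- function(traj, threshold = 5.0,
                         s_atom = "S_EXO", n_atom = "C433_N") {
  for (a in c(s_atom, n_atom)) {
    if (!a %in% traj$atoms$name) {
      stop("bound-frame criterion needs anchor atom '", a,
           "', absent from the topology")
    }
  }
  d <- atom_distance(traj, s_atom, n_atom)
  mask <- d < threshold
  list(trajectory = subset_frames(traj, mask), bound_mask = mask)
}

# PDB field mapping for the stylised topology.  The PDB atom-name field is
# four characters wide, so unique package labels ("C433_N", "S_EXO", ...)
# are encoded as residue (name + number) plus a short atom name, and
# decoded on read.
ligand_pdb_names <- c(C_THIO = "C1", S_EXO = "S1", N1 = "N1", N2 = "N2",
                      C5 = "C5", C6 = "C6", O_CARB = "O1", S_THIO = "S2")
res3 <- c(C = "CYS", D = "ASP", Y = "TYR", W = "TRP")

pdb_fields <- function(atoms) {
  out <- data.frame(pdb_name = atoms$elety, resnm = "LIG",
                    resno = 900L, rectype = "HETATM",
                    stringsAsFactors = FALSE)
  lig <- atoms$role == "ligand"
  known <- lig & atoms$name %in% names(ligand_pdb_names)
  out$pdb_name[known] <- ligand_pdb_names[atoms$name[known]]
  pw <- !lig
  out$resno[pw] <- suppressWarnings(as.integer(sub("^[A-Z]+", "", atoms$resid[pw])))
  out$resno[pw & is.na(out$resno)] <- 1L
  out$resnm[pw] <- ifelse(atoms$resid[pw] == "HOH", "HOH",
                          res3[substr(atoms$resid[pw], 1L, 1L)])
  out$rectype[atoms$role == "protein"] <- "ATOM  "
  out
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; pocket anchors are written as
#' `ATOM` records of their residues (e.g. the C433 backbone N as atom `N`
#' of `CYS 433`), the structural water as `HOH`, and the ligand scaffold
#' as `HETATM` records of residue `LIG`.  The output is plain PDB and can
#' be read back with [read_trajectory_pdb()] or any standard structure
#' reader.
#'
#' @param traj a `trajectory`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  atoms <- traj$atoms
  fld <- pdb_fields(atoms)
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf("%s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     fld$rectype, seq_len(nrow(atoms)), fld$pdb_name,
                     fld$resnm, fld$resno, co[, 1], co[, 2], co[, 3],
                     substr(atoms$elety, 1L, 1L))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Parses the file with `bio3d::read.pdb(multi = TRUE)` and restores the
#' package's unique atom labels: protein anchors become
#' `<one-letter-residue><number>_<atom>` (e.g. `C433_N`), the water oxygen
#' `HOH_O`, and `LIG` atoms are decoded to the scaffold names
#' (`S_EXO`, `N1`, ...).  Donor/acceptor flags and frame times are
#' metadata the PDB format does not carry: times default to a 1 ns grid
#' starting at 1 ns, and hydrogen-bond flags are restored from the
#' standard topology ([make_pocket_topology()], [pose_template()]) where
#' labels match.
#'
#' @param file path to a multi-model PDB.
#' @param times optional frame times (ns); default `1:n_models`.
#' @param replicate_id replicate label.
#' @return A `trajectory`.
#' @export
read_trajectory_pdb <- function(file, times = NULL, replicate_id = "rep1") {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  at <- pdb$atom
  role <- ifelse(at$resid == "HOH", "water",
                 ifelse(at$type == "ATOM", "protein", "ligand"))
  res1 <- c(CYS = "C", ASP = "D", TYR = "Y", TRP = "W")
  name <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    if (role[i] == "water") {
      name[i] <- "HOH_O"
    } else if (role[i] == "protein") {
      name[i] <- paste0(res1[at$resid[i]], at$resno[i], "_", at$elety[i])
    } else {
      hit <- names(ligand_pdb_names)[match(at$elety[i], ligand_pdb_names)]
      name[i] <- if (is.na(hit)) at$elety[i] else hit
    }
  }
  atoms <- data.frame(name = name, stringsAsFactors = FALSE)
  atoms$resid <- ifelse(role == "ligand", "LIG",
                        ifelse(role == "water", "HOH",
                               sub("_.*$", "", name)))
  atoms$elety <- at$elety
  atoms$role <- role
  atoms$donor <- FALSE
  atoms$acceptor <- FALSE
  ref <- rbind(make_pocket_topology()[, c("name", "donor", "acceptor")],
               pose_template("A")[, c("name", "donor", "acceptor")])
  i <- match(atoms$name, ref$name)
  hit <- !is.na(i)
  atoms$donor[hit] <- ref$donor[i[hit]]
  atoms$acceptor[hit] <- ref$acceptor[i[hit]]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (is.null(times)) times <- seq_len(nrow(xyz))
  trajectory(atoms, xyz, times, replicate_id = replicate_id)
}
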