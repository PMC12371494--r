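#' Docking pose with energy annotations
#'
#' @param pose_id identifier.
#' @param atoms `data.frame` with columns `name`, `elety`, `x`, `y`, `z`,
#'   `donor`, `acceptor` (hydrogen-bond capability flags).
#' @param e_total total binding energy in kcal/mol.
#' @param delec electrostatic interaction energy in solvent minus the
#'   ligand desolvation penalty, kcal/mol.
#' @return An object of class `dock_pose`.
#' @export
dock_pose <- function(pose_id, atoms, e_total, delec) {
  stopifnot(is.finite(e_total), is.finite(delec),
            all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
  structure(list(pose_id = pose_id, atoms = atoms,
                 e_total = e_total, delec = delec),
            class = "dock_pose")
}

#' Rank docking poses by the two energy terms
#'
#' Builds two independent ascending rankings — total binding energy and
#' the electrostatics-minus-desolvation term — and returns the union of
#' the top `top_n` of each, every entry annotated with both ranks.  Ties
#' break deterministically by `pose_id`, and the result is invariant to
#' input order.
#'
#' @param poses list of `dock_pose` objects, or a `data.frame` with
#'   columns `pose_id`, `E_total`, `Delec` (a score table).
#' @param top_n shortlist depth per ranking.
#' @return A `data.frame` with columns `pose_id`, `E_total`, `Delec`,
#'   `rank_e_total`, `rank_delec`, `shortlisted`, sorted by
#'   `rank_e_total`.  All poses are listed; `shortlisted` marks the
#'   union of the two top-`top_n` sets.
#' @export
rank_poses <- function(poses, top_n) {
  scores <- if (is.data.frame(poses)) {
    poses
  } else {
    if (length(poses) == 0L) stop("need at least one pose to rank")
    data.frame(pose_id = vapply(poses, `[[`, character(1), "pose_id"),
               E_total = vapply(poses, `[[`, numeric(1), "e_total"),
               Delec = vapply(poses, `[[`, numeric(1), "delec"),
               stringsAsFactors = FALSE)
  }
  if (nrow(scores) == 0L) stop("need at least one pose to rank")
  ord_e <- order(scores$E_total, scores$pose_id)
  ord_d <- order(scores$Delec, scores$pose_id)
  scores$rank_e_total <- match(seq_len(nrow(scores)), ord_e)
  scores$rank_delec <- match(seq_len(nrow(scores)), ord_d)
  scores$shortlisted <- scores$rank_e_total <= top_n | scores$rank_delec <= top_n
  scores <- scores[order(scores$rank_e_total), ]
  rownames(scores) <- NULL
  scores
}

#' Hydrogen-bond geometry criteria
#'
#' @param max_donor_acceptor_distance maximum donor-to-acceptor heavy-atom
#'   distance, Angstrom (default 3.5).
#' @param min_angle_at_hydrogen minimum donor-H-acceptor angle, degrees
#'   (default 120).
#' @param heavy_atom_fallback_distance distance criterion applied when no
#'   hydrogen position is available (default 3.5 Angstrom).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 3.5,
                           min_angle_at_hydrogen = 120,
                           heavy_atom_fallback_distance = 3.5) {
  stopifnot(max_donor_acceptor_distance > 0,
            min_angle_at_hydrogen > 0, min_angle_at_hydrogen <= 180,
            heavy_atom_fallback_distance > 0)
  structure(list(max_donor_acceptor_distance = max_donor_acceptor_distance,
                 min_angle_at_hydrogen = min_angle_at_hydrogen,
                 heavy_atom_fallback_distance = heavy_atom_fallback_distance),
            class = "hbond_criteria")
}

#' Detect a hydrogen bond between a donor and an acceptor atom
#'
#' With an explicit hydrogen, the bond requires the donor-acceptor
#' distance within the cutoff *and* the donor-H-acceptor angle at or
#' above the minimum.  Without a hydrogen (the usual case for docking
#' poses and MD pseudo-atoms), the heavy-atom fallback distance alone
#' decides.  The measured geometry is always returned.
#'
#' @param donor,acceptor numeric xyz vectors (Angstrom); must differ.
#' @param hydrogen optional numeric xyz of the donor hydrogen.
#' @param criteria an [hbond_criteria()].
#' @return A list with `is_hbond` (logical), `distance` (Angstrom), and
#'   `angle` (degrees at the hydrogen, `NA` without one).
#' @export
detect_hbond <- function(donor, acceptor, hydrogen = NULL,
                         criteria = hbond_criteria()) {
  donor <- as.numeric(donor); acceptor <- as.numeric(acceptor)
  d <- sqrt(sum((donor - acceptor)^2))
  if (d < sqrt(.Machine$double.eps)) {
    stop("donor and acceptor are the same atom position")
  }
  if (is.null(hydrogen)) {
    return(list(is_hbond = d <= criteria$heavy_atom_fallback_distance,
                distance = d, angle = NA_real_))
  }
  hydrogen <- as.numeric(hydrogen)
  v1 <- donor - hydrogen
  v2 <- acceptor - hydrogen
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  list(is_hbond = d <= criteria$max_donor_acceptor_distance &&
         angle >= criteria$min_angle_at_hydrogen,
       distance = d, angle = angle)
}

# All donor->acceptor hydrogen bonds between two atom tables (heavy-atom
# fallback; the tables carry no hydrogens).
hbonds_between <- function(from_atoms, from_xyz, to_atoms, to_xyz, criteria) {
  out <- list()
  for (i in which(from_atoms$donor)) {
    for (j in which(to_atoms$acceptor)) {
      hb <- detect_hbond(from_xyz[i, ], to_xyz[j, ], criteria = criteria)
      if (hb$is_hbond) {
        out[[length(out) + 1L]] <- data.frame(
          donor = from_atoms$name[i], acceptor = to_atoms$name[j],
          distance = hb$distance, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(donor = character(), acceptor = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Pharmacophore filter for the m6A recognition pocket
#'
#' Keeps a pose only if a ligand donor hydrogen-bonds the C433 backbone
#' carbonyl (the acceptor of the natural ligand's N6-H) **and** the pose
#' makes at least one further favourable polar contact: a ligand acceptor
#' receiving the Y418 backbone NH, a ligand donor reaching the D422
#' carboxylate, or a hydrogen bond in either direction with the conserved
#' structural water.  The returned fingerprint lists every satisfied
#' interaction with its geometry.
#'
#' @param pose a `dock_pose`.
#' @param pocket a `pocket_topology` (must provide `C433_O`, `Y418_N`,
#'   `D422_OD1`/`D422_OD2`, and `HOH_O`).
#' @param criteria an [hbond_criteria()].
#' @return A list with `keep` (logical) and `fingerprint` (`data.frame`
#'   with columns `site`, `ligand_atom`, `pocket_atom`, `distance`).
#' @export
pharmacophore_filter <- function(pose, pocket = make_pocket_topology(),
                                 criteria = hbond_criteria()) {
  need <- c("C433_O", "Y418_N", "D422_OD1", "D422_OD2", "HOH_O")
  missing <- setdiff(need, pocket$name)
  if (length(missing) > 0L) {
    stop("pocket is missing pharmacophore anchor(s): ",
         paste(missing, collapse = ", "))
  }
  lig <- pose$atoms
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  poc_xyz <- as.matrix(pocket[, c("x", "y", "z")])
  fp <- list()
  add <- function(site, ligand_atom, pocket_atom, distance) {
    fp[[length(fp) + 1L]] <<- data.frame(
      site = site, ligand_atom = ligand_atom, pocket_atom = pocket_atom,
      distance = distance, stringsAsFactors = FALSE)
  }
  site_rows <- function(names) match(names, pocket$name)

  # mandatory: ligand donor -> C433 backbone carbonyl
  hb <- hbonds_between(lig, lig_xyz, pocket[site_rows("C433_O"), ],
                       poc_xyz[site_rows("C433_O"), , drop = FALSE], criteria)
  if (nrow(hb) > 0L) {
    best <- hb[which.min(hb$distance), ]
    add("C433", best$donor, best$acceptor, best$distance)
  }
  has_c433 <- nrow(hb) > 0L

  # Y418 backbone NH donating to a ligand acceptor
  y418 <- pocket[site_rows("Y418_N"), ]
  hb <- hbonds_between(y418, poc_xyz[site_rows("Y418_N"), , drop = FALSE],
                       lig, lig_xyz, criteria)
  if (nrow(hb) > 0L) {
    best <- hb[which.min(hb$distance), ]
    add("Y418", best$acceptor, best$donor, best$distance)
  }

  # ligand donor -> D422 carboxylate
  d422_rows <- site_rows(c("D422_OD1", "D422_OD2"))
  hb <- hbonds_between(lig, lig_xyz, pocket[d422_rows, ],
                       poc_xyz[d422_rows, , drop = FALSE], criteria)
  if (nrow(hb) > 0L) {
    best <- hb[which.min(hb$distance), ]
    add("D422", best$donor, best$acceptor, best$distance)
  }

  # structural water, either direction
  w_row <- site_rows("HOH_O")
  hb1 <- hbonds_between(lig, lig_xyz, pocket[w_row, ],
                        poc_xyz[w_row, , drop = FALSE], criteria)
  hb2 <- hbonds_between(pocket[w_row, ], poc_xyz[w_row, , drop = FALSE],
                        lig, lig_xyz, criteria)
  if (nrow(hb1) > 0L || nrow(hb2) > 0L) {
    both <- rbind(hb1, hb2[, c("donor", "acceptor", "distance")])
    best <- both[which.min(both$distance), ]
    lig_atom <- if (best$donor %in% lig$name) best$donor else best$acceptor
    poc_atom <- setdiff(c(best$donor, best$acceptor), lig_atom)
    add("water", lig_atom, poc_atom, best$distance)
  }

  fingerprint <- if (length(fp) == 0L) {
    data.frame(site = character(), ligand_atom = character(),
               pocket_atom = character(), distance = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, fp)
  }
  secondary <- any(fingerprint$site %in% c("Y418", "D422", "water"))
  list(keep = has_c433 && secondary, fingerprint = fingerprint)
}

#' Docking triage report: rank, filter, select
#'
#' For every pose, records both energy ranks, the pharmacophore verdict,
#' and the interaction fingerprint size; the selected set is the
#' intersection of the rank shortlist (union of the two top-`top_n`
#' lists) with the poses passing the filter.
#'
#' @param poses list of `dock_pose` objects.
#' @param pocket a `pocket_topology`.
#' @param criteria an [hbond_criteria()].
#' @param top_n shortlist depth per ranking.
#' @return A list with `table` (per-pose `data.frame` including a
#'   `selected` column), `fingerprints` (named list of fingerprint
#'   `data.frame`s), and `selected` (character vector of pose ids).
#' @export
triage_report <- function(poses, pocket = make_pocket_topology(),
                          criteria = hbond_criteria(), top_n = 50L) {
  if (length(poses) == 0L) {
    return(list(table = data.frame(pose_id = character(), E_total = numeric(),
                                   Delec = numeric(), rank_e_total = integer(),
                                   rank_delec = integer(), shortlisted = logical(),
                                   filter_keep = logical(), n_interactions = integer(),
                                   selected = logical(), stringsAsFactors = FALSE),
                fingerprints = list(), selected = character()))
  }
  ranked <- rank_poses(poses, top_n)
  verdicts <- lapply(poses, pharmacophore_filter, pocket = pocket,
                     criteria = criteria)
  ids <- vapply(poses, `[[`, character(1), "pose_id")
  keep <- vapply(verdicts, `[[`, logical(1), "keep")
  nint <- vapply(verdicts, function(v) nrow(v$fingerprint), integer(1))
  i <- match(ranked$pose_id, ids)
  ranked$filter_keep <- keep[i]
  ranked$n_interactions <- nint[i]
  ranked$selected <- ranked$shortlisted & ranked$filter_keep
  fps <- stats::setNames(lapply(verdicts, `[[`, "fingerprint"), ids)
  list(table = ranked, fingerprints = fps,
       selected = ranked$pose_id[ranked$selected])
}

#' Write docking poses as a multi-model PDB with a score-table CSV
#'
#' @param gen result of [generate_docking_poses()] (or a list with
#'   `poses` and `scores`).
#' @param pdb_file,scores_file output paths.
#' @return `pdb_file`, invisibly.
#' @export
write_docking_poses <- function(gen, pdb_file, scores_file) {
  if (length(gen$poses) > 0L) {
    at0 <- gen$poses[[1L]]$atoms
    atoms <- data.frame(name = at0$name, resid = "LIG", elety = at0$elety,
                        role = "ligand", donor = at0$donor,
                        acceptor = at0$acceptor, stringsAsFactors = FALSE)
    xyz <- t(vapply(gen$poses, function(p) {
      as.vector(t(as.matrix(p$atoms[, c("x", "y", "z")])))
    }, numeric(3L * nrow(at0))))
    write_trajectory_pdb(trajectory(atoms, xyz, seq_along(gen$poses)), pdb_file)
  } else {
    writeLines("END", pdb_file)
  }
  utils::write.csv(gen$scores, scores_file, row.names = FALSE)
  invisible(pdb_file)
}
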