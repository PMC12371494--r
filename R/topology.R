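#' Construct the pseudo-pocket topology of the m6A recognition site
#'
#' Builds a stylised, fixed-coordinate model of the YTH aromatic-cage
#' pocket carrying one labelled anchor atom set per residue relevant to
#' ligand recognition: the C433 backbone nitrogen and carbonyl oxygen, the
#' two carboxylate oxygens of D422, the Y418 backbone nitrogen (a
#' hydrogen-bond donor NH), ring centroids for the cage tryptophans W432,
#' W486 and W491, a D528 carboxylate oxygen, and the conserved
#' structural-water oxygen.  Coordinates are fixed constants (in Angstrom)
#' chosen so that
#'
#' * the exocyclic sulfur of both pose templates lies well inside the
#'   5 Angstrom bound-frame criterion measured to the C433 backbone N;
#' * pose A places the ligand carbonyl oxygen nearest the Y418 backbone
#'   NH while pose B places it nearest the structural water, reproducing
#'   the hydrogen-bond swap between the two binding modes;
#' * the thiourea NH groups sit at hydrogen-bond distance of the C433
#'   carbonyl and the D422 carboxylate in both poses.
#'
#' The pocket is deliberately schematic — anchors are single pseudo-atoms,
#' not full residues — but its geometry preserves every relation the
#' downstream featurization, clustering, and pharmacophore filter rely on.
#'
#' @return An object of class `pocket_topology`: a `data.frame` with one
#'   row per anchor atom and columns `name` (unique atom label), `resid`
#'   (residue label), `elety` (element/centroid tag), `role` (`"protein"`
#'   or `"water"`), `donor`/`acceptor` (logical hydrogen-bond capability),
#'   and `x`, `y`, `z` coordinates in Angstrom.
#' @examples
#' pocket <- make_pocket_topology()
#' nrow(pocket)           # 10 anchors
#' subset(pocket, resid == "C433")
#' @export
make_pocket_topology <- function() {
  top <- data.frame(
    name  = c("C433_N", "C433_O", "D422_OD1", "D422_OD2", "Y418_N",
              "W432_CEN", "W486_CEN", "W491_CEN", "D528_OD1", "HOH_O"),
    resid = c("C433", "C433", "D422", "D422", "Y418",
              "W432", "W486", "W491", "D528", "HOH"),
    elety = c("N", "O", "OD1", "OD2", "N", "CEN", "CEN", "CEN", "OD1", "O"),
    role  = c(rep("protein", 9L), "water"),
    donor    = c(TRUE,  FALSE, FALSE, FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE, TRUE),
    acceptor = c(FALSE, TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE, TRUE,  TRUE),
    x = c( 4.8, -1.2, -1.2, -0.3, -4.6,  3.6,  3.4,  5.4, -5.8, -4.6),
    y = c( 1.0,  3.9, -3.9, -4.6,  3.4, -2.2,  2.4, -0.6, -4.6, -3.4),
    z = c( 0.0,  0.8, -0.8, -0.2,  1.2,  2.4, -2.2, -1.8, -0.4, -1.2),
    stringsAsFactors = FALSE
  )
  class(top) <- c("pocket_topology", "data.frame")
  top
}

#' Ligand pose templates for the thiourea scaffold
#'
#' Returns the coordinates of the thiourea-ring scaffold in one of its two
#' binding modes.  The scaffold carries eight heavy atoms: the thiourea
#' carbon (`C_THIO`) and exocyclic sulfur (`S_EXO`), the two ring NH
#' nitrogens (`N1`, `N2`), two ring carbons (`C5`, `C6`), the carbonyl
#' oxygen (`O_CARB`), and the thiophene sulfur (`S_THIO`).  Template B is
#' template A rotated by 180 degrees about the S=C double-bond axis (the x
#' axis of the template frame): atoms on the axis are unchanged while
#' `N1`/`N2` and `O_CARB`/`S_THIO` swap positions.  In pose A the carbonyl
#' oxygen points toward the Y418 backbone NH; in pose B it points toward
#' the conserved structural water.
#'
#' @param pose `"A"` or `"B"`.
#' @return A `data.frame` with columns `name`, `elety`, `role` (always
#'   `"ligand"`), `donor`, `acceptor`, and `x`, `y`, `z` in Angstrom.
#' @examples
#' a <- pose_template("A")
#' b <- pose_template("B")
#' # the flip swaps the carbonyl oxygen with the thiophene sulfur:
#' a[a$name == "O_CARB", c("x", "y", "z")]
#' b[b$name == "O_CARB", c("x", "y", "z")]
#' @export
pose_template <- function(pose = c("A", "B")) {
  pose <- match.arg(pose)
  lig <- data.frame(
    name  = c("C_THIO", "S_EXO", "N1", "N2", "C5", "C6", "O_CARB", "S_THIO"),
    elety = c("C", "S", "N", "N", "C", "C", "O", "S"),
    role  = "ligand",
    donor    = c(FALSE, FALSE, TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE),
    acceptor = c(FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE, TRUE,  TRUE),
    x = c(0.0,  1.70, -0.70, -0.70, -2.10, -2.10, -2.80, -2.80),
    y = c(0.0,  0.00,  1.20, -1.20,  1.25, -1.25,  1.80, -1.80),
    z = c(0.0,  0.00,  0.00,  0.00,  0.25, -0.25,  0.50, -0.50),
    stringsAsFactors = FALSE
  )
  if (pose == "B") {
    # 180 degree rotation about the x axis through the S=C bond
    lig$y <- -lig$y
    lig$z <- -lig$z
  }
  lig
}

#' Default atom pairs defining the ten pocket--ligand distances
#'
#' The featurization measures ten distances between scaffold heavy atoms
#' and pocket anchors: four to C433 (the bound-frame S--N distance, the
#' two NH-to-carbonyl distances, and the carbonyl-O-to-backbone-N
#' distance), two to the D422 carboxylate, and one each to Y418 and the
#' three cage tryptophan centroids.  These pairs follow the hydrogen-bond
#' partners seen in the crystal structures of this fragment series; they
#' can be overridden wherever a `FeatureMatrix` is computed.
#'
#' @return A `data.frame` with columns `feature` (fixed column name),
#'   `ligand_atom`, and `pocket_atom`.
#' @export
default_feature_pairs <- function() {
  data.frame(
    feature     = c("C433_1", "C433_2", "C433_3", "C433_4",
                    "D422_1", "D422_2", "Y418", "W432", "W486", "W491"),
    ligand_atom = c("S_EXO", "N1", "N2", "O_CARB",
                    "N1", "N2", "S_EXO", "S_EXO", "S_EXO", "S_EXO"),
    pocket_atom = c("C433_N", "C433_O", "C433_O", "C433_N",
                    "D422_OD1", "D422_OD2", "Y418_N",
                    "W432_CEN", "W486_CEN", "W491_CEN"),
    stringsAsFactors = FALSE
  )
}
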