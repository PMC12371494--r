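#' Compute the ten pocket--ligand distance features
#'
#' For each frame, measures the ten distances between scaffold heavy
#' atoms and pocket anchors defined by `pairs` (default:
#' [default_feature_pairs()]).  By convention this is applied to bound
#' frames only (after [select_bound()]); the function itself accepts any
#' trajectory whose topology carries the required atoms.  Atoms are looked
#' up by name, so the result is invariant to atom order in the topology.
#'
#' @param traj a `trajectory`, or a `trajectory_set` (replicates are
#'   pooled row-wise in list order).
#' @param pairs `data.frame` with columns `feature`, `ligand_atom`,
#'   `pocket_atom`.
#' @return A `feature_matrix`: numeric matrix, one row per frame and one
#'   column per distance (Angstrom), with attributes `replicate_id` and
#'   `frame_index` locating each row in its source trajectory.
#' @export
featurize <- function(traj, pairs = default_feature_pairs()) {
  if (inherits(traj, "trajectory_set")) {
    mats <- lapply(traj, featurize, pairs = pairs)
    out <- do.call(rbind, mats)
    attr(out, "replicate_id") <- unlist(lapply(mats, attr, "replicate_id"))
    attr(out, "frame_index") <- unlist(lapply(mats, attr, "frame_index"))
    class(out) <- c("feature_matrix", class(out))
    return(out)
  }
  need <- unique(c(pairs$ligand_atom, pairs$pocket_atom))
  missing <- setdiff(need, traj$atoms$name)
  if (length(missing) > 0L) {
    stop("featurization anchors absent from topology: ",
         paste(missing, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = n_frames(traj), ncol = nrow(pairs),
                dimnames = list(NULL, pairs$feature))
  for (j in seq_len(nrow(pairs))) {
    out[, j] <- atom_distance(traj, pairs$ligand_atom[j], pairs$pocket_atom[j])
  }
  attr(out, "replicate_id") <- rep(traj$replicate_id, n_frames(traj))
  attr(out, "frame_index") <- seq_len(n_frames(traj))
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Project distance features onto the top two principal components
#'
#' Mean-centers the feature matrix (no scaling — all features share units
#' of Angstrom) and projects onto the first two principal components.
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making projections reproducible across
#' implementations.
#'
#' @param features a `feature_matrix` (or plain numeric matrix) with at
#'   least three rows.
#' @return A list of class `pca_projection` with elements `scores`
#'   (n x 2 matrix, columns `PC1`, `PC2`), `explained_variance` (two
#'   fractions), `loadings` (p x 2), `center` (feature means),
#'   `replicate_id`, and `frame_index`.
#' @export
project_2d <- function(features) {
  x <- unclass(features)
  if (nrow(x) < 3L) stop("need at least 3 frames for a 2-D projection")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[1L] <= sqrt(.Machine$double.eps)) {
    stop("feature matrix is rank-deficient: no variance to project; ",
         "cannot build a 2-D projection")
  }
  if (pc$sdev[2L] <= sqrt(.Machine$double.eps)) {
    # two-point geometries (e.g. noise-free pose templates) are legal:
    # all variance lives on PC1 and PC2 is identically zero
    warning("feature matrix has rank 1; PC2 carries no variance")
  }
  load2 <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(load2[, j]))
    if (load2[k, j] < 0) {
      load2[, j] <- -load2[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(load2) <- c("PC1", "PC2")
  structure(
    list(scores = scores,
         explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[1:2],
         loadings = load2,
         center = pc$center,
         replicate_id = attr(features, "replicate_id"),
         frame_index = attr(features, "frame_index")),
    class = "pca_projection"
  )
}
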