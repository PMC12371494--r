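#' Attach scientific pose labels (A/B) to fitted clusters
#'
#' Cluster identity is resolved from centroid geometry, never from fit
#' order: the cluster whose centroid frame places the ligand carbonyl
#' oxygen closer to the Y418 backbone NH than to the structural water is
#' labelled pose A (the hydrogen-bond arrangement seen in the reference
#' crystal structure); the cluster with the opposite arrangement is pose
#' B.  Ties break toward A.
#'
#' @param result a `pose_cluster_result` from [fit_mixture()].
#' @param trajectories the `trajectory_set` (or single `trajectory`) the
#'   projection was built from; centroid frames are located by
#'   `(replicate_id, frame_index)`.
#' @param carbonyl,y418,water atom labels used by the geometric rule.
#' @return `result` with elements `pose_labels` (per cluster) and
#'   `centroids` (the [centroid_frames()] table with a `pose` column).
#' @export
label_clusters <- function(result, trajectories,
                           carbonyl = "O_CARB", y418 = "Y418_N",
                           water = "HOH_O") {
  if (inherits(trajectories, "trajectory")) {
    trajectories <- structure(list(trajectories), class = "trajectory_set")
  }
  cent <- centroid_frames(result)
  reps <- vapply(trajectories, `[[`, character(1), "replicate_id")
  labels <- character(nrow(cent))
  margin <- numeric(nrow(cent))
  for (j in seq_len(nrow(cent))) {
    if (is.na(cent$row[j])) {
      labels[j] <- NA_character_
      next
    }
    tr <- trajectories[[match(cent$replicate_id[j], reps)]]
    co <- frame_coords(tr, cent$frame_index[j])
    d_y <- sqrt(sum((co[carbonyl, ] - co[y418, ])^2))
    d_w <- sqrt(sum((co[carbonyl, ] - co[water, ])^2))
    labels[j] <- if (d_y <= d_w) "A" else "B"
    margin[j] <- d_w - d_y
  }
  if (length(labels) == 2L && !anyNA(labels) && labels[1L] == labels[2L]) {
    # both centroids matched the same geometry: keep the clearer match,
    # assign the alternative label to the other cluster
    warning("both cluster centroids matched pose ", labels[1L],
            "; disambiguating by hydrogen-bond margin")
    weaker <- which.min(abs(margin))
    labels[weaker] <- setdiff(c("A", "B"), labels[-weaker])
  }
  cent$pose <- labels
  result$pose_labels <- labels
  result$centroids <- cent
  result
}

#' Pose populations by label
#'
#' @param result a labelled `pose_cluster_result` (see [label_clusters()]).
#' @return Named numeric vector of bound-frame fractions (sums to 1).
#' @export
pose_populations <- function(result) {
  if (is.null(result$pose_labels)) {
    stop("result carries no pose labels; run label_clusters() first")
  }
  stats::setNames(result$populations, result$pose_labels)
}

#' Full pose-inference pipeline
#'
#' Runs the complete chain on a trajectory ensemble:
#' subsample (default: second half of each run at 1 ns) -> bound-frame
#' selection (sulfur-to-C433-N distance < 5 Angstrom) -> ten-distance
#' featurization -> PCA to two dimensions -> full-covariance Gaussian
#' mixture -> pose labelling and centroid extraction.  Replicates are
#' pooled into a single clustering.  Deterministic for a fixed `seed`.
#'
#' @param trajectories a `trajectory_set` (or single `trajectory`).
#' @param t_start,t_end,interval subsampling window and grid in ns (see
#'   [subsample()]); `t_start = NULL` uses half of each run's span.
#' @param threshold bound-frame cutoff in Angstrom.
#' @param k number of mixture components.
#' @param seed RNG seed for the mixture fit.
#' @param pairs feature definition (see [default_feature_pairs()]).
#' @return A list of class `pose_pipeline_result` with elements
#'   `result` (labelled `pose_cluster_result`), `projection`,
#'   `features`, `bound` (the pooled bound `trajectory_set`),
#'   `populations` (named by pose), and `counts` (frames at each stage).
#' @examples
#' spec <- trajectory_gen_spec(n_replicates = 2, n_frames_per_replicate = 60,
#'                             pose_weight_A = 0.6, seed = 7)
#' trajs <- generate_trajectory(spec)
#' fit <- cluster_poses(trajs, t_start = 30, t_end = 60, seed = 7)
#' fit$populations
#' @export
cluster_poses <- function(trajectories, t_start = NULL, t_end = NULL,
                          interval = 1, threshold = 5.0, k = 2L, seed = 1L,
                          pairs = default_feature_pairs()) {
  if (inherits(trajectories, "trajectory")) {
    trajectories <- structure(list(trajectories), class = "trajectory_set")
  }
  n_read <- sum(vapply(trajectories, n_frames, integer(1)))
  sub <- lapply(trajectories, subsample, t_start = t_start, t_end = t_end,
                interval = interval)
  n_sub <- sum(vapply(sub, n_frames, integer(1)))
  bound <- lapply(sub, function(tr) select_bound(tr, threshold)$trajectory)
  bound <- structure(bound, class = "trajectory_set")
  n_bound <- sum(vapply(bound, n_frames, integer(1)))
  features <- featurize(bound, pairs = pairs)
  projection <- project_2d(features)
  result <- fit_mixture(projection, k = k, seed = seed)
  result <- label_clusters(result, bound)
  structure(
    list(result = result, projection = projection, features = features,
         bound = bound,
         populations = pose_populations(result),
         counts = c(frames_read = n_read, frames_subsampled = n_sub,
                    frames_bound = n_bound)),
    class = "pose_pipeline_result"
  )
}

#' @export
print.pose_pipeline_result <- function(x, ...) {
  cat("pose-inference pipeline\n")
  cat(sprintf("  frames: %d read -> %d subsampled -> %d bound\n",
              x$counts[["frames_read"]], x$counts[["frames_subsampled"]],
              x$counts[["frames_bound"]]))
  cat(sprintf("  explained variance (PC1, PC2): %.1f%%, %.1f%%\n",
              100 * x$projection$explained_variance[1],
              100 * x$projection$explained_variance[2]))
  print(x$result)
  invisible(x)
}

#' Write the clustering report of a pipeline run
#'
#' Emits a JSON report (weights, populations by pose, centroid frame
#' references, explained variance, convergence flag) and optionally a
#' per-frame assignment CSV.
#'
#' @param fit a `pose_pipeline_result` from [cluster_poses()].
#' @param report_file path for the JSON report.
#' @param assignments_file optional path for the per-frame CSV.
#' @return `report_file`, invisibly.
#' @export
write_cluster_report <- function(fit, report_file, assignments_file = NULL) {
  res <- fit$result
  report <- list(
    k = length(res$weights),
    weights = res$weights,
    pose_labels = res$pose_labels,
    populations = as.list(pose_populations(res)),
    explained_variance = res$explained_variance,
    centroids = res$centroids[, c("cluster", "pose", "replicate_id",
                                  "frame_index", "distance")],
    converged = res$converged,
    counts = as.list(fit$counts)
  )
  jsonlite::write_json(report, report_file, dataframe = "rows",
                       auto_unbox = TRUE, digits = 10)
  if (!is.null(assignments_file)) {
    utils::write.csv(
      data.frame(replicate_id = res$replicate_id,
                 frame_index = res$frame_index,
                 PC1 = res$scores[, 1], PC2 = res$scores[, 2],
                 cluster = res$assignments,
                 pose = res$pose_labels[res$assignments]),
      assignments_file, row.names = FALSE)
  }
  invisible(report_file)
}
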