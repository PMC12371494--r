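test_that("subsampling implements the window, interval, and boundary rule", {
  topo <- make_pocket_topology()
  tr <- template_trajectory(n_frames = 200)  # times 1..200 ns
  # analysis window [100, 200] at 1 ns: both ends included -> 101 frames
  sub <- subsample(tr, t_start = 100, t_end = 200, interval = 1)
  expect_identical(n_frames(sub), 101L)
  expect_equal(range(sub$times), c(100, 200))
  # full span at native spacing: identity
  sub <- subsample(tr, t_start = 1, t_end = 200, interval = 1)
  expect_identical(sub$xyz, tr$xyz)
  # doubled interval: every second frame
  sub <- subsample(tr, t_start = 1, t_end = 200, interval = 2)
  expect_equal(sub$times, seq(1, 199, by = 2))
  # empty selection is an explicit error
  expect_error(subsample(tr, t_start = 0.2, t_end = 0.4, interval = 1),
               "no frames")
})

test_that("bound-frame selection applies the strict 5 A criterion", {
  trajs <- small_ensemble(unbound_fraction = 0.2, seed = 5)
  pooled <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(bound = select_bound(tr)$bound_mask,
               truth = tr$ground_truth$bound)
  }))
  expect_identical(pooled$bound, pooled$truth)
  frac <- mean(pooled$bound)
  half <- qnorm(0.995) * sqrt(0.8 * 0.2 / nrow(pooled))
  expect_gte(frac, 0.8 - half)
  expect_lte(frac, 0.8 + half)

  # a frame at exactly the threshold is excluded; all-bound input is identity
  tr <- template_trajectory(n_frames = 3)
  i_s <- posepop:::xyz_cols(tr, "S_EXO")
  i_n <- posepop:::xyz_cols(tr, "C433_N")
  u <- tr$xyz[2, i_s] - tr$xyz[2, i_n]
  u <- u / sqrt(sum(u^2))
  d0 <- sqrt(sum((tr$xyz[2, i_s] - tr$xyz[2, i_n])^2))
  lig <- which(tr$atoms$role == "ligand")
  for (j in lig) {
    cols <- posepop:::xyz_cols(tr, j)
    tr$xyz[2, cols] <- tr$xyz[2, cols] + (5 - d0) * u
  }
  sel <- select_bound(tr)
  expect_identical(sel$bound_mask, c(TRUE, FALSE, TRUE))

  tr_all <- template_trajectory(n_frames = 4)
  sel <- select_bound(tr_all)
  expect_true(all(sel$bound_mask))
  expect_identical(sel$trajectory$xyz, tr_all$xyz)

  # missing anchor names the absent atom
  tr_broken <- tr_all
  tr_broken$atoms$name[tr_broken$atoms$name == "C433_N"] <- "XX"
  expect_error(select_bound(tr_broken), "C433_N")
})

test_that("featurization returns the ten named distances and is atom-order invariant", {
  tr <- template_trajectory("A", n_frames = 3)
  f <- featurize(tr)
  expect_identical(colnames(f),
                   c("C433_1", "C433_2", "C433_3", "C433_4",
                     "D422_1", "D422_2", "Y418", "W432", "W486", "W491"))
  expect_true(all(f > 0))
  # noise-free frames of one pose: rows exactly constant
  expect_equal(unclass(f)[1, ], unclass(f)[3, ])

  # independent oracle: pairwise distances via dist() on the raw frame
  co <- posepop:::frame_coords(tr, 1)
  dd <- as.matrix(dist(co))
  pairs <- default_feature_pairs()
  expected <- mapply(function(l, p) dd[l, p], pairs$ligand_atom,
                     pairs$pocket_atom)
  expect_equal(unname(unclass(f)[1, ]), unname(expected))

  # permuting atom order leaves the features unchanged (lookup by name)
  perm <- sample(nrow(tr$atoms))
  cols <- as.vector(vapply(perm, function(j) 3L * (j - 1L) + 1:3, integer(3)))
  tr_perm <- trajectory(tr$atoms[perm, ], tr$xyz[, cols, drop = FALSE],
                        tr$times, tr$replicate_id)
  expect_equal(unclass(featurize(tr_perm)), unclass(f),
               ignore_attr = TRUE)

  # absent anchors are reported by name
  tr_broken <- tr
  tr_broken$atoms$name[tr_broken$atoms$name == "W486_CEN"] <- "XX"
  expect_error(featurize(tr_broken), "W486_CEN")
})

test_that("PCA projection handles two-point, isotropic, and shifted inputs", {
  # noise-free two-template data collapses to exactly 2 locations
  topo <- make_pocket_topology()
  trA <- template_trajectory("A", n_frames = 5)
  trB <- template_trajectory("B", n_frames = 5, replicate_id = "rep2")
  f <- featurize(structure(list(trA, trB), class = "trajectory_set"))
  proj <- suppressWarnings(project_2d(f))
  pts <- unique(round(proj$scores, 8))
  expect_identical(nrow(pts), 2L)

  # isotropic Gaussian cloud: the two explained variances are comparable
  set.seed(42)
  cloud <- matrix(rnorm(4000), ncol = 4)
  pr <- project_2d(cloud)
  expect_lt(abs(pr$explained_variance[1] - pr$explained_variance[2]), 0.05)

  # adding a constant to every column only shifts the mean: projection
  # (with the fixed sign convention) is unchanged
  pr2 <- project_2d(cloud + 7)
  expect_equal(pr2$scores, pr$scores)

  # all-identical frames carry no variance to project
  expect_error(project_2d(matrix(1, nrow = 5, ncol = 10)), "rank-deficient")
})

test_that("the mixture fit recovers planted weights and matches mclust", {
  # Mclust resolves mclustBIC in the calling frame, so attach the package
  suppressPackageStartupMessages(library(mclust))
  set.seed(7)
  n <- 800; w <- 0.55
  nA <- round(n * w)
  x <- rbind(cbind(rnorm(nA, -3, 0.5), rnorm(nA, 0, 0.5)),
             cbind(rnorm(n - nA, 3, 0.5), rnorm(n - nA, 0, 0.5)))
  fit <- fit_mixture(x, k = 2, seed = 1)
  expect_true(fit$converged)
  expect_equal(sum(fit$populations), 1)
  expect_lt(abs(max(fit$populations) - w), 0.03)

  # independent route: mclust VVV on the same data
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_lt(abs(max(fit$populations) -
                  max(tabulate(mc$classification, 2) / n)), 0.005)

  # k = 1 is a single cluster with population 1
  fit1 <- fit_mixture(x, k = 1, seed = 1)
  expect_equal(fit1$populations, 1)

  # deterministic for a fixed seed
  fit2 <- fit_mixture(x, k = 2, seed = 1)
  expect_identical(fit$populations, fit2$populations)
  expect_identical(fit$assignments, fit2$assignments)
})

test_that("population estimates are invariant to frame order", {
  set.seed(13)
  x <- rbind(cbind(rnorm(300, -3, 0.5), rnorm(300, 0, 0.5)),
             cbind(rnorm(200, 3, 0.5), rnorm(200, 0, 0.5)))
  f1 <- fit_mixture(x, k = 2, seed = 3)
  f2 <- fit_mixture(x[sample(nrow(x)), ], k = 2, seed = 3)
  expect_equal(sort(f1$populations), sort(f2$populations), tolerance = 1e-6)
})

test_that("centroid frames agree with an exhaustive nearest-frame search", {
  fitres <- cluster_poses(small_ensemble(seed = 19), t_start = 50,
                          t_end = 100, seed = 19)
  res <- fitres$result
  cent <- centroid_frames(res)
  for (j in seq_along(res$weights)) {
    rows <- which(res$assignments == j)
    d <- apply(res$scores[rows, , drop = FALSE], 1L,
               function(p) sqrt(sum((p - res$means[j, ])^2)))
    expect_identical(cent$row[j], rows[which.min(d)])
    expect_equal(cent$distance[j], min(d))
  }

  # degenerate geometry: exact ties break toward the earliest frame
  scores <- rbind(c(0, 0), c(0, 0), c(10, 0), c(10, 0))
  res0 <- structure(list(weights = c(0.5, 0.5),
                         means = rbind(c(0, 0), c(10, 0)),
                         covariances = list(diag(2), diag(2)),
                         assignments = c(1L, 1L, 2L, 2L),
                         populations = c(0.5, 0.5), scores = scores,
                         replicate_id = rep("rep1", 4),
                         frame_index = 1:4),
                    class = "pose_cluster_result")
  cent0 <- centroid_frames(res0)
  expect_identical(cent0$row, c(1L, 3L))   # earliest of each tied pair
  expect_equal(cent0$distance, c(0, 0))    # points exactly at the means
})

test_that("ligand RMSD obeys closed forms and rigid-motion invariance", {
  tr <- template_trajectory(n_frames = 4)
  ref <- reference_frame(tr, 1)
  # self-reference: identically zero
  series <- ligand_rmsd(tr, ref)
  expect_equal(max(abs(series$per_replicate_rmsd)), 0, tolerance = 1e-10)

  # rigid 2 A ligand translation with anchors fixed: RMSD exactly 2
  tr2 <- tr
  for (j in which(tr$atoms$role == "ligand")) {
    cols <- posepop:::xyz_cols(tr, j)
    tr2$xyz[2, cols] <- tr2$xyz[2, cols] + c(2, 0, 0)
  }
  series2 <- ligand_rmsd(tr2, ref)
  expect_equal(series2$per_replicate_rmsd[1, 2], 2, tolerance = 1e-8)

  # global rigid motion of whole frames is removed by superposition
  tr3 <- rigid_transform_trajectory(tr2)
  series3 <- ligand_rmsd(tr3, ref)
  expect_equal(series3$per_replicate_rmsd, series2$per_replicate_rmsd,
               tolerance = 1e-6)

  # atom mismatch is an explicit error
  trX <- template_trajectory(n_frames = 2)
  trX$atoms$name[nrow(trX$atoms)] <- "ZZ"
  expect_error(ligand_rmsd(trX, ref), "atoms")
})

test_that("median and MAD across replicates follow their definitions", {
  # four replicates with RMSD {1, 1, 1, 5} at one time point
  atoms <- template_trajectory(n_frames = 1)$atoms
  base <- template_trajectory(n_frames = 1)
  ref <- reference_frame(base, 1)
  mk <- function(shift) {
    tr <- template_trajectory(n_frames = 1)
    for (j in which(tr$atoms$role == "ligand")) {
      cols <- posepop:::xyz_cols(tr, j)
      tr$xyz[1, cols] <- tr$xyz[1, cols] + c(shift, 0, 0)
    }
    tr
  }
  series <- ligand_rmsd(structure(list(mk(1), mk(1), mk(1), mk(5)),
                                  class = "trajectory_set"), ref)
  expect_equal(series$median, 1, tolerance = 1e-8)
  expect_equal(series$mad, 0, tolerance = 1e-8)   # unscaled MAD of {1,1,1,5}
})

test_that("stability comparison ranks the quieter pose as more stable", {
  s <- list(times = 1:5, median = rep(1, 5))
  sa <- structure(c(s, list(per_replicate_rmsd = NULL, mad = rep(0, 5))),
                  class = "rmsd_series")
  sb <- sa
  # identical series: tie, difference 0
  cmp <- compare_pose_stability(sa, sb)
  expect_equal(cmp$difference, 0)
  expect_identical(cmp$more_stable, "tie")
  # B shifted up by 1 A: A more stable by exactly 1
  sb$median <- sb$median + 1
  cmp <- compare_pose_stability(sa, sb)
  expect_equal(cmp$difference, -1)
  expect_identical(cmp$more_stable, "A")
  # mismatched grids are an explicit error
  sb$times <- 2:6
  expect_error(compare_pose_stability(sa, sb), "time grids")

  # generated ensembles: doubling the pose-B noise makes pose A more stable
  ensA <- small_ensemble(pose_weight_A = 1, unbound_fraction = 0,
                         noise = 0.2, seed = 33, n_replicates = 2)
  ensB <- small_ensemble(pose_weight_A = 1, unbound_fraction = 0,
                         noise = 0.4, seed = 34, n_replicates = 2)
  ref <- reference_frame(template_trajectory("A", n_frames = 1), 1)
  cmp <- compare_pose_stability(ligand_rmsd(ensA, ref),
                                ligand_rmsd(ensB, ref))
  expect_identical(cmp$more_stable, "A")
})

test_that("the pooled pipeline is deterministic and labels poses by geometry", {
  trajs <- small_ensemble(pose_weight_A = 0.3, seed = 8)
  fit1 <- cluster_poses(trajs, t_start = 50, t_end = 100, seed = 8)
  fit2 <- cluster_poses(trajs, t_start = 50, t_end = 100, seed = 8)
  expect_identical(fit1$populations, fit2$populations)
  expect_identical(fit1$result$assignments, fit2$result$assignments)
  # with pose A generated as the minority, labelling must still call it A
  expect_lt(fit1$populations[["A"]], fit1$populations[["B"]])
  expect_equal(sum(fit1$populations), 1)

  # recovered populations track the generator ground truth per label
  gt_frac <- {
    bound_gt <- unlist(lapply(fit1$bound, function(tr) tr$ground_truth$pose))
    mean(bound_gt == "A")
  }
  expect_lt(abs(fit1$populations[["A"]] - gt_frac), 0.02)
})

test_that("trajectories round-trip through multi-model PDB", {
  tr <- template_trajectory(n_frames = 3)
  file <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, file)
  back <- read_trajectory_pdb(file)
  expect_identical(back$atoms$name, tr$atoms$name)
  expect_identical(back$atoms$role, tr$atoms$role)
  expect_equal(back$xyz, tr$xyz, tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(n_frames(back), 3L)
  unlink(file)
})
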