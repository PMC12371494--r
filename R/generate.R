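#' Specification for synthetic trajectory generation
#'
#' Describes an ensemble of replicate trajectories whose bound frames are
#' a two-component mixture of pose A and pose B of the thiourea scaffold.
#' The defaults mirror the production-MD conditions the pose analysis
#' assumes: eight independent replicates, frames on a 1 ns grid spanning
#' 200 ns, and a mixture of the two flip-related poses.
#'
#' The generator fixes the ensemble composition exactly at the requested
#' fractions (the numbers of pose-A, pose-B, and unbound frames are the
#' rounded products of the fractions and the frame count, allocated by a
#' seeded permutation).  Parameter-recovery tests therefore probe the
#' inference pipeline itself rather than binomial sampling noise in the
#' generator.
#'
#' @param n_replicates number of independent replicate runs.
#' @param n_frames_per_replicate frames per replicate.
#' @param frame_interval time between frames in ns.
#' @param pose_weight_A fraction of bound frames generated from pose A
#'   (pose B receives the complement).
#' @param positional_noise_sd isotropic Gaussian noise per ligand-atom
#'   coordinate, in Angstrom.
#' @param unbound_fraction fraction of frames in which the ligand is
#'   rigidly displaced out of the pocket (must be < 1).
#' @param unbound_offset margin in Angstrom beyond the 5 Angstrom
#'   bound-frame cutoff for displaced frames.
#' @param ar1_phi optional AR(1) autocorrelation coefficient for the
#'   positional noise (default 0, i.e. uncorrelated frames — the analysis
#'   subsamples at 1 ns precisely to decorrelate frames).
#' @param seed RNG seed.
#' @return An object of class `trajectory_gen_spec`.
#' @export
trajectory_gen_spec <- function(n_replicates = 8L,
                                n_frames_per_replicate = 200L,
                                frame_interval = 1,
                                pose_weight_A = 0.5,
                                positional_noise_sd = 0.3,
                                unbound_fraction = 0.1,
                                unbound_offset = 3,
                                ar1_phi = 0,
                                seed = 1L) {
  stopifnot(pose_weight_A >= 0, pose_weight_A <= 1,
            unbound_fraction >= 0, unbound_fraction < 1,
            positional_noise_sd >= 0, unbound_offset > 0,
            ar1_phi >= 0, ar1_phi < 1, frame_interval > 0)
  structure(
    list(n_replicates = as.integer(n_replicates),
         n_frames_per_replicate = as.integer(n_frames_per_replicate),
         frame_interval = frame_interval,
         pose_weight_A = pose_weight_A,
         positional_noise_sd = positional_noise_sd,
         unbound_fraction = unbound_fraction,
         unbound_offset = unbound_offset,
         ar1_phi = ar1_phi,
         seed = as.integer(seed)),
    class = "trajectory_gen_spec"
  )
}

#' Generate a synthetic trajectory ensemble with known pose labels
#'
#' Each frame places the ligand scaffold on the pose-A or pose-B template
#' plus isotropic Gaussian noise; pocket anchors stay fixed.  Unbound
#' frames additionally translate the ligand rigidly along the
#' pocket-exit direction so that the sulfur-to-C433-N distance exceeds
#' `5 + unbound_offset` Angstrom.  Pose labels and bound flags are stored
#' per frame as ground truth.
#'
#' @param spec a [trajectory_gen_spec()].
#' @param topology pocket anchors from [make_pocket_topology()].
#' @return An object of class `trajectory_set`: a list of [trajectory()]
#'   objects (one per replicate), each carrying a `ground_truth`
#'   `data.frame` with columns `pose` and `bound`.
#' @examples
#' spec <- trajectory_gen_spec(n_replicates = 2, n_frames_per_replicate = 50)
#' trajs <- generate_trajectory(spec, make_pocket_topology())
#' trajs[[1]]$ground_truth[1:5, ]
#' @export
generate_trajectory <- function(spec, topology = make_pocket_topology()) {
  if (spec$n_replicates < 1L || spec$n_frames_per_replicate < 1L) {
    stop("degenerate generation spec: need at least one replicate and one frame")
  }
  tmplA <- pose_template("A")
  tmplB <- pose_template("B")
  atoms <- rbind(
    topology[, c("name", "resid", "elety", "role", "donor", "acceptor")],
    cbind(tmplA[, c("name", "elety", "role", "donor", "acceptor")],
          resid = "LIG")[, c("name", "resid", "elety", "role", "donor", "acceptor")]
  )
  n_pocket <- nrow(topology)
  n_lig <- nrow(tmplA)
  n_total <- spec$n_replicates * spec$n_frames_per_replicate

  # exit direction: from the C433 backbone N through the exocyclic sulfur
  s0 <- as.numeric(tmplA[tmplA$name == "S_EXO", c("x", "y", "z")])
  n0 <- as.numeric(topology[topology$name == "C433_N", c("x", "y", "z")])
  u <- (s0 - n0) / sqrt(sum((s0 - n0)^2))
  d0 <- sqrt(sum((s0 - n0)^2))
  shift <- (5 + spec$unbound_offset + 1 - d0) * u

  with_seed(spec$seed, {
    n_unbound <- round(spec$unbound_fraction * n_total)
    n_bound <- n_total - n_unbound
    n_a <- round(spec$pose_weight_A * n_bound)
    pose <- sample(rep(c("A", "B"), c(n_a, n_bound - n_a)))
    bound <- sample(rep(c(TRUE, FALSE), c(n_bound, n_unbound)))
    pose_all <- character(n_total)
    pose_all[bound] <- pose
    pose_all[!bound] <- sample(c("A", "B"), n_unbound, replace = TRUE)

    pocket_xyz <- as.vector(t(as.matrix(topology[, c("x", "y", "z")])))
    out <- vector("list", spec$n_replicates)
    idx <- 0L
    for (r in seq_len(spec$n_replicates)) {
      nf <- spec$n_frames_per_replicate
      xyz <- matrix(0, nrow = nf, ncol = 3L * (n_pocket + n_lig))
      eps_prev <- matrix(0, n_lig, 3L)
      for (f in seq_len(nf)) {
        idx <- idx + 1L
        tmpl <- if (pose_all[idx] == "A") tmplA else tmplB
        co <- as.matrix(tmpl[, c("x", "y", "z")])
        eps <- matrix(stats::rnorm(3L * n_lig, sd = spec$positional_noise_sd),
                      n_lig, 3L)
        if (spec$ar1_phi > 0 && f > 1L) {
          eps <- spec$ar1_phi * eps_prev + sqrt(1 - spec$ar1_phi^2) * eps
        }
        eps_prev <- eps
        co <- co + eps
        if (!bound[idx]) co <- sweep(co, 2L, shift, "+")
        xyz[f, ] <- c(pocket_xyz, as.vector(t(co)))
      }
      i0 <- (r - 1L) * nf
      gt <- data.frame(pose = pose_all[i0 + seq_len(nf)],
                       bound = bound[i0 + seq_len(nf)],
                       stringsAsFactors = FALSE)
      out[[r]] <- trajectory(atoms, xyz,
                             times = seq_len(nf) * spec$frame_interval,
                             replicate_id = paste0("rep", r),
                             ground_truth = gt)
    }
    structure(out, class = "trajectory_set")
  })
}

#' Specification for synthetic dose-response generation
#'
#' @param true_ic50 generating IC50 in M.
#' @param hill_slope Hill coefficient (default 1).
#' @param top,bottom upper and lower signal plateaus (arbitrary units).
#' @param concentrations tested concentrations in M, strictly positive and
#'   sorted ascending; default ten half-log dilutions bracketing
#'   `true_ic50`.
#' @param noise_cv multiplicative Gaussian noise (coefficient of
#'   variation) applied to the concentration-dependent signal fraction.
#' @param n_replicates technical replicates per concentration.
#' @param compound,protein,assay panel labels.
#' @param seed RNG seed.
#' @return An object of class `assay_gen_spec`.
#' @export
assay_gen_spec <- function(true_ic50 = 1e-5, hill_slope = 1,
                           top = 100, bottom = 0,
                           concentrations = NULL,
                           noise_cv = 0.02, n_replicates = 4L,
                           compound = "CPD1", protein = "DF2",
                           assay = "FP", seed = 1L) {
  if (is.null(concentrations)) {
    concentrations <- true_ic50 * 10^seq(-2.25, 2.25, by = 0.5)
  }
  stopifnot(all(concentrations > 0), !is.unsorted(concentrations, strictly = TRUE),
            top > bottom, true_ic50 > 0, noise_cv >= 0, n_replicates >= 1)
  structure(
    list(true_ic50 = true_ic50, hill_slope = hill_slope, top = top,
         bottom = bottom, concentrations = concentrations,
         noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
         compound = compound, protein = protein, assay = assay,
         seed = as.integer(seed)),
    class = "assay_gen_spec"
  )
}

#' Generate a synthetic competition dose-response panel
#'
#' Signals follow a four-parameter logistic,
#' `signal(c) = bottom + (top - bottom) / (1 + (c / IC50)^hill) * (1 + e)`
#' with `e ~ N(0, noise_cv)` drawn independently per replicate and
#' concentration.
#'
#' @param spec an [assay_gen_spec()].
#' @return A `data.frame` with columns `compound`, `protein`, `assay`,
#'   `conc_M`, `signal`, `replicate`.
#' @examples
#' panel <- generate_dose_response(assay_gen_spec(noise_cv = 0))
#' head(panel)
#' @export
generate_dose_response <- function(spec) {
  with_seed(spec$seed, {
    grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                        conc_M = spec$concentrations)
    frac <- 1 / (1 + (grid$conc_M / spec$true_ic50)^spec$hill_slope)
    eps <- stats::rnorm(nrow(grid), sd = spec$noise_cv)
    data.frame(
      compound = spec$compound, protein = spec$protein, assay = spec$assay,
      conc_M = grid$conc_M,
      signal = spec$bottom + (spec$top - spec$bottom) * frac * (1 + eps),
      replicate = grid$replicate,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate synthetic docking poses with planted pharmacophore binders
#'
#' Emits `n` ligand poses with docking-energy annotations.  Exactly
#' `planted_binders` of them are built on the pose-A template with small
#' positional noise, so by construction they donate the crucial hydrogen
#' bond to the C433 backbone carbonyl and contact Y418, D422, and the
#' structural water.  The remaining poses are rotated and displaced out of
#' the hydrogen-bonding geometry.  Planted binders receive more favourable
#' (more negative) energies on both terms.
#'
#' @param n number of poses.
#' @param topology pocket anchors from [make_pocket_topology()].
#' @param planted_binders number of poses satisfying the pharmacophore
#'   (must be `<= n`).
#' @param seed RNG seed.
#' @return A list with elements `poses` (list of `dock_pose` objects),
#'   `scores` (`data.frame` with `pose_id`, `E_total`, `Delec`), and
#'   `ground_truth` (`data.frame` with `pose_id`, `binder`).
#' @export
generate_docking_poses <- function(n, topology = make_pocket_topology(),
                                   planted_binders = 0L, seed = 1L) {
  n <- as.integer(n)
  planted_binders <- as.integer(planted_binders)
  if (planted_binders > n) stop("planted_binders must not exceed n")
  if (n == 0L) {
    return(list(poses = list(),
                scores = data.frame(pose_id = character(), E_total = numeric(),
                                    Delec = numeric(), stringsAsFactors = FALSE),
                ground_truth = data.frame(pose_id = character(),
                                          binder = logical(),
                                          stringsAsFactors = FALSE)))
  }
  tmpl <- pose_template("A")
  with_seed(seed, {
    binder <- sample(rep(c(TRUE, FALSE), c(planted_binders, n - planted_binders)))
    ids <- sprintf("pose_%03d", seq_len(n))
    poses <- vector("list", n)
    e_total <- numeric(n)
    delec <- numeric(n)
    for (i in seq_len(n)) {
      at <- tmpl
      co <- as.matrix(at[, c("x", "y", "z")])
      if (binder[i]) {
        co <- co + matrix(stats::rnorm(length(co), sd = 0.15), ncol = 3L)
        e_total[i] <- stats::rnorm(1, -9, 0.5)
        delec[i] <- stats::rnorm(1, -6, 0.5)
      } else {
        # rotate about z and push the scaffold out of hydrogen-bond range
        th <- stats::runif(1, 0, 2 * pi)
        rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                      3L, 3L, byrow = TRUE)
        co <- co %*% t(rot)
        co <- sweep(co, 2L, c(6, 0, 6) + stats::rnorm(3, sd = 0.5), "+")
        co <- co + matrix(stats::rnorm(length(co), sd = 0.15), ncol = 3L)
        e_total[i] <- stats::rnorm(1, -5, 1)
        delec[i] <- stats::rnorm(1, -2, 1)
      }
      at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
      poses[[i]] <- dock_pose(ids[i], at, e_total = e_total[i], delec = delec[i])
    }
    list(poses = poses,
         scores = data.frame(pose_id = ids, E_total = e_total, Delec = delec,
                             stringsAsFactors = FALSE),
         ground_truth = data.frame(pose_id = ids, binder = binder,
                                   stringsAsFactors = FALSE))
  })
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param x a `trajectory_set` or the result of [generate_docking_poses()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ground_truth <- function(x, file) {
  if (inherits(x, "trajectory_set")) {
    gt <- lapply(x, function(tr) {
      cbind(replicate_id = tr$replicate_id, frame = seq_len(n_frames(tr)),
            tr$ground_truth)
    })
    gt <- do.call(rbind, gt)
  } else {
    gt <- x$ground_truth
  }
  jsonlite::write_json(gt, file, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
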