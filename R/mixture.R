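# Full-covariance Gaussian mixture by expectation-maximization on the
# 2-D principal-component projection.  Small and self-contained: k-means++
# seeding, multiple restarts, log-likelihood tolerance 1e-6.

log_mvn_density <- function(x, mean, sigma) {
  # x: n x d.  Cholesky-based log density; sigma is ridge-regularised by
  # the caller, so chol() is expected to succeed.
  d <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
      dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
  }
  centers
}

em_gmm_once <- function(x, k, tol = 1e-6, max_iter = 500L, ridge = 1e-8) {
  n <- nrow(x); d <- ncol(x)
  centers <- kmeanspp_centers(x, k)
  # hard initial assignment to nearest seed
  dist2 <- sapply(seq_len(k), function(j) {
    rowSums((x - matrix(centers[j, ], n, d, byrow = TRUE))^2)
  })
  assign0 <- max.col(-dist2)
  w <- tabulate(assign0, k) / n
  mu <- centers
  sigma <- vector("list", k)
  for (j in seq_len(k)) {
    xj <- x[assign0 == j, , drop = FALSE]
    sigma[[j]] <- if (nrow(xj) > d) stats::cov(xj) + diag(ridge, d) else diag(1, d)
  }
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step
    logp <- sapply(seq_len(k), function(j) {
      log(pmax(w[j], 1e-300)) + log_mvn_density(x, mu[j, ], sigma[[j]])
    })
    m <- apply(logp, 1L, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    resp <- exp(logp - lse)
    # M-step
    nk <- colSums(resp)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
      xc <- x - matrix(mu[j, ], n, d, byrow = TRUE)
      sigma[[j]] <- crossprod(xc * sqrt(resp[, j])) / nk[j] + diag(ridge, d)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, covariances = sigma, log_lik = ll_old,
       converged = converged, n_iter = it)
}

#' Fit a full-covariance Gaussian mixture to the 2-D projection
#'
#' Expectation-maximization with full covariance matrices, k-means++
#' seeding, `n_restarts` seeded restarts (best log-likelihood kept), and a
#' convergence tolerance of 1e-6 on the log-likelihood.  Frames receive
#' hard assignments by maximum responsibility; cluster populations are the
#' assignment fractions.  A fit that fails to converge within `max_iter`
#' iterations is returned with `converged = FALSE`, never silently.
#'
#' Clusters are ordered by decreasing mixture weight; scientific pose
#' labels (A/B) are attached later from centroid geometry by
#' [label_clusters()] — never from fit order.
#'
#' @param projection a `pca_projection` from [project_2d()] (or an n x 2
#'   matrix of coordinates).
#' @param k number of mixture components (default 2, the two flip-related
#'   poses).
#' @param seed RNG seed for seeding and restarts.
#' @param n_restarts number of EM restarts (default 10).
#' @param max_iter EM iteration cap per restart.
#' @param tol log-likelihood convergence tolerance.
#' @return An object of class `pose_cluster_result`: list with `weights`,
#'   `means`, `covariances`, `assignments` (integer per frame),
#'   `populations`, `log_lik`, `converged`, `explained_variance`,
#'   `replicate_id`, `frame_index`, `scores`, and (after
#'   [label_clusters()]) `pose_labels`.
#' @export
fit_mixture <- function(projection, k = 2L, seed = 1L, n_restarts = 10L,
                        max_iter = 500L, tol = 1e-6) {
  x <- if (inherits(projection, "pca_projection")) projection$scores else as.matrix(projection)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (nrow(x) < 10L * k) {
    stop("need at least 10 frames per mixture component (have ", nrow(x),
         " frames for k = ", k, ")")
  }
  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) em_gmm_once(x, k, tol, max_iter))
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "log_lik"))]]
  if (!best$converged) {
    warning("EM did not converge within ", max_iter,
            " iterations; result flagged (converged = FALSE)")
  }
  # deterministic component order: decreasing weight, ties by mean PC1
  ord <- order(-best$weights, best$means[, 1L])
  w <- best$weights[ord]
  mu <- best$means[ord, , drop = FALSE]
  sig <- best$covariances[ord]
  logp <- sapply(seq_len(k), function(j) {
    log(pmax(w[j], 1e-300)) + log_mvn_density(x, mu[j, ], sig[[j]])
  })
  assignments <- max.col(logp, ties.method = "first")
  populations <- tabulate(assignments, k) / nrow(x)
  structure(
    list(weights = w, means = mu, covariances = sig,
         assignments = assignments, populations = populations,
         log_lik = best$log_lik, converged = best$converged,
         scores = x,
         explained_variance = if (inherits(projection, "pca_projection"))
           projection$explained_variance else NULL,
         replicate_id = if (inherits(projection, "pca_projection"))
           projection$replicate_id else NULL,
         frame_index = if (inherits(projection, "pca_projection"))
           projection$frame_index else NULL),
    class = "pose_cluster_result"
  )
}

#' @export
print.pose_cluster_result <- function(x, ...) {
  k <- length(x$weights)
  cat("Gaussian-mixture pose clustering (k = ", k, ", ",
      nrow(x$scores), " bound frames)\n", sep = "")
  lab <- if (!is.null(x$pose_labels)) x$pose_labels else paste0("cluster ", seq_len(k))
  for (j in seq_len(k)) {
    cat(sprintf("  %s: population %.1f%%, mean PC = (%.2f, %.2f)\n",
                lab[j], 100 * x$populations[j], x$means[j, 1], x$means[j, 2]))
  }
  if (!x$converged) cat("  [EM flagged: not converged]\n")
  invisible(x)
}

#' Representative (centroid) frame of each cluster
#'
#' For each cluster, returns the assigned frame whose projection lies
#' closest (Euclidean) to the cluster mean in PC space.  Ties are broken
#' toward the earliest frame in `(replicate_id, frame_index)` order.
#' Empty clusters are flagged with `NA` references.
#'
#' @param result a `pose_cluster_result` from [fit_mixture()].
#' @return A `data.frame` with one row per cluster: `cluster`,
#'   `replicate_id`, `frame_index`, `row` (row in the pooled projection),
#'   and `distance` to the cluster mean.
#' @export
centroid_frames <- function(result) {
  k <- length(result$weights)
  out <- data.frame(cluster = seq_len(k), replicate_id = NA_character_,
                    frame_index = NA_integer_, row = NA_integer_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    rows <- which(result$assignments == j)
    if (length(rows) == 0L) {
      warning("cluster ", j, " is empty; centroid flagged as NA")
      next
    }
    d <- sqrt(rowSums((result$scores[rows, , drop = FALSE] -
                         matrix(result$means[j, ], length(rows), 2L,
                                byrow = TRUE))^2))
    # which.min returns the first minimum; rows are in pooled
    # (replicate_id, frame_index) order, so ties break toward the earliest
    best <- rows[which.min(d)]
    out$row[j] <- best
    out$distance[j] <- min(d)
    if (!is.null(result$replicate_id)) out$replicate_id[j] <- result$replicate_id[best]
    if (!is.null(result$frame_index)) out$frame_index[j] <- result$frame_index[best]
  }
  out
}
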