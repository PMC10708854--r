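#' Supervised prototype stage (LVQ-like, self-determined cluster count)
#'
#' Incremental prototype allocation in the standardised joint
#' (input, target) space.  Points are presented in dataset order; a
#' point farther than `radius_frac` times the diameter of the
#' standardised cloud from every existing prototype spawns a new
#' prototype at that point, otherwise the nearest prototype moves toward
#' it by `lvq_rate`.  Supervision enters through the target coordinate,
#' so prototypes separate regions of differing response even when the
#' inputs overlap.  The number of prototypes - and hence the number of
#' fuzzy rules downstream - is therefore emergent, not user-fixed.
#'
#' @param X numeric input matrix (n x q).
#' @param y numeric target vector (length n).
#' @param radius_frac allocation radius as a fraction of the diameter of
#'   the standardised joint cloud, in (0, 1].
#' @param lvq_rate prototype step size toward an absorbed point.
#' @param shuffle present points in random order (default FALSE, so the
#'   result is deterministic without a seed).
#' @param seed seed for the optional shuffle.
#' @return Numeric matrix (c x q) of prototype centres in the original
#'   input units (target coordinate dropped); the emergent count `c` is
#'   `nrow()` of the result.
#' @export
supervised_prototype_stage <- function(X, y, radius_frac = 0.3,
                                       lvq_rate = 0.05, shuffle = FALSE,
                                       seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stop("at least one sample is required", call. = FALSE)
  stopifnot(length(y) == n, radius_frac > 0, radius_frac <= 1)
  J <- cbind(X, y)
  ctr <- colMeans(J)
  scl <- apply(J, 2, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  Z <- sweep(sweep(J, 2, ctr), 2, scl, "/")
  # diameter of the standardised cloud: bounding-box diagonal
  rng <- apply(Z, 2, function(v) diff(range(v)))
  diam <- sqrt(sum(rng^2))
  if (diam < .Machine$double.eps) diam <- 1
  radius <- radius_frac * diam
  order_idx <- seq_len(n)
  if (shuffle) {
    old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(as.integer(seed))
    order_idx <- sample(n)
  }
  protos <- Z[order_idx[1], , drop = FALSE]
  for (k in order_idx[-1]) {
    z <- Z[k, ]
    d2 <- colSums((t(protos) - z)^2)
    i <- which.min(d2)
    if (sqrt(d2[i]) > radius) {
      protos <- rbind(protos, z)
    } else {
      protos[i, ] <- protos[i, ] + lvq_rate * (z - protos[i, ])
    }
  }
  q <- ncol(X)
  centers <- sweep(sweep(protos[, seq_len(q), drop = FALSE], 2,
                         scl[seq_len(q)], "*"), 2, ctr[seq_len(q)], "+")
  colnames(centers) <- colnames(X)
  rownames(centers) <- NULL
  centers
}

#' Fuzzy c-means refinement from given initial centres
#'
#' Standard FCM alternating optimisation: memberships
#' `u_ik = 1 / sum_j (d_ik/d_jk)^(2/(m-1))`, centres as the
#' membership^m-weighted means.  Iteration stops when the objective
#' `J = sum_ik u_ik^m d_ik^2` improves by less than `tol` or at
#' `max_iter`.  Points coinciding with a centre receive crisp
#' membership for that centre (the usual limit convention).
#'
#' @param X numeric data matrix (n x q).
#' @param centers_init numeric initial centre matrix (c x q), `c <= n`.
#' @param m fuzzifier exponent, `> 1` (default 2).
#' @param tol objective improvement tolerance.
#' @param max_iter iteration cap.
#' @return A `fuzzy_partition`: list with `centers` (c x q), `U`
#'   (c x n, columns sum to 1), `fuzzifier`, `objective` (per-iteration
#'   values), `converged`, and `sigma_init = NULL` (see
#'   [init_spreads()]).
#' @export
fcm_refine <- function(X, centers_init, m = 2, tol = 1e-8, max_iter = 200) {
  X <- as.matrix(X)
  C <- as.matrix(centers_init)
  n <- nrow(X); cc <- nrow(C)
  stopifnot(cc >= 1, cc <= n, m > 1)
  # collapse guard: perturb duplicated initial centres
  if (cc > 1) {
    d <- as.matrix(stats::dist(C))
    diag(d) <- Inf
    if (min(d) < 1e-12) {
      warning("duplicate initial centers perturbed")
      C <- C + matrix(stats::rnorm(length(C), 0, 1e-6 + 1e-6 * stats::sd(X)),
                      nrow = cc)
    }
  }
  memberships <- function(C) {
    # d2[i, k] = squared distance centre i to point k
    d2 <- matrix(0, cc, n)
    for (i in seq_len(cc)) d2[i, ] <- colSums((t(X) - C[i, ])^2)
    U <- matrix(0, cc, n)
    expo <- 1 / (m - 1)
    for (k in seq_len(n)) {
      zero <- d2[, k] < .Machine$double.eps
      if (any(zero)) {
        U[zero, k] <- 1 / sum(zero)
      } else {
        inv <- (1 / d2[, k])^expo
        U[, k] <- inv / sum(inv)
      }
    }
    list(U = U, d2 = d2)
  }
  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mem <- memberships(C)
    U <- mem$U
    obj[it] <- sum(U^m * mem$d2)
    Um <- U^m
    wsum <- rowSums(Um)
    C_new <- (Um %*% X) / wsum
    # keep a collapsed (zero-membership) centre where it was
    bad <- wsum < .Machine$double.eps
    if (any(bad)) C_new[bad, ] <- C[bad, ]
    C <- C_new
    if (it > 1 && abs(obj[it - 1] - obj[it]) < tol) {
      converged <- TRUE
      break
    }
  }
  mem <- memberships(C)
  structure(list(centers = C, U = mem$U, fuzzifier = m,
                 objective = obj, converged = converged,
                 sigma_init = NULL),
            class = "fuzzy_partition")
}

#' Membership-weighted initial spreads
#'
#' For each cluster i and coordinate j,
#' `sigma_ij = sqrt( sum_k u_ik (x_kj - c_ij)^2 / sum_k u_ik )`:
#' the square root of the membership-weighted second moment about the
#' cluster centre.  With crisp memberships this is the within-cluster
#' population standard deviation.  Spreads are floored at `1e-3` times
#' the coordinate-wise data range so that degenerate (point-mass)
#' clusters cannot produce zero-width membership functions.
#'
#' @param X numeric data matrix (n x q).
#' @param part a `fuzzy_partition` from [fcm_refine()].
#' @return The partition with `sigma_init` (c x q matrix) filled in.
#' @export
init_spreads <- function(X, part) {
  X <- as.matrix(X)
  stopifnot(inherits(part, "fuzzy_partition"))
  U <- part$U
  C <- part$centers
  cc <- nrow(C); q <- ncol(C)
  tot <- rowSums(U)
  if (any(tot <= 0)) {
    stop(sprintf("cluster %d has zero total membership",
                 which(tot <= 0)[1]), call. = FALSE)
  }
  sigma <- matrix(0, cc, q)
  for (i in seq_len(cc)) {
    dev2 <- sweep(X, 2, C[i, ])^2
    sigma[i, ] <- sqrt(colSums(U[i, ] * dev2) / tot[i])
  }
  floor_v <- 1e-3 * apply(X, 2, function(v) diff(range(v)))
  floor_v[floor_v < .Machine$double.eps] <- 1e-6
  sigma <- pmax(sigma, matrix(floor_v, cc, q, byrow = TRUE))
  part$sigma_init <- sigma
  part
}

#' Full clustering initialisation for the neuro-fuzzy regressor
#'
#' Chains the supervised prototype stage (which determines the cluster
#' count), FCM refinement of the centres, and spread initialisation.
#' The downstream network gets one fuzzy rule per cluster.
#'
#' @inheritParams supervised_prototype_stage
#' @inheritParams fcm_refine
#' @param n_clusters optional manual override of the emergent cluster
#'   count (mainly for tests); when given, the prototype stage is
#'   replaced by seeded k-means-style sampling of initial centres.
#' @return A `fuzzy_partition` with `sigma_init` filled in, all in the
#'   original units of `X`.
#' @export
cluster_init <- function(X, y, radius_frac = 0.3, lvq_rate = 0.05,
                         m = 2, shuffle = FALSE, seed = 1,
                         n_clusters = NULL) {
  X <- as.matrix(X)
  if (is.null(n_clusters)) {
    centers0 <- supervised_prototype_stage(X, y, radius_frac = radius_frac,
                                           lvq_rate = lvq_rate,
                                           shuffle = shuffle, seed = seed)
  } else {
    stopifnot(n_clusters >= 1, n_clusters <= nrow(X))
    old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(as.integer(seed))
    centers0 <- X[sample(nrow(X), n_clusters), , drop = FALSE]
  }
  part <- fcm_refine(X, centers0, m = m)
  init_spreads(X, part)
}
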