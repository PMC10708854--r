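test_that("the prototype stage self-determines a sensible cluster count", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
             matrix(rnorm(40, 5, 0.1), ncol = 2))
  y <- c(rep(0, 20), rep(10, 20))
  two <- supervised_prototype_stage(X, y, radius_frac = 0.3)
  expect_equal(nrow(two), 2)
  # one centre per blob
  d_lo <- apply(two, 1, function(p) sqrt(sum((p - c(0, 0))^2)))
  d_hi <- apply(two, 1, function(p) sqrt(sum((p - c(5, 5))^2)))
  expect_true(any(d_lo < 1) && any(d_hi < 1))
  expect_equal(nrow(supervised_prototype_stage(X, y, radius_frac = 1)), 1)
  one_pt <- supervised_prototype_stage(matrix(c(2, 3), 1), 5)
  expect_equal(unname(one_pt), matrix(c(2, 3), 1), tolerance = 1e-12)
  expect_error(supervised_prototype_stage(X[0, , drop = FALSE], numeric(0)),
               "at least one")
})

test_that("cluster count is non-increasing in the allocation radius", {
  ds <- generate_dataset(seed = 2)
  X <- feature_matrix(ds, "mean", bands = c(1, 5, 9, 12))
  counts <- sapply(c(0.1, 0.15, 0.2, 0.3, 0.5, 0.8, 1),
                   function(r) nrow(supervised_prototype_stage(X, ds$tvc,
                                                               radius_frac = r)))
  expect_true(all(diff(counts) <= 0))
})

test_that("FCM refinement satisfies the fixed-point identities", {
  ds <- generate_dataset(n_per_temp = 6, seed = 9)
  X <- feature_matrix(ds, "mean", bands = c(5, 9, 12))
  part <- fcm_refine(X, X[c(2, 15, 28), ])
  expect_equal(colSums(part$U), rep(1, nrow(X)), tolerance = 1e-9)
  expect_true(all(diff(part$objective) <= 1e-8))
  expect_true(part$converged)
  # membership formula at the solution
  d2 <- sapply(seq_len(3), function(i) colSums((t(X) - part$centers[i, ])^2))
  U_check <- t(1 / (d2 * rowSums(1 / d2)))
  expect_equal(part$U, U_check, tolerance = 1e-9, ignore_attr = TRUE)
  # c = 1 gives crisp membership everywhere
  p1 <- fcm_refine(X, X[5, , drop = FALSE])
  expect_true(all(p1$U == 1))
  # points coincident with centres get full membership (limit rule)
  p2 <- fcm_refine(rbind(c(0, 0), c(10, 10)), rbind(c(0, 0), c(10, 10)))
  expect_equal(p2$U, diag(2), ignore_attr = TRUE)
})

test_that("FCM objective matches an independent alternating-optimisation oracle", {
  set.seed(3)
  X <- matrix(rnorm(12), nrow = 6)
  init <- X[c(1, 4), ]
  mine <- fcm_refine(X, init, tol = 1e-12, max_iter = 500)
  oracle <- oracle_fcm_objective(X, init, iters = 500)
  expect_equal(tail(mine$objective, 1), oracle, tolerance = 1e-8)
  # and against the established implementation
  skip_if_not_installed("e1071")
  cm <- e1071::cmeans(X, centers = init, m = 2, method = "cmeans",
                      iter.max = 500)
  expect_equal(tail(mine$objective, 1), tail(cm$withinerror, 1) * nrow(X),
               tolerance = 1e-6)
})

test_that("spread initialisation is the membership-weighted second moment", {
  set.seed(4)
  X <- matrix(rnorm(20), nrow = 10)
  U <- matrix(runif(20), nrow = 2)
  U <- sweep(U, 2, colSums(U), "/")
  C <- rbind(colMeans(X[1:5, ]), colMeans(X[6:10, ]))
  part <- structure(list(centers = C, U = U, fuzzifier = 2,
                         sigma_init = NULL), class = "fuzzy_partition")
  got <- init_spreads(X, part)$sigma_init
  want <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    want[i, j] <- sqrt(sum(U[i, ] * (X[, j] - C[i, j])^2) / sum(U[i, ]))
  }
  expect_equal(got, want, tolerance = 1e-12)

  # crisp memberships reduce to within-cluster population sd
  Uc <- rbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  partc <- structure(list(centers = C, U = Uc, fuzzifier = 2,
                          sigma_init = NULL), class = "fuzzy_partition")
  gotc <- init_spreads(X, partc)$sigma_init
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(gotc[1, 1], pop_sd(X[1:5, 1]), tolerance = 1e-12)
  expect_equal(gotc[2, 2], pop_sd(X[6:10, 2]), tolerance = 1e-12)

  # identical points trigger the spread floor, zero membership errors
  Xz <- matrix(1, 4, 2)
  pz <- fcm_refine(Xz, Xz[1, , drop = FALSE])
  sz <- init_spreads(Xz, pz)$sigma_init
  expect_true(all(sz > 0))
  bad <- structure(list(centers = C, U = matrix(0, 2, 10), fuzzifier = 2,
                        sigma_init = NULL), class = "fuzzy_partition")
  expect_error(init_spreads(X, bad), "zero total membership")
})

test_that("end-to-end initialisation yields one rule per cluster", {
  ds <- generate_dataset(n_per_temp = 6, seed = 10)
  X <- feature_matrix(ds, "mean", bands = c(1, 9, 12))
  part <- cluster_init(X, ds$tvc)
  model <- cagfinn_fit(X, ds$tvc, part,
                       control = cagfinn_control(max_epochs = 5))
  expect_equal(model$n_rules, nrow(part$centers))
  expect_true(all(part$sigma_init > 0))
})
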