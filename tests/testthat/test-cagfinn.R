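test_that("asymmetric membership peaks at the centre and records sides", {
  mf <- asym_membership(1, center = 1, sigma_left = 0.3, sigma_right = 0.7)
  expect_equal(mf$degree, 1.0)
  expect_equal(mf$side, "right")  # x == c counts as right by convention
  # symmetric spreads s reduce to a plain Gaussian of spread 2s
  s <- 0.4
  xs <- seq(-2, 2, length.out = 21)
  got <- asym_membership(xs, 0.5, s, s)$degree
  expect_equal(got, exp(-(xs - 0.5)^2 / (2 * (2 * s)^2)), tolerance = 1e-12)
  # one total spread to the right of the centre
  m2 <- asym_membership(1 + 1.0, center = 1, sigma_left = 0.5,
                        sigma_right = 0.5)
  expect_equal(m2$degree, exp(-0.5), tolerance = 1e-12)
  expect_equal(m2$side, "right")
  expect_equal(asym_membership(0.2, 1, 0.5, 0.5)$side, "left")
  expect_error(asym_membership(Inf, 1, 0.5, 0.5), "finite")
})

test_that("rule strengths normalise to one and match a brute-force oracle", {
  set.seed(6)
  q <- 3; cc <- 4
  model <- cagfinn_model(
    centers = matrix(rnorm(cc * q), cc),
    sigma_left = matrix(runif(cc * q, 0.2, 0.8), cc),
    sigma_right = matrix(runif(cc * q, 0.2, 0.8), cc),
    consequents = matrix(rnorm(cc * (q + 1)), cc))
  for (rep in 1:20) {
    x <- rnorm(q)
    fr <- fire_rules(model, x)
    expect_equal(sum(fr$Rbar), 1, tolerance = 1e-12)
    b <- model$sigma_left + model$sigma_right
    R_oracle <- sapply(seq_len(cc), function(i) {
      prod(exp(-(x - model$centers[i, ])^2 / (2 * b[i, ]^2)))
    })
    expect_equal(fr$R, R_oracle, tolerance = 1e-12)
    expect_equal(fr$Rbar, R_oracle / sum(R_oracle), tolerance = 1e-12)
  }
  # single rule always fires with full normalised strength
  one <- cagfinn_model(matrix(0, 1, 2), matrix(1, 1, 2), matrix(1, 1, 2),
                       matrix(c(0, 0, 3), 1))
  expect_equal(fire_rules(one, c(9, -9))$Rbar, 1)
  # input at a rule's centre fires it at full strength
  fr_c <- fire_rules(model, model$centers[2, ])
  expect_equal(fr_c$R[2], 1, tolerance = 1e-12)
  expect_error(fire_rules(model, c(1, 2)), "dimension")
})

test_that("underflow of all rule strengths falls back to uniform weights", {
  tiny <- cagfinn_model(matrix(c(0, 1e6), 2, 1),
                        matrix(1e-3, 2, 1), matrix(1e-3, 2, 1),
                        cbind(c(0, 0), c(5, 7)))
  fr <- fire_rules(tiny, 5e5)
  expect_equal(fr$Rbar, c(0.5, 0.5))
  expect_equal(predict(tiny, 5e5), mean(c(5, 7)))
})

test_that("prediction is the normalised affine mixture", {
  # all-zero linear weights with common bias: output is the bias everywhere
  cc <- 3
  model <- cagfinn_model(matrix(rnorm(cc * 2), cc),
                         matrix(0.5, cc, 2), matrix(0.5, cc, 2),
                         cbind(matrix(0, cc, 2), rep(4.4, cc)))
  expect_equal(predict(model, matrix(rnorm(20), ncol = 2)),
               rep(4.4, 10), tolerance = 1e-12)
  # single rule, q = 1: plain affine evaluation
  aff <- cagfinn_model(matrix(0, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1),
                       matrix(c(2, 1), 1))
  expect_equal(predict(aff, 3), 7)
})

test_that("the symmetric-spread limit equals a standard Gaussian TSK system", {
  set.seed(7)
  cc <- 3; q <- 2
  centers <- matrix(rnorm(cc * q), cc)
  spreads <- matrix(runif(cc * q, 0.5, 1.5), cc)   # total spreads
  weights <- matrix(rnorm(cc * (q + 1)), cc)
  model <- cagfinn_model(centers, spreads / 2, spreads / 2, weights)
  X <- matrix(rnorm(60), ncol = q)
  expect_lt(max(abs(predict(model, X) -
                      oracle_tsk_forward(X, centers, spreads, weights))),
            1e-10)
})

test_that("consequent-only training reproduces batch least squares", {
  d <- generate_tsk_dataset(120, toy_rules(), noise_sd = 0.3, seed = 13)
  part <- toy_partition(120)
  ctrl <- cagfinn_control(max_epochs = 3, gd_rate = 0, rls_forgetting = 1,
                          rls_init_cov = 1e8, scale_inputs = FALSE,
                          keep_best = FALSE)
  m <- cagfinn_fit(d$X, d$y, part, control = ctrl)
  Phi <- t(sapply(seq_len(nrow(d$X)), function(k) {
    fr <- fire_rules(m, d$X[k, ])
    as.numeric(t(outer(fr$Rbar, c(d$X[k, ], 1))))
  }))
  w_ols <- qr.solve(Phi, d$y)
  expect_equal(as.numeric(t(m$consequents)), unname(w_ols),
               tolerance = 1e-6)
})

test_that("premise gradients match central finite differences", {
  model <- cagfinn_model(
    centers = rbind(c(0.2, -0.1), c(0.9, -1.2)),
    sigma_left = rbind(c(0.4, 0.6), c(0.3, 0.5)),
    sigma_right = rbind(c(0.6, 0.4), c(0.45, 0.35)),
    consequents = rbind(c(1, -1, 0.5), c(-0.3, 0.2, 2)))
  x <- c(0.3, -0.5); y <- 1.1
  g <- msitvc:::.cagfinn_gradients(model, x, y)
  loss <- function(mod) 0.5 * (predict(mod, x) - y)^2
  h <- 1e-6
  for (i in 1:2) for (j in 1:2) {
    mp <- model; mp$centers[i, j] <- mp$centers[i, j] + h
    mm <- model; mm$centers[i, j] <- mm$centers[i, j] - h
    fd <- (loss(mp) - loss(mm)) / (2 * h)
    expect_lt(abs(fd - g$d_centers[i, j]) / max(abs(fd), 1e-8), 1e-4)
    # perturbing one side spread perturbs the total spread b
    mp <- model; mp$sigma_left[i, j] <- mp$sigma_left[i, j] + h
    mm <- model; mm$sigma_left[i, j] <- mm$sigma_left[i, j] - h
    fd <- (loss(mp) - loss(mm)) / (2 * h)
    expect_lt(abs(fd - g$d_spread_total[i, j]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("hybrid training recovers a known TSK system", {
  d <- generate_tsk_dataset(150, toy_rules(), noise_sd = 0, seed = 3)
  m <- cagfinn_fit(d$X, d$y, toy_partition(150),
                   control = cagfinn_control(max_epochs = 60,
                                             scale_inputs = FALSE))
  test <- generate_tsk_dataset(200, toy_rules(), noise_sd = 0, seed = 99)
  p <- predict(m, test$X)
  expect_lt(sqrt(mean((p - test$y)^2)), 1e-3)
  expect_gt(cor(p, test$y)^2, 0.99)
  # rule count never changes during training
  expect_equal(m$n_rules, 2)
  # training RMSE does not rise between the first and the final epoch
  expect_lte(tail(m$training_log, 1), m$training_log[1] + 1e-12)
})

test_that("training stays finite under an aggressive step size and serialises", {
  d <- generate_tsk_dataset(60, toy_rules(), noise_sd = 0, seed = 3)
  # the bounded membership and the spread floor keep even a reckless
  # learning rate from producing non-finite parameters
  wild <- cagfinn_fit(d$X, d$y, toy_partition(60),
                      control = cagfinn_control(max_epochs = 20,
                                                gd_rate = 5,
                                                scale_inputs = FALSE))
  expect_true(all(is.finite(wild$training_log)))
  expect_true(all(wild$sigma_left > 0) && all(wild$sigma_right > 0))
  m <- cagfinn_fit(d$X, d$y, toy_partition(60),
                   control = cagfinn_control(max_epochs = 10,
                                             scale_inputs = FALSE))
  path <- withr::local_tempfile(fileext = ".json")
  write_cagfinn(m, path)
  back <- read_cagfinn(path)
  X <- matrix(rnorm(20), ncol = 2)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
})
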