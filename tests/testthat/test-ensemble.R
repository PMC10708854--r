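test_that("averaging combines elementwise and stays within the base range", {
  sp <- stacked_predictions(c(4, 6, 5), c(6, 6, 3))
  expect_equal(average_combine(sp), c(5, 6, 4))
  set.seed(8)
  a <- runif(50, 3, 10); b <- runif(50, 3, 10)
  avg <- average_combine(stacked_predictions(a, b))
  expect_equal(avg, (a + b) / 2)
  expect_true(all(avg >= pmin(a, b) - 1e-12 & avg <= pmax(a, b) + 1e-12))
  expect_error(stacked_predictions(1:3, 1:4), "equal length")
})

test_that("NIPALS PLS1 agrees with the Krylov-subspace closed form", {
  set.seed(9)
  X <- matrix(rnorm(40 * 5), 40)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(40, 0, 0.1)
  for (a in 1:3) {
    fit <- nipals_pls(X, y, ncomp = a, scale = FALSE)
    # PLS1 predictions = OLS on the Krylov basis {X'y, (X'X)X'y, ...}
    Xc <- scale(X, scale = FALSE)
    yc <- y - mean(y)
    S <- crossprod(Xc)
    v <- drop(crossprod(Xc, yc))
    K <- sapply(seq_len(a), function(i) {
      out <- v
      if (i > 1) for (s in seq_len(i - 1)) out <- S %*% out
      out
    })
    Bk <- Xc %*% K
    beta_k <- K %*% qr.solve(crossprod(Bk), crossprod(Bk, yc))
    pred_k <- drop(Xc %*% beta_k) + mean(y)
    expect_equal(predict(fit, X), pred_k, tolerance = 1e-8,
                 label = sprintf("ncomp=%d", a))
  }
  # full-rank PLS equals OLS
  full <- nipals_pls(X, y, ncomp = 5, scale = FALSE)
  ols <- stats::lm(y ~ X)
  expect_equal(unname(full$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
})

test_that("the linear meta-model recovers an identity mapping", {
  set.seed(10)
  x_mean <- runif(40, 3, 10)
  x_sd <- x_mean + rnorm(40, 0, 0.5)
  sp <- stacked_predictions(x_mean, x_sd, y = x_mean)
  meta <- fit_meta(sp, kind = "pls_linear")
  pred <- predict_meta(meta, x_mean, x_sd)
  expect_gt(cor(pred, x_mean)^2, 0.999)
})

test_that("poly4 meta-fit matches a generating degree-4 polynomial", {
  set.seed(11)
  x_mean <- runif(60, 3, 9)
  x_sd <- runif(60, 3, 9)
  beta <- c(1.37, -1.38, 0.65, 0.171, -0.198, -0.087, 0.073, 0.012, -0.011)
  B <- cbind(x_mean, x_sd, x_mean^2, x_sd^2, x_mean^3, x_sd^3,
             x_mean^4, x_sd^4)
  y <- beta[1] + drop(B %*% beta[-1])
  meta <- fit_meta(stacked_predictions(x_mean, x_sd, y),
                   kind = "poly4_nipals", ncomp_max = 8)
  pred <- predict_meta(meta, x_mean, x_sd)
  expect_lt(max(abs(pred - y)), 1e-6)
  expect_length(meta$coefficients, 9)
})

test_that("more latent components never hurt the in-sample meta fit", {
  set.seed(12)
  x_mean <- runif(50, 3, 9); x_sd <- runif(50, 3, 9)
  y <- 0.4 * x_mean + 0.6 * x_sd + 0.05 * x_mean^2 + rnorm(50, 0, 0.1)
  B <- cbind(x_mean, x_sd, x_mean^2, x_sd^2, x_mean^3, x_sd^3,
             x_mean^4, x_sd^4)
  one <- nipals_pls(B, y, ncomp = 1)
  ols <- stats::lm(y ~ B)
  rmse <- function(p) sqrt(mean((y - p)^2))
  expect_lte(rmse(fitted(ols)), rmse(predict(one, B)))
})

test_that("predict_meta evaluates supplied coefficient vectors exactly", {
  co <- c(1.37, -51.38, 50.65, 17.71, -16.98, -2.87, 2.73, 0.22, -0.21)
  x <- seq(3, 9, length.out = 7)
  got <- predict_meta(co, x, x)
  # with equal base inputs the antisymmetric coefficient pairs collapse
  want <- 1.37 + (-51.38 + 50.65) * x + (17.71 - 16.98) * x^2 +
    (-2.87 + 2.73) * x^3 + (0.22 - 0.21) * x^4
  expect_equal(got, want, tolerance = 1e-12)
  # Horner-scheme oracle on random coefficients
  set.seed(13)
  co2 <- rnorm(9)
  xm <- runif(10, 3, 9); xs <- runif(10, 3, 9)
  horner <- function(x, c1, c2, c3, c4) (((c4 * x + c3) * x + c2) * x + c1) * x
  want2 <- co2[1] + horner(xm, co2[2], co2[4], co2[6], co2[8]) +
    horner(xs, co2[3], co2[5], co2[7], co2[9])
  expect_equal(predict_meta(co2, xm, xs), want2, tolerance = 1e-12)
  # constant meta-model
  expect_equal(predict_meta(c(5, rep(0, 8)), xm, xs), rep(5, 10))
})

test_that("meta-fitting guards its preconditions", {
  sp_small <- stacked_predictions(runif(5), runif(5), runif(5))
  expect_error(fit_meta(sp_small, "poly4_nipals"), "at least 10")
  sp_const <- stacked_predictions(rep(1, 12), rep(1, 12), runif(12))
  expect_error(fit_meta(sp_const, "poly4_nipals"), "more data|variation")
})
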