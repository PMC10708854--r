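test_that("hand-worked metric values are reproduced", {
  y <- c(1, 2, 3, 4)
  r_perfect <- compute_metrics(y, y)
  expect_equal(r_perfect$rmse, 0)
  expect_equal(r_perfect$bf, 1)
  expect_equal(r_perfect$af, 1)
  expect_true("zero_rmse" %in% r_perfect$flags)
  expect_equal(r_perfect$rpd, Inf)

  r_shift <- compute_metrics(y, y + 1)
  expect_equal(r_shift$rmse, 1)
  expect_equal(r_shift$rer, 3)
  expect_equal(r_shift$theta, (2.5 - 3.5) / sd(y))
  expect_equal(r_shift$mae, 1)

  # tenfold over-prediction: every log10 ratio is exactly 1
  r_ten <- compute_metrics(y, 10 * y)
  expect_equal(r_ten$bf, 10)
  expect_equal(r_ten$af, 10)

  expect_error(compute_metrics(1, 1), "length >= 2")
  neg <- compute_metrics(c(-1, 2, 3), c(1, 2, 3))
  expect_true(is.na(neg$bf))
  expect_true("log_ratio_undefined" %in% neg$flags)
})

test_that("every metric matches the straight-loop oracle on random instances", {
  set.seed(14)
  for (rep in 1:300) {
    n <- sample(5:40, 1)
    y <- runif(n, 0.5, 12)
    yhat <- y * exp(rnorm(n, 0, 0.15))
    got <- compute_metrics(y, yhat)
    want <- oracle_metrics(y, yhat)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10, label = f)
    }
    # internal identities
    expect_equal(got$rpiq * got$rmse,
                 diff(quantile(y, c(0.25, 0.75), names = FALSE)),
                 tolerance = 1e-9)
    expect_gte(got$rer, got$rpiq)
    expect_gte(got$af, max(got$bf, 1 / got$bf) - 1e-12)
    expect_equal(got$ape, got$n * got$mape_pct, tolerance = 1e-9)
  }
})

test_that("bias/accuracy factors transform correctly under swap and scaling", {
  set.seed(15)
  y <- runif(20, 1, 10); yhat <- runif(20, 1, 10)
  fwd <- compute_metrics(y, yhat)
  rev <- compute_metrics(yhat, y)
  expect_equal(fwd$af, rev$af, tolerance = 1e-12)
  expect_equal(fwd$bf, 1 / rev$bf, tolerance = 1e-12)
  # common positive rescaling leaves the relative metrics unchanged
  s <- 3.7
  sc <- compute_metrics(s * y, s * yhat)
  for (f in c("bf", "af", "mape_pct", "sep_pct", "rpd", "rer", "rpiq",
              "r_squared", "theta", "cohens_d")) {
    expect_equal(sc[[f]], fwd[[f]], tolerance = 1e-9, label = f)
  }
  expect_equal(sc$rmse, s * fwd$rmse, tolerance = 1e-9)
  expect_equal(sc$mae, s * fwd$mae, tolerance = 1e-9)
})

test_that("the two R-squared conventions are both available", {
  y <- c(1, 2, 3, 4, 5)
  yhat <- c(1.2, 1.9, 3.3, 3.8, 5.1)
  expect_equal(compute_metrics(y, yhat)$r_squared, cor(y, yhat)^2)
  expect_equal(compute_metrics(y, yhat, r2 = "determination")$r_squared,
               1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
})

test_that("leave-one-out predictions equal the hat-matrix closed form", {
  set.seed(16)
  n <- 12
  X <- cbind(rnorm(n), rnorm(n))
  colnames(X) <- c("a", "b")
  y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(n, 0, 0.3)
  res <- loocv(X, y,
               fit_fun = function(Xt, yt)
                 stats::lm(y ~ a + b, data = data.frame(y = yt, Xt)),
               predict_fun = function(m, Xn)
                 stats::predict(m, newdata = as.data.frame(Xn)))
  D <- cbind(1, X)
  H <- D %*% solve(crossprod(D)) %*% t(D)
  e <- y - drop(H %*% y)
  loo_oracle <- y - e / (1 - diag(H))
  expect_equal(res$predictions, unname(loo_oracle), tolerance = 1e-9)
  expect_length(res$failed, 0)
})

test_that("loocv tolerates constant targets and records failed folds", {
  n <- 8
  X <- matrix(rnorm(n * 2), n)
  res <- loocv(X, rep(5, n),
               fit_fun = function(Xt, yt) mean(yt),
               predict_fun = function(m, Xn) m)
  expect_equal(res$predictions, rep(5, n))
  expect_equal(res$report$bf, 1)
  expect_equal(res$report$af, 1)

  flaky <- loocv(X, rnorm(n),
                 fit_fun = function(Xt, yt) {
                   if (abs(Xt[1, 1]) > 0) stop("boom") else 1
                 })
  expect_equal(length(flaky$failed), n)
  expect_null(flaky$report)
})

test_that("hold-out splits are exact, stratified and reproducible", {
  ds <- generate_dataset(seed = 17)
  ds84 <- spectral_dataset(as.data.frame(ds)[1:84, ])
  sp <- holdout_split(ds84, test_frac = 0.1, seed = 2)
  expect_equal(nrow(sp$test), 8)
  expect_equal(nrow(sp$train), 76)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:84)
  # every temperature stratum contributes at least one test sample
  expect_setequal(unique(sp$test$temperature_C),
                  unique(ds84$temperature_C))
  sp2 <- holdout_split(ds84, test_frac = 0.1, seed = 2)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_false(identical(sp$test_idx,
                         holdout_split(ds84, 0.1, seed = 3)$test_idx))
  expect_error(holdout_split(ds84, 0), "between 0 and 1")
  expect_error(holdout_split(ds84, 1), "between 0 and 1")
})
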