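#' Univariate partial least squares regression by NIPALS
#'
#' Fits a PLS1 model by nonlinear iterative partial least squares
#' component extraction: each component's weight vector is the
#' (normalised) covariance direction `X'y`, scores are `t = Xw`, and
#' both `X` and `y` are deflated by the score before the next component.
#' Predictors are centred and (by default) unit-variance scaled; the
#' response is centred.  Regression coefficients are reported back in
#' the raw units of `X` and `y`.
#'
#' @param X numeric predictor matrix (n x p).
#' @param y numeric response vector (length n).
#' @param ncomp number of latent components, `1 <= ncomp <= min(n-1, p)`.
#' @param scale logical, unit-variance scale the predictors (default TRUE).
#' @return List of class `nipals_pls` with elements `coefficients`
#'   (length p, raw units), `intercept`, `scores`, `loadings`, `weights`,
#'   `ncomp`, and the centring/scaling used.
#' @export
nipals_pls <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop("ncomp must lie in 1..min(n-1, p)", call. = FALSE)
  }
  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  x_scale[x_scale < .Machine$double.eps] <- 1
  y_center <- mean(y)
  E <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  f <- y - y_center
  W <- matrix(0, p, ncomp)   # weights
  P <- matrix(0, p, ncomp)   # X loadings
  Tm <- matrix(0, n, ncomp)  # scores
  qv <- numeric(ncomp)       # y loadings
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {
      # residual response is orthogonal to X: truncate
      ncomp <- a - 1L
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      Tm <- Tm[, seq_len(ncomp), drop = FALSE]
      qv <- qv[seq_len(ncomp)]
      break
    }
    w <- w / nw
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    pv <- drop(crossprod(E, tt)) / t2
    qa <- sum(f * tt) / t2
    E <- E - tcrossprod(tt, pv)
    f <- f - qa * tt
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- tt; qv[a] <- qa
  }
  if (ncomp == 0L) {
    beta_std <- rep(0, p)
  } else {
    # B = W (P'W)^-1 q, in standardised predictor units
    beta_std <- drop(W %*% solve(crossprod(P, W), qv))
  }
  coefficients <- beta_std / x_scale
  intercept <- y_center - sum(coefficients * x_center)
  structure(list(coefficients = coefficients, intercept = intercept,
                 scores = Tm, loadings = P, weights = W, y_loadings = qv,
                 ncomp = ncomp, x_center = x_center, x_scale = x_scale,
                 y_center = y_center),
            class = "nipals_pls")
}

#' @export
predict.nipals_pls <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  drop(X %*% object$coefficients) + object$intercept
}
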