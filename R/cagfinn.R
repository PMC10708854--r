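#' Asymmetric Gaussian membership degree
#'
#' The membership function shares one centre `c` between two spreads: a
#' left spread for inputs below the centre and a right spread above it.
#' During the forward pass the degree is evaluated with the *total*
#' spread `b = sigma_left + sigma_right`,
#' `A(x) = exp(-(x - c)^2 / (2 b^2))`,
#' and the side the input fell on is recorded; the backward learning
#' phase uses that record to update only the corresponding side-spread.
#'
#' @param x scalar (or vector) input; must be finite.
#' @param center membership centre.
#' @param sigma_left,sigma_right positive side spreads.
#' @return List with `degree` in (0, 1] and `side` (`"left"` when
#'   `x < center`, else `"right"`), each the length of `x`.
#' @examples
#' asym_membership(1.5, center = 1, sigma_left = 0.25, sigma_right = 0.25)
#' @export
asym_membership <- function(x, center, sigma_left, sigma_right) {
  if (any(!is.finite(x))) stop("input must be finite", call. = FALSE)
  stopifnot(sigma_left > 0, sigma_right > 0)
  b <- sigma_left + sigma_right
  list(degree = exp(-(x - center)^2 / (2 * b^2)),
       side = ifelse(x < center, "left", "right"))
}

#' Construct a CAGFINN model from explicit parameters
#'
#' Mainly for tests and for deserialisation: assembles the
#' clustering-based asymmetric Gaussian fuzzy inference neural network
#' from its parameter matrices.  There is one fuzzy rule per cluster;
#' rule `i` carries one asymmetric Gaussian membership function per
#' input coordinate (centres `centers[i, ]`, side spreads
#' `sigma_left[i, ]`, `sigma_right[i, ]`) and an affine consequent
#' `f_i = w_i1 x_1 + ... + w_iq x_q + w_i(q+1)`.
#'
#' @param centers c x q matrix of membership centres.
#' @param sigma_left,sigma_right c x q matrices of positive side spreads.
#' @param consequents c x (q+1) matrix of consequent weights (bias last).
#' @param x_center,x_scale optional length-q input standardisation
#'   applied before the premise layer (defaults: identity).
#' @return An object of class `cagfinn`.
#' @export
cagfinn_model <- function(centers, sigma_left, sigma_right, consequents,
                          x_center = NULL, x_scale = NULL) {
  centers <- as.matrix(centers)
  sigma_left <- as.matrix(sigma_left)
  sigma_right <- as.matrix(sigma_right)
  consequents <- as.matrix(consequents)
  cc <- nrow(centers); q <- ncol(centers)
  stopifnot(all(dim(sigma_left) == c(cc, q)),
            all(dim(sigma_right) == c(cc, q)),
            all(dim(consequents) == c(cc, q + 1)),
            all(sigma_left > 0), all(sigma_right > 0))
  if (is.null(x_center)) x_center <- rep(0, q)
  if (is.null(x_scale)) x_scale <- rep(1, q)
  structure(list(centers = centers, sigma_left = sigma_left,
                 sigma_right = sigma_right, consequents = consequents,
                 q = q, n_rules = cc,
                 x_center = x_center, x_scale = x_scale,
                 training_log = numeric(0), underflow_count = 0L),
            class = "cagfinn")
}

#' @export
print.cagfinn <- function(x, ...) {
  cat(sprintf("cagfinn: %d rules, %d inputs\n", x$n_rules, x$q))
  if (length(x$training_log)) {
    cat(sprintf("  trained %d epochs, final RMSE %.6g\n",
                length(x$training_log), utils::tail(x$training_log, 1)))
  }
  invisible(x)
}

# standardise an input matrix into the model's premise space
.cagfinn_std <- function(model, X) {
  sweep(sweep(as.matrix(X), 2, model$x_center), 2, model$x_scale, "/")
}

#' Rule firing strengths for one input vector
#'
#' Layer 3/4 of the network: the rule strength is the product of the
#' per-coordinate membership degrees, `R_i = prod_j A_ij(x_j)`, and the
#' normalised strength is `Rbar_i = R_i / sum_j R_j`.  If every rule
#' strength underflows to zero the normalised strengths fall back to
#' the uniform `1/c` (counted on the model, not an error).
#'
#' @param model a `cagfinn` model.
#' @param x numeric input vector of length `model$q` (original units).
#' @return List with `R` (raw strengths), `Rbar` (normalised, sums to
#'   1), and `sides` (c x q character matrix of recorded sides).
#' @export
fire_rules <- function(model, x) {
  stopifnot(inherits(model, "cagfinn"))
  if (length(x) != model$q) stop("input dimension mismatch", call. = FALSE)
  z <- drop(.cagfinn_std(model, matrix(x, nrow = 1)))
  dev <- sweep(model$centers, 2, z, function(c_, z_) z_ - c_) * -1  # c - z
  b <- model$sigma_left + model$sigma_right
  A <- exp(-(dev)^2 / (2 * b^2))
  R <- apply(A, 1, prod)
  s <- sum(R)
  if (s <= 0) {
    Rbar <- rep(1 / model$n_rules, model$n_rules)
  } else {
    Rbar <- R / s
  }
  sides <- ifelse(sweep(model$centers, 2, z, function(c_, z_) z_ < c_),
                  "left", "right")
  list(R = R, Rbar = Rbar, sides = sides)
}

#' Predict TVC (or any target) with a CAGFINN model
#'
#' Layer 5: `O = sum_i Rbar_i (w_i . x + w_i(q+1))`, the normalised-
#' strength-weighted combination of the affine rule consequents.
#' Consequents act on the same (standardised) premise inputs.
#'
#' @param object a `cagfinn` model.
#' @param newdata numeric matrix (n x q) or vector (length q).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.cagfinn <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(X) != object$q) stop("input dimension mismatch", call. = FALSE)
  fwd <- .cagfinn_forward(object, .cagfinn_std(object, X))
  fwd$O
}

# Vectorised forward pass over a standardised input matrix Z (n x q).
# Returns rule strengths (n x c), normalised strengths, predictions and
# per-rule consequent outputs.
.cagfinn_forward <- function(model, Z) {
  n <- nrow(Z); cc <- model$n_rules; q <- model$q
  b <- model$sigma_left + model$sigma_right
  logR <- matrix(0, n, cc)
  for (i in seq_len(cc)) {
    dev <- sweep(Z, 2, model$centers[i, ])
    logR[, i] <- -rowSums(sweep(dev^2, 2, 2 * b[i, ]^2, "/"))
  }
  R <- exp(logR)
  s <- rowSums(R)
  under <- s <= 0
  Rbar <- R / ifelse(s > 0, s, 1)
  if (any(under)) Rbar[under, ] <- 1 / cc
  Fmat <- Z %*% t(model$consequents[, seq_len(q), drop = FALSE])
  Fmat <- sweep(Fmat, 2, model$consequents[, q + 1], "+")
  O <- rowSums(Rbar * Fmat)
  list(R = R, Rbar = Rbar, F = Fmat, O = O, underflow = sum(under))
}

#' Training configuration for the hybrid learning algorithm
#'
#' @param max_epochs epoch cap (default 500; training usually stops far
#'   earlier on the improvement tolerance).
#' @param gd_rate gradient-descent step for the premise parameters,
#'   applied in standardised input space.
#' @param rls_forgetting RLS forgetting factor in (0, 1]; 1 gives
#'   ordinary (growing-window) least squares.
#' @param rls_init_cov initial RLS covariance scale P0 (P = P0 * I).
#' @param tol stop when the epoch-RMSE improvement falls below this.
#' @param reset_cov_each_epoch restart the RLS covariance at the top of
#'   every epoch (default TRUE); with forgetting 1 the consequents then
#'   converge to the batch least-squares solution of the linearised
#'   system.
#' @param scale_inputs z-score the inputs (and map the initial
#'   partition) into standardised space before training (default TRUE).
#' @param keep_best return the parameters from the best epoch rather
#'   than the last (default TRUE).
#' @param seed integer seed (training itself is deterministic; the seed
#'   covers any stochastic extensions).
#' @return List of class `cagfinn_control`.
#' @export
cagfinn_control <- function(max_epochs = 500, gd_rate = 0.01,
                            rls_forgetting = 1.0, rls_init_cov = 1e4,
                            tol = 1e-6, reset_cov_each_epoch = TRUE,
                            scale_inputs = TRUE, keep_best = TRUE,
                            seed = 1) {
  stopifnot(max_epochs >= 1, gd_rate >= 0,
            rls_forgetting > 0, rls_forgetting <= 1,
            rls_init_cov > 0, tol >= 0)
  structure(list(max_epochs = max_epochs, gd_rate = gd_rate,
                 rls_forgetting = rls_forgetting,
                 rls_init_cov = rls_init_cov, tol = tol,
                 reset_cov_each_epoch = reset_cov_each_epoch,
                 scale_inputs = scale_inputs, keep_best = keep_best,
                 seed = seed),
            class = "cagfinn_control")
}

#' Fit a CAGFINN model by hybrid RLS + gradient descent
#'
#' One epoch processes the samples sequentially.  For each sample the
#' forward pass computes the normalised rule strengths; the consequent
#' weights are updated by recursive least squares on the regressor
#' vector `(Rbar_1 [x, 1], ..., Rbar_c [x, 1])`; then the premise
#' parameters take a gradient-descent step on the squared error: the
#' centres by the chain rule through the Gaussian, and the *total*
#' spread's step yields `sigma_new`, of which only the side the input
#' fell on (recorded during the forward pass) is set to `sigma_new / 2`
#' - the other side keeps its value, so the next forward pass uses the
#' asymmetric total `sigma_left + sigma_right`.  Training stops at
#' `max_epochs` or when the epoch-RMSE improvement drops below `tol`.
#'
#' @param X numeric input matrix (n x q).
#' @param y numeric target vector.
#' @param init a `fuzzy_partition` (from [cluster_init()] or built
#'   manually) holding centres and `sigma_init` in the units of `X`;
#'   side spreads start at `sigma_init / 2` each.
#' @param control a [cagfinn_control()].
#' @return A trained `cagfinn` model; `training_log` holds per-epoch RMSE.
#' @export
cagfinn_fit <- function(X, y, init, control = cagfinn_control()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); q <- ncol(X)
  stopifnot(length(y) == n, inherits(init, "fuzzy_partition"))
  if (is.null(init$sigma_init)) {
    stop("initial partition has no sigma_init; run init_spreads()",
         call. = FALSE)
  }
  cc <- nrow(init$centers)
  if (control$scale_inputs) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, stats::sd)
    x_scale[!is.finite(x_scale) | x_scale < .Machine$double.eps] <- 1
  } else {
    x_center <- rep(0, q); x_scale <- rep(1, q)
  }
  Z <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  centers <- sweep(sweep(as.matrix(init$centers), 2, x_center), 2,
                   x_scale, "/")
  sig <- sweep(as.matrix(init$sigma_init), 2, x_scale, "/")
  spread_floor <- 1e-3 * apply(Z, 2, function(v) max(diff(range(v)), 1e-3))
  sig <- pmax(sig, matrix(spread_floor, cc, q, byrow = TRUE))
  sigma_left <- sig / 2
  sigma_right <- sig / 2
  W <- matrix(0, cc, q + 1)       # consequents
  p_dim <- cc * (q + 1)
  P <- diag(p_dim) * control$rls_init_cov
  lam <- control$rls_forgetting
  eta <- control$gd_rate
  rmse_log <- numeric(0)
  best <- list(rmse = Inf)
  underflow <- 0L
  for (epoch in seq_len(control$max_epochs)) {
    if (control$reset_cov_each_epoch) {
      P <- diag(p_dim) * control$rls_init_cov
    }
    sse <- 0
    for (k in seq_len(n)) {
      z <- Z[k, ]
      dev <- sweep(centers, 2, z, function(c_, z_) c_ - z_)  # c - z
      b <- sigma_left + sigma_right
      A <- exp(-dev^2 / (2 * b^2))
      R <- apply(A, 1, prod)
      s <- sum(R)
      if (s <= 0) {
        Rbar <- rep(1 / cc, cc)
        underflow <- underflow + 1L
      } else {
        Rbar <- R / s
      }
      xb <- c(z, 1)
      phi <- as.numeric(t(outer(Rbar, xb)))       # rule-major regressor
      # RLS update of the consequent weights
      w_vec <- as.numeric(t(W))                   # rule-major: (w_i., bias_i)
      Pphi <- P %*% phi
      gain <- Pphi / (lam + sum(phi * Pphi))
      err_pri <- y[k] - sum(phi * w_vec)
      w_vec <- w_vec + gain * err_pri
      P <- (P - tcrossprod(gain, Pphi)) / lam
      W <- matrix(w_vec, nrow = cc, byrow = TRUE)
      # forward output with updated consequents
      f <- drop(W[, seq_len(q), drop = FALSE] %*% z) + W[, q + 1]
      O <- sum(Rbar * f)
      e <- O - y[k]
      sse <- sse + e^2
      if (eta > 0 && s > 0) {
        # dE/dR_i = e * (f_i - O) / s ; chain through A and the Gaussian
        dE_dR <- e * (f - O) / s
        g_common <- dE_dR * R                     # dE/d(logR_i)
        dc <- -g_common * dev / b^2               # dE/dc_ij
        dbm <- g_common * dev^2 / b^3             # dE/db_ij (total spread)
        centers <- centers - eta * dc
        sigma_new <- pmax(b - eta * dbm,
                          matrix(spread_floor, cc, q, byrow = TRUE))
        left_side <- dev > 0                      # c > z  <=>  z < c
        half <- sigma_new / 2
        sigma_left[left_side] <- half[left_side]
        sigma_right[!left_side] <- half[!left_side]
        sigma_left <- pmax(sigma_left,
                           matrix(spread_floor / 2, cc, q, byrow = TRUE))
        sigma_right <- pmax(sigma_right,
                            matrix(spread_floor / 2, cc, q, byrow = TRUE))
      }
    }
    rmse <- sqrt(sse / n)
    if (!is.finite(rmse)) {
      stop("training diverged (non-finite RMSE); reduce gd_rate",
           call. = FALSE)
    }
    rmse_log[epoch] <- rmse
    if (rmse < best$rmse) {
      best <- list(rmse = rmse, centers = centers,
                   sigma_left = sigma_left, sigma_right = sigma_right,
                   W = W)
    }
    if (epoch > 1 &&
        (rmse_log[epoch - 1] - rmse) < control$tol &&
        rmse <= rmse_log[epoch - 1]) {
      break
    }
  }
  if (control$keep_best && is.finite(best$rmse)) {
    centers <- best$centers
    sigma_left <- best$sigma_left
    sigma_right <- best$sigma_right
    W <- best$W
  }
  model <- cagfinn_model(centers, sigma_left, sigma_right, W,
                         x_center = x_center, x_scale = x_scale)
  model$training_log <- rmse_log
  model$underflow_count <- underflow
  model
}

# gradient of the single-sample squared-error loss 0.5 * (O - y)^2 with
# respect to centres and total spreads, in standardised space; used by
# the finite-difference tests.
.cagfinn_gradients <- function(model, x, y) {
  z <- drop(.cagfinn_std(model, matrix(x, nrow = 1)))
  cc <- model$n_rules; q <- model$q
  dev <- sweep(model$centers, 2, z, function(c_, z_) c_ - z_)
  b <- model$sigma_left + model$sigma_right
  A <- exp(-dev^2 / (2 * b^2))
  R <- apply(A, 1, prod)
  s <- sum(R)
  Rbar <- R / s
  f <- drop(model$consequents[, seq_len(q), drop = FALSE] %*% z) +
    model$consequents[, q + 1]
  O <- sum(Rbar * f)
  e <- O - y
  dE_dR <- e * (f - O) / s
  g_common <- dE_dR * R
  list(d_centers = -g_common * dev / b^2,
       d_spread_total = g_common * dev^2 / b^3,
       loss = 0.5 * e^2)
}

#' Serialise / deserialise a CAGFINN model as JSON
#'
#' @param model a `cagfinn` model.
#' @param path output (or input) file path.
#' @return `write_cagfinn()` returns `path` invisibly; `read_cagfinn()`
#'   the reconstructed model.
#' @export
write_cagfinn <- function(model, path) {
  stopifnot(inherits(model, "cagfinn"))
  obj <- list(centers = model$centers, sigma_left = model$sigma_left,
              sigma_right = model$sigma_right,
              consequents = model$consequents,
              x_center = model$x_center, x_scale = model$x_scale,
              training_log = model$training_log)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cagfinn
#' @export
read_cagfinn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- cagfinn_model(obj$centers, obj$sigma_left, obj$sigma_right,
                         obj$consequents,
                         x_center = obj$x_center, x_scale = obj$x_scale)
  model$training_log <- as.numeric(obj$training_log)
  model
}
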