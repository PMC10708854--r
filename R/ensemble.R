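#' Aligned base-model predictions for stacking
#'
#' Holds the TVC predictions of the mean-feature and sd-feature base
#' models for the same samples, plus (for meta-training) the observed
#' targets.  For honest stacking the base predictions should be
#' out-of-fold, never in-sample fits.
#'
#' @param x_mean,x_sd numeric prediction vectors of equal length.
#' @param y optional observed targets (required by [fit_meta()]).
#' @return List of class `stacked_predictions`.
#' @export
stacked_predictions <- function(x_mean, x_sd, y = NULL) {
  if (length(x_mean) != length(x_sd)) {
    stop("base prediction vectors must have equal length", call. = FALSE)
  }
  if (!is.null(y) && length(y) != length(x_mean)) {
    stop("targets must align with the base predictions", call. = FALSE)
  }
  if (any(!is.finite(c(x_mean, x_sd, y)))) {
    stop("base predictions and targets must be finite", call. = FALSE)
  }
  structure(list(x_mean = as.numeric(x_mean), x_sd = as.numeric(x_sd),
                 y = if (is.null(y)) NULL else as.numeric(y)),
            class = "stacked_predictions")
}

#' Combine base predictions by averaging
#'
#' @param sp a [stacked_predictions()].
#' @return Elementwise `(x_mean + x_sd) / 2`.
#' @export
average_combine <- function(sp) {
  stopifnot(inherits(sp, "stacked_predictions"))
  (sp$x_mean + sp$x_sd) / 2
}

# degree-4 polynomial basis of the two base predictions (8 columns)
.poly4_basis <- function(x_mean, x_sd) {
  B <- cbind(x_mean, x_sd, x_mean^2, x_sd^2, x_mean^3, x_sd^3,
             x_mean^4, x_sd^4)
  colnames(B) <- c("Xmean", "Xsd", "Xmean2", "Xsd2", "Xmean3", "Xsd3",
                   "Xmean4", "Xsd4")
  B
}

#' Fit a stacking meta-model on base predictions
#'
#' Two meta-model forms are available.  `pls_linear` regresses the
#' target on `(X_mean, X_sd)`; `poly4_nipals` regresses it on the
#' 8-term polynomial basis `{X_mean^d, X_sd^d : d = 1..4}`.  Both are
#' fitted by NIPALS partial-least-squares component extraction on the
#' standardised basis, with the number of latent components chosen by
#' k-fold cross-validation (capped at `ncomp_max`); coefficients are
#' reported back in raw units.
#'
#' @param sp a [stacked_predictions()] with `y` present; `poly4_nipals`
#'   needs at least 10 rows (9 parameters).
#' @param kind `"poly4_nipals"` (default) or `"pls_linear"`.
#' @param ncomp_max cap on the number of latent components (default 4).
#' @param folds folds for the inner component-selection CV (default 10,
#'   reduced to `n` when `n < folds`, i.e. leave-one-out).
#' @return List of class `meta_model` with `kind`, `coefficients`
#'   (intercept first: length 9 for poly4, 3 for linear), and `ncomp`.
#' @export
fit_meta <- function(sp, kind = c("poly4_nipals", "pls_linear"),
                     ncomp_max = 4, folds = 10) {
  kind <- match.arg(kind)
  stopifnot(inherits(sp, "stacked_predictions"))
  if (is.null(sp$y)) stop("meta-training requires targets", call. = FALSE)
  n <- length(sp$y)
  if (kind == "poly4_nipals" && n < 10) {
    stop("poly4 meta-model needs at least 10 rows", call. = FALSE)
  }
  if (n < 3) stop("too few rows to fit a meta-model", call. = FALSE)
  B <- if (kind == "poly4_nipals") .poly4_basis(sp$x_mean, sp$x_sd) else
    cbind(Xmean = sp$x_mean, Xsd = sp$x_sd)
  if (any(apply(B, 2, stats::sd) < 1e-12) &&
      qr(scale(B, scale = FALSE))$rank < min(dim(B))) {
    # fully degenerate basis (e.g. constant base predictions)
    if (all(apply(B, 2, stats::sd) < 1e-12)) {
      stop("basis is rank deficient: base predictions have no variation; more data needed",
           call. = FALSE)
    }
  }
  max_comp <- min(ncomp_max, ncol(B), n - 2)
  folds <- min(folds, n)
  fold_id <- rep(seq_len(folds), length.out = n)
  cv_rmse <- vapply(seq_len(max_comp), function(a) {
    press <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (sum(tr) <= a) return(Inf)
      fit <- nipals_pls(B[tr, , drop = FALSE], sp$y[tr], ncomp = a)
      pred <- predict(fit, B[!tr, , drop = FALSE])
      press <- press + sum((sp$y[!tr] - pred)^2)
    }
    sqrt(press / n)
  }, numeric(1))
  ncomp <- which.min(cv_rmse)
  fit <- nipals_pls(B, sp$y, ncomp = ncomp)
  structure(list(kind = kind,
                 coefficients = c(intercept = fit$intercept,
                                  stats::setNames(fit$coefficients,
                                                  colnames(B))),
                 ncomp = fit$ncomp, cv_rmse = cv_rmse),
            class = "meta_model")
}

#' Evaluate a stacking meta-model
#'
#' For the degree-4 form,
#' `Y = b0 + sum_d (b_mean,d X_mean^d + b_sd,d X_sd^d)`.
#' Coefficients may also be supplied directly (e.g. a published set)
#' via a bare numeric vector of length 9 (intercept first, then the
#' basis order `Xmean, Xsd, Xmean^2, Xsd^2, Xmean^3, Xsd^3, Xmean^4,
#' Xsd^4`), which is interpreted as a `poly4_nipals` model.
#'
#' @param meta a `meta_model` from [fit_meta()], or a length-9 numeric
#'   coefficient vector.
#' @param x_mean,x_sd numeric base-prediction vectors.
#' @return Numeric vector of combined predictions.
#' @export
predict_meta <- function(meta, x_mean, x_sd) {
  if (is.numeric(meta) && length(meta) == 9) {
    meta <- structure(list(kind = "poly4_nipals", coefficients = meta),
                      class = "meta_model")
  }
  stopifnot(inherits(meta, "meta_model"))
  if (any(!is.finite(c(x_mean, x_sd)))) {
    stop("inputs must be finite", call. = FALSE)
  }
  B <- if (meta$kind == "poly4_nipals") .poly4_basis(x_mean, x_sd) else
    cbind(x_mean, x_sd)
  co <- as.numeric(meta$coefficients)
  drop(B %*% co[-1]) + co[1]
}
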