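#' Food-microbiology and chemometric validation metrics
#'
#' Computes the full comparison suite for observed vs predicted TVC:
#' \describe{
#'   \item{bf}{bias factor, `10^(sum(log10(yhat/y))/n)`; 1 at perfect
#'     agreement, >1 for systematic over-prediction.}
#'   \item{af}{accuracy factor, `10^(sum(|log10(yhat/y)|)/n)`; the mean
#'     fold-discrepancy, >= 1, equal to 1 only at perfect agreement.}
#'   \item{rmse, mae}{root-mean-square and mean absolute error.}
#'   \item{mape_pct}{mean absolute percentage error, percent.}
#'   \item{ape}{un-averaged sum of absolute percentage errors,
#'     `sum(100 |y - yhat| / y)` (so `ape = n * mape_pct`).}
#'   \item{sep_pct}{standard error of prediction, `100 * rmse / mean(y)`.}
#'   \item{rpd, rer, rpiq}{sd, range and interquartile range of the
#'     observations, each divided by RMSE; larger is better.}
#'   \item{theta}{standardised mean difference
#'     `(mean(y) - mean(yhat)) / sd(y)`.}
#'   \item{cohens_d}{mean difference over the pooled standard deviation.}
#'   \item{r_squared}{squared Pearson correlation of `(y, yhat)` by
#'     default; set `r2 = "determination"` for `1 - SSE/SST`.}
#' }
#' Bf/Af (and the percentage metrics) require strictly positive
#' observations; when violated they are reported as `NA` with a flag
#' rather than failing the whole report.  Zero RMSE flags the ratio
#' metrics and reports them as `Inf`.
#'
#' @param y observed values (length >= 2).
#' @param yhat predicted values, same length.
#' @param r2 R-squared convention, `"correlation"` (default) or
#'   `"determination"`.
#' @return List of class `metrics_report`; `flags` lists any metric
#'   groups that were undefined, `quartile_type` records the quartile
#'   convention (type 7, linear interpolation).
#' @examples
#' compute_metrics(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
compute_metrics <- function(y, yhat, r2 = c("correlation", "determination")) {
  r2 <- match.arg(r2)
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  n <- length(y)
  if (n < 2 || length(yhat) != n) {
    stop("need two aligned vectors of length >= 2", call. = FALSE)
  }
  flags <- character(0)
  e <- y - yhat
  rmse <- sqrt(mean(e^2))
  mae <- mean(abs(e))
  if (all(y > 0)) {
    lr <- log10(yhat / y)
    bf <- 10^(sum(lr) / n)
    af <- 10^(sum(abs(lr)) / n)
    mape <- 100 * mean(abs(e) / y)
    ape <- 100 * sum(abs(e) / y)
  } else {
    flags <- c(flags, "log_ratio_undefined")
    bf <- af <- mape <- ape <- NA_real_
  }
  sep <- 100 * rmse / mean(y)
  sd_y <- stats::sd(y)
  qs <- stats::quantile(y, c(0.25, 0.75), type = 7, names = FALSE)
  iq <- qs[2] - qs[1]
  if (rmse == 0) {
    flags <- c(flags, "zero_rmse")
    rpd <- rer <- rpiq <- Inf
  } else {
    rpd <- sd_y / rmse
    rer <- (max(y) - min(y)) / rmse
    rpiq <- iq / rmse
  }
  theta <- (mean(y) - mean(yhat)) / sd_y
  sd_p <- stats::sd(yhat)
  pooled <- sqrt(((n - 1) * sd_y^2 + (n - 1) * sd_p^2) / (2 * n))
  cohens_d <- if (pooled > 0) (mean(y) - mean(yhat)) / pooled else 0
  r_squared <- if (r2 == "correlation") {
    if (sd_y == 0 || sd_p == 0) {
      flags <- c(flags, "degenerate_correlation")
      NA_real_
    } else {
      stats::cor(y, yhat)^2
    }
  } else {
    1 - sum(e^2) / sum((y - mean(y))^2)
  }
  structure(list(rmse = rmse, mape_pct = mape, sep_pct = sep, ape = ape,
                 mae = mae, rpd = rpd, rer = rer, rpiq = rpiq,
                 bf = bf, af = af, cohens_d = cohens_d, theta = theta,
                 r_squared = r_squared, n = n,
                 flags = flags, quartile_type = 7L,
                 r2_definition = r2),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (n = %d)\n", x$n))
  fields <- c("rmse", "mape_pct", "sep_pct", "ape", "mae", "rpd", "rer",
              "rpiq", "bf", "af", "cohens_d", "theta", "r_squared")
  for (f in fields) cat(sprintf("  %-10s %s\n", f, format(x[[f]], digits = 5)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-out cross-validation of an arbitrary regressor
#'
#' For each sample, the model is fitted on the remaining `n - 1` and
#' used to predict the held-out one; the report aggregates all `n`
#' out-of-fold predictions.  A fold whose fit fails is recorded (its
#' prediction stays `NA`) and the report is marked incomplete.
#'
#' @param X numeric input matrix (n x q), `n >= 3`.
#' @param y numeric target vector.
#' @param fit_fun function `(X_train, y_train) -> model`.
#' @param predict_fun function `(model, X_new) -> predictions`
#'   (default calls [predict()]).
#' @return List with `predictions` (length n, out-of-fold), `report`
#'   (a [compute_metrics()] result over the completed folds), and
#'   `failed` (indices of failed folds, if any).
#' @export
loocv <- function(X, y, fit_fun, predict_fun = function(m, X) predict(m, X)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 samples", call. = FALSE)
  stopifnot(length(y) == n)
  preds <- rep(NA_real_, n)
  failed <- integer(0)
  for (k in seq_len(n)) {
    res <- tryCatch({
      m <- fit_fun(X[-k, , drop = FALSE], y[-k])
      predict_fun(m, X[k, , drop = FALSE])
    }, error = function(err) err)
    if (inherits(res, "error")) {
      failed <- c(failed, k)
    } else {
      preds[k] <- as.numeric(res)[1]
    }
  }
  ok <- !is.na(preds)
  report <- if (sum(ok) >= 2) compute_metrics(y[ok], preds[ok]) else NULL
  if (length(failed) && !is.null(report)) {
    report$flags <- c(report$flags, "incomplete_folds")
  }
  list(predictions = preds, report = report, failed = failed)
}

#' Temperature-stratified train/test hold-out split
#'
#' Draws a test set of `max(1, round(n * test_frac))` samples,
#' stratified by storage temperature when the dataset carries one
#' (per-stratum quotas by largest remainder, so the total is exact).
#' With 84 samples and a 10 percent fraction this reserves exactly 8
#' test samples.
#'
#' @param ds a [spectral_dataset()] (or any data frame with an optional
#'   `temperature_C` column).
#' @param test_frac test fraction in (0, 1), default 0.1.
#' @param seed integer seed; the same seed reproduces the same split.
#' @return List with `train` and `test` (both `spectral_dataset`s when
#'   the input was one) and the integer index vectors `train_idx`,
#'   `test_idx`.
#' @export
holdout_split <- function(ds, test_frac = 0.1, seed = 1) {
  if (test_frac <= 0 || test_frac >= 1) {
    stop("test_frac must lie strictly between 0 and 1", call. = FALSE)
  }
  df <- as.data.frame(ds)
  n <- nrow(df)
  m <- max(1L, as.integer(round(n * test_frac)))
  if (m >= n) stop("test fraction leaves no training data", call. = FALSE)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  strata <- if ("temperature_C" %in% names(df) &&
                !anyNA(df$temperature_C)) {
    as.character(df$temperature_C)
  } else {
    rep("all", n)
  }
  groups <- split(seq_len(n), strata)
  quota_raw <- vapply(groups, length, integer(1)) * m / n
  quota <- floor(quota_raw)
  remainder <- quota_raw - quota
  short <- m - sum(quota)
  if (short > 0) {
    bump <- order(remainder, decreasing = TRUE)[seq_len(short)]
    quota[bump] <- quota[bump] + 1
  }
  test_idx <- sort(unlist(mapply(function(idx, k) {
    if (k == 0) integer(0) else sample(idx, min(k, length(idx)))
  }, groups, quota, SIMPLIFY = FALSE), use.names = FALSE))
  # top up if rounding against tiny strata left the quota unmet
  if (length(test_idx) < m) {
    pool <- setdiff(seq_len(n), test_idx)
    test_idx <- sort(c(test_idx, sample(pool, m - length(test_idx))))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  subset_ds <- function(idx) {
    out <- df[idx, , drop = FALSE]
    rownames(out) <- NULL
    if (inherits(ds, "spectral_dataset")) spectral_dataset(out) else out
  }
  list(train = subset_ds(train_idx), test = subset_ds(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Serialise a metrics report to JSON
#'
#' @param report a [compute_metrics()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- unclass(report)
  obj$rpd <- .inf_safe(obj$rpd); obj$rer <- .inf_safe(obj$rer)
  obj$rpiq <- .inf_safe(obj$rpiq)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

.inf_safe <- function(x) if (is.infinite(x)) "Inf" else x
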