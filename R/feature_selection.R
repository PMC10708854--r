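#' Fuse per-method wavelength rankings by majority voting
#'
#' A waveband is selected when at least `threshold` of the methods in
#' the ranking table retained it.  Selected bands are ordered by vote
#' count (descending), then by their average rank among the methods
#' that retained them (ascending), then by band index.
#'
#' @param rt a [ranking_table()] with `K >= 1` methods.
#' @param threshold minimum vote count, or `"majority"` (the default)
#'   for the strict majority `floor(K/2) + 1`.
#' @return List of class `fusion_result` with elements `selected`
#'   (integer vector of band indices in selection order), `votes` and
#'   `mean_rank` (named over all voted bands), `threshold`, and
#'   `n_methods`.
#' @examples
#' rt <- ranking_table(data.frame(
#'   method = c("a", "a", "b"), band_index = c(3, 5, 3), rank = c(1, 2, 1)))
#' fuse_rankings(rt, threshold = 2)$selected
#' @export
fuse_rankings <- function(rt, threshold = "majority") {
  stopifnot(inherits(rt, "ranking_table"))
  methods <- unique(rt$method)
  K <- length(methods)
  if (K < 1) stop("ranking table has no methods", call. = FALSE)
  if (identical(threshold, "majority")) {
    threshold <- K %/% 2L + 1L
  }
  threshold <- as.integer(threshold)
  if (threshold < 1L || threshold > K) {
    stop(sprintf("threshold must lie in 1..%d", K), call. = FALSE)
  }
  votes <- integer(18)
  rank_sum <- numeric(18)
  for (i in seq_len(nrow(rt))) {
    b <- rt$band_index[i]
    votes[b] <- votes[b] + 1L
    rank_sum[b] <- rank_sum[b] + rt$rank[i]
  }
  voted <- which(votes > 0)
  mean_rank <- rank_sum[voted] / votes[voted]
  names(mean_rank) <- voted
  v <- votes[voted]; names(v) <- voted
  sel <- voted[votes[voted] >= threshold]
  if (length(sel) > 0) {
    ord <- order(-votes[sel], rank_sum[sel] / votes[sel], sel)
    sel <- sel[ord]
  }
  structure(list(selected = as.integer(sel), votes = v,
                 mean_rank = mean_rank, threshold = threshold,
                 n_methods = K,
                 statistic = attr(rt, "statistic")),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("fusion_result (%s block): %d of 18 bands selected at threshold %d/%d\n",
              if (is.null(x$statistic)) "?" else x$statistic,
              length(x$selected), x$threshold, x$n_methods))
  if (length(x$selected)) {
    cat("  bands:", paste(x$selected, collapse = ", "), "\n")
    cat("  nm:   ", paste(waveband_nm(x$selected), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Registered wavelength-ranking methods
#'
#' @return Character vector of the method identifiers accepted by
#'   [rank_features()]: `boruta` (shadow-feature random-forest test),
#'   `rfe` (recursive feature elimination with random forests),
#'   `ga` (genetic-algorithm subset search), `stepwise` (AIC stepwise
#'   linear regression), `lasso` (cross-validated L1 regression),
#'   `relimp` (LMG relative importance decomposition), and
#'   `plsr` (partial-least-squares coefficient filter).
#' @export
fs_methods <- function() {
  c("boruta", "rfe", "ga", "stepwise", "lasso", "relimp", "plsr")
}

#' Rank wavebands by a single feature-selection method
#'
#' Runs one ranking method on a feature block of a dataset and returns a
#' one-method [ranking_table()]: the bands the method retained, ranked
#' 1..m by decreasing importance.  A method may legitimately retain no
#' band (e.g. the lasso under full shrinkage); the result is then an
#' empty table carrying `attr(, "empty") = TRUE`.
#'
#' @param ds a [spectral_dataset()] with `tvc` present.
#' @param method one of [fs_methods()].
#' @param block feature block, `"mean"` or `"sd"`.
#' @param n_keep maximum number of bands to retain (default 8); methods
#'   with their own stopping rule (boruta, stepwise, lasso) may keep fewer.
#' @param seed integer seed for the stochastic methods.
#' @param ... method-specific settings: `ntree` (forest size, default
#'   200) for boruta/rfe; `pop_size` (default 30), `generations`
#'   (default 20), `p_crossover` (default 0.8), `p_mutation` (default
#'   0.1) for ga; `n_perm` (default 200) for the sampled LMG
#'   decomposition; `ncomp` (default 2) for plsr.
#' @return A one-method [ranking_table()].
#' @export
rank_features <- function(ds, method, block = c("mean", "sd"),
                          n_keep = 8, seed = 1, ...) {
  block <- match.arg(block)
  if (!method %in% fs_methods()) {
    stop(sprintf("unknown ranking method '%s'; see fs_methods()", method),
         call. = FALSE)
  }
  y <- ds$tvc
  if (all(is.na(y))) stop("dataset has no tvc targets", call. = FALSE)
  keep <- !is.na(y)
  X <- feature_matrix(ds, block)[keep, , drop = FALSE]
  y <- y[keep]
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  scores <- switch(method,
    boruta = .rank_boruta(X, y, ...),
    rfe = .rank_rfe(X, y, n_keep = n_keep, ...),
    ga = .rank_ga(X, y, n_keep = n_keep, ...),
    stepwise = .rank_stepwise(X, y, ...),
    lasso = .rank_lasso(X, y, ...),
    relimp = .rank_relimp(X, y, ...),
    plsr = .rank_plsr(X, y, ...)
  )
  # scores: named numeric over retained band indices, larger = better
  if (length(scores) > n_keep && !method %in% c("boruta", "stepwise", "lasso")) {
    scores <- sort(scores, decreasing = TRUE)[seq_len(n_keep)]
  }
  bands <- as.integer(names(scores))
  ord <- order(-scores, bands)
  df <- data.frame(method = rep(method, length(bands)),
                   band_index = bands[ord],
                   rank = seq_along(bands))
  rt <- ranking_table(df, statistic = block)
  attr(rt, "empty") <- length(bands) == 0
  rt
}

# --- individual rankers ----------------------------------------------------
# Scores are returned as a named vector over the 1..18 band indices the
# method retains; names are the indices, larger score = more important.

# Shadow-feature test in the spirit of Boruta: across `runs` forests, a
# band is confirmed when its permutation importance beats the best
# shadow (permuted-copy) importance in a clear majority of runs.
.rank_boruta <- function(X, y, ntree = 200, runs = 15) {
  p <- ncol(X)
  hits <- integer(p)
  imp_sum <- numeric(p)
  for (r in seq_len(runs)) {
    shadow <- apply(X, 2, sample)
    colnames(shadow) <- paste0("shadow", seq_len(p))
    rf <- randomForest::randomForest(cbind(X, shadow), y, ntree = ntree,
                                     importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1]
    shadow_max <- max(imp[(p + 1):(2 * p)])
    hits <- hits + as.integer(imp[seq_len(p)] > shadow_max)
    imp_sum <- imp_sum + imp[seq_len(p)]
  }
  confirmed <- which(hits > runs / 2)
  stats::setNames(imp_sum[confirmed] / runs, confirmed)
}

# Backward recursive elimination with random-forest importance; the
# survivors of the last round are ranked by their final importance.
.rank_rfe <- function(X, y, n_keep = 8, ntree = 200) {
  active <- seq_len(ncol(X))
  while (length(active) > n_keep) {
    rf <- randomForest::randomForest(X[, active, drop = FALSE], y,
                                     ntree = ntree, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1]
    drop_n <- max(1L, floor(length(active) * 0.2))
    drop_n <- min(drop_n, length(active) - n_keep)
    active <- active[order(imp, decreasing = TRUE)][
      seq_len(length(active) - drop_n)]
    active <- sort(active)
  }
  rf <- randomForest::randomForest(X[, active, drop = FALSE], y,
                                   ntree = ntree, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  stats::setNames(as.numeric(imp), active)
}

# Compact generational GA over band subsets; fitness is the AIC of the
# linear model on the subset (lower is fitter).  Survivors of the best
# chromosome are ranked by |t|-statistic.
.rank_ga <- function(X, y, n_keep = 8, pop_size = 30, generations = 20,
                     p_crossover = 0.8, p_mutation = 0.1) {
  p <- ncol(X)
  fitness <- function(mask) {
    if (!any(mask)) return(Inf)
    fit <- stats::lm(y ~ ., data = data.frame(y = y, X[, mask, drop = FALSE]))
    stats::AIC(fit)
  }
  pop <- matrix(stats::runif(pop_size * p) < 0.4, nrow = pop_size)
  fit_v <- apply(pop, 1, fitness)
  for (g in seq_len(generations)) {
    new_pop <- pop
    for (i in seq(1, pop_size - 1, by = 2)) {
      # tournament selection of two parents
      pick <- function() {
        cand <- sample(pop_size, 2)
        cand[which.min(fit_v[cand])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      if (stats::runif(1) < p_crossover) {
        cut <- sample(p - 1, 1)
        child_a <- c(pa[1:cut], pb[(cut + 1):p])
        child_b <- c(pb[1:cut], pa[(cut + 1):p])
      } else {
        child_a <- pa; child_b <- pb
      }
      flip <- stats::runif(p) < p_mutation
      child_a <- xor(child_a, flip)
      flip <- stats::runif(p) < p_mutation
      child_b <- xor(child_b, flip)
      new_pop[i, ] <- child_a
      new_pop[i + 1, ] <- child_b
    }
    new_fit <- apply(new_pop, 1, fitness)
    # elitism: keep the incumbent best
    worst <- which.max(new_fit)
    best <- which.min(fit_v)
    new_pop[worst, ] <- pop[best, ]
    new_fit[worst] <- fit_v[best]
    pop <- new_pop; fit_v <- new_fit
  }
  mask <- pop[which.min(fit_v), ]
  sel <- which(mask)
  if (length(sel) == 0) return(stats::setNames(numeric(0), integer(0)))
  fit <- stats::lm(y ~ ., data = data.frame(y = y, X[, sel, drop = FALSE]))
  tv <- abs(summary(fit)$coefficients[-1, "t value"])
  stats::setNames(as.numeric(tv), sel)
}

# Forward-backward stepwise linear regression under AIC; bands are
# ranked by entry order into the final model.
.rank_stepwise <- function(X, y) {
  df <- data.frame(y = y, X)
  colnames(df) <- c("y", paste0("b", seq_len(ncol(X))))
  null_fit <- stats::lm(y ~ 1, data = df)
  full <- stats::as.formula(paste("y ~", paste(colnames(df)[-1], collapse = "+")))
  fit <- stats::step(null_fit, scope = list(lower = ~1, upper = full),
                     direction = "both", trace = 0)
  terms_in <- attr(stats::terms(fit), "term.labels")
  if (length(terms_in) == 0) return(stats::setNames(numeric(0), integer(0)))
  # entry order from the step history
  hist <- fit$anova$Step
  entered <- sub("^\\+ ", "", hist[grepl("^\\+", hist)])
  entered <- entered[entered %in% terms_in]
  entered <- c(entered, setdiff(terms_in, entered))
  bands <- as.integer(sub("^b", "", entered))
  stats::setNames(rev(seq_along(bands)), bands)  # first entered = best
}

# Cross-validated lasso; nonzero coefficients at lambda.min ranked by
# magnitude on standardised predictors.
.rank_lasso <- function(X, y, lambda = NULL) {
  nfolds <- min(10, max(3, nrow(X) %/% 3))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = nfolds,
                          standardize = TRUE)
  lam <- if (is.null(lambda)) cv$lambda.min else lambda
  co <- as.numeric(stats::coef(cv$glmnet.fit, s = lam))[-1]
  co_std <- co * apply(X, 2, stats::sd)
  sel <- which(abs(co) > 0)
  stats::setNames(abs(co_std[sel]), sel)
}

# LMG relative importance: average sequential R^2 contribution over
# orderings; exact over all subsets for p <= 12, otherwise a seeded
# Monte-Carlo average over random permutations.
.rank_relimp <- function(X, y, n_perm = 200) {
  p <- ncol(X)
  contrib <- numeric(p)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(stats::lm(y ~ ., data = data.frame(y = y,
                                               X[, cols, drop = FALSE])))$r.squared
  }
  if (p <= 12) {
    # exact Shapley decomposition over all subsets
    r2_cache <- new.env(hash = TRUE)
    r2_of <- function(cols) {
      key <- paste(cols, collapse = ",")
      if (!is.null(r2_cache[[key]])) return(r2_cache[[key]])
      val <- r2(cols)
      r2_cache[[key]] <- val
      val
    }
    for (j in seq_len(p)) {
      others <- setdiff(seq_len(p), j)
      for (s in 0:length(others)) {
        subsets <- if (s == 0) list(integer(0)) else
          utils::combn(others, s, simplify = FALSE)
        w <- factorial(s) * factorial(p - s - 1) / factorial(p)
        for (S in subsets) {
          contrib[j] <- contrib[j] + w * (r2_of(sort(c(S, j))) - r2_of(S))
        }
      }
    }
  } else {
    for (b in seq_len(n_perm)) {
      perm <- sample(p)
      prev <- 0
      cols <- integer(0)
      for (j in perm) {
        cols <- c(cols, j)
        cur <- r2(cols)
        contrib[j] <- contrib[j] + (cur - prev) / n_perm
        prev <- cur
      }
    }
  }
  stats::setNames(contrib, seq_len(p))
}

# PLSR coefficient filter: bands ranked by the magnitude of their
# standardised NIPALS regression coefficient; near-zero coefficients
# (relative to the largest) are not retained.
.rank_plsr <- function(X, y, ncomp = 2) {
  fit <- nipals_pls(X, y, ncomp = min(ncomp, ncol(X), nrow(X) - 1),
                    scale = TRUE)
  beta_std <- fit$coefficients * fit$x_scale
  mag <- abs(beta_std)
  sel <- which(mag > 1e-8 * max(mag, .Machine$double.eps))
  stats::setNames(mag[sel], sel)
}

#' Principal-component baseline for a feature block
#'
#' Covariance-based PCA of one 18-band feature block, the conventional
#' unsupervised alternative to wavelength selection: the leading
#' components (typically 5-6 here) can be fed to a regressor in place of
#' selected bands.
#'
#' @param ds a [spectral_dataset()].
#' @param block feature block, `"mean"` or `"sd"`.
#' @param k number of components to retain, `1 <= k <= 18`.
#' @return List of class `pc_baseline` with `loadings` (18 x k,
#'   orthonormal), `eigenvalues` (k, non-increasing), `cum_prop`
#'   (cumulative explained-variance proportions over the k components),
#'   and `scores` (n x k transformed features).
#' @export
pca_baseline <- function(ds, block = c("mean", "sd"), k = 6) {
  block <- match.arg(block)
  if (k < 1 || k > 18) stop("k must lie in 1..18", call. = FALSE)
  X <- feature_matrix(ds, block)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k_eff <- min(k, length(ev))
  total <- sum(ev)
  structure(list(loadings = pc$rotation[, seq_len(k_eff), drop = FALSE],
                 eigenvalues = ev[seq_len(k_eff)],
                 cum_prop = cumsum(ev)[seq_len(k_eff)] / total,
                 scores = pc$x[, seq_len(k_eff), drop = FALSE]),
            class = "pc_baseline")
}
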