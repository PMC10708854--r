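# Independent oracles used across the suite.  These are deliberately
# written as plain loops / closed forms, separate from the package's
# implementation paths.

# straight-loop implementation of every validation metric
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  se <- 0; ae <- 0; lr_sum <- 0; lr_abs <- 0; pe_sum <- 0
  for (i in seq_len(n)) {
    se <- se + (y[i] - yhat[i])^2
    ae <- ae + abs(y[i] - yhat[i])
    lr_sum <- lr_sum + log10(yhat[i] / y[i])
    lr_abs <- lr_abs + abs(log10(yhat[i] / y[i]))
    pe_sum <- pe_sum + 100 * abs(y[i] - yhat[i]) / y[i]
  }
  rmse <- sqrt(se / n)
  ybar <- sum(y) / n
  sd_y <- sqrt(sum((y - ybar)^2) / (n - 1))
  ps <- sort(y)
  q_type7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    ps[lo] + (h - lo) * (ps[min(lo + 1, n)] - ps[lo])
  }
  iq <- q_type7(0.75) - q_type7(0.25)
  pbar <- sum(yhat) / n
  sd_p <- sqrt(sum((yhat - pbar)^2) / (n - 1))
  pooled <- sqrt(((n - 1) * sd_y^2 + (n - 1) * sd_p^2) / (2 * n))
  r <- sum((y - ybar) * (yhat - pbar)) / ((n - 1) * sd_y * sd_p)
  list(rmse = rmse,
       mae = ae / n,
       mape_pct = pe_sum / n,
       ape = pe_sum,
       sep_pct = 100 * rmse / ybar,
       bf = 10^(lr_sum / n),
       af = 10^(lr_abs / n),
       rpd = sd_y / rmse,
       rer = (max(y) - min(y)) / rmse,
       rpiq = iq / rmse,
       theta = (ybar - pbar) / sd_y,
       cohens_d = (ybar - pbar) / pooled,
       r_squared = r^2)
}

# brute-force vote counting over all 18 bands
oracle_fuse <- function(rt, threshold) {
  votes <- sapply(1:18, function(b) sum(rt$band_index == b))
  mean_rank <- sapply(1:18, function(b) {
    r <- rt$rank[rt$band_index == b]
    if (length(r)) mean(r) else NA
  })
  sel <- which(votes >= threshold)
  sel[order(-votes[sel], mean_rank[sel], sel)]
}

# plain alternating-optimisation FCM returning the final objective
oracle_fcm_objective <- function(X, centers, m = 2, iters = 200) {
  X <- as.matrix(X); C <- as.matrix(centers)
  n <- nrow(X); cc <- nrow(C)
  for (it in seq_len(iters)) {
    U <- matrix(0, cc, n)
    for (k in seq_len(n)) {
      d2 <- sapply(seq_len(cc), function(i) sum((X[k, ] - C[i, ])^2))
      if (any(d2 < 1e-300)) {
        U[d2 < 1e-300, k] <- 1 / sum(d2 < 1e-300)
      } else {
        for (i in seq_len(cc)) {
          U[i, k] <- 1 / sum((d2[i] / d2)^(1 / (m - 1)))
        }
      }
    }
    for (i in seq_len(cc)) {
      w <- U[i, ]^m
      C[i, ] <- colSums(w * X) / sum(w)
    }
  }
  obj <- 0
  for (k in seq_len(n)) for (i in seq_len(cc)) {
    obj <- obj + U[i, k]^m * sum((X[k, ] - C[i, ])^2)
  }
  obj
}

# forward pass of a symmetric-Gaussian TSK system (plain loops)
oracle_tsk_forward <- function(X, centers, spreads, weights) {
  X <- as.matrix(X)
  n <- nrow(X); cc <- nrow(centers); q <- ncol(X)
  out <- numeric(n)
  for (k in seq_len(n)) {
    R <- numeric(cc)
    for (i in seq_len(cc)) {
      prod_a <- 1
      for (j in seq_len(q)) {
        prod_a <- prod_a *
          exp(-(X[k, j] - centers[i, j])^2 / (2 * spreads[i, j]^2))
      }
      R[i] <- prod_a
    }
    rbar <- R / sum(R)
    f <- numeric(cc)
    for (i in seq_len(cc)) {
      f[i] <- sum(weights[i, 1:q] * X[k, ]) + weights[i, q + 1]
    }
    out[k] <- sum(rbar * f)
  }
  out
}

# the two printed ranking tables, loaded from the packaged encodings
table_mean_rankings <- function() {
  read_ranking_table(system.file("extdata", "rankings_mean.csv",
                                 package = "msitvc"), statistic = "mean")
}
table_sd_rankings <- function() {
  read_ranking_table(system.file("extdata", "rankings_sd.csv",
                                 package = "msitvc"), statistic = "sd")
}

# a small reference TSK system shared by several tests
toy_rules <- function() {
  list(list(center = c(0, 0), spread = c(1, 1), weights = c(1, -1, 0.5)),
       list(center = c(1, -1), spread = c(0.5, 0.8), weights = c(-0.3, 0.2, 2)))
}

toy_partition <- function(n) {
  structure(list(centers = rbind(c(0, 0), c(1, -1)),
                 U = matrix(0.5, 2, n),
                 sigma_init = rbind(c(1, 1), c(0.5, 0.8)),
                 fuzzifier = 2),
            class = "fuzzy_partition")
}
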