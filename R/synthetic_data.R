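#' Baranyi-Roberts growth parameters
#'
#' Parameter set for the primary (Baranyi-Roberts) growth model combined
#' with a Ratkowsky square-root secondary model for the temperature
#' dependence of the maximum specific growth rate.  Defaults emulate
#' aerobic beef spoilage flora stored at chill to mild-abuse
#' temperatures: counts start near 3.06 and plateau near 9.89 log10 cfu
#' cm^-2, and the rate is referenced at 16 degC so that spoilage is
#' reached within roughly 80 h at 16 degC but only approached after
#' 400+ h at 0 degC.
#'
#' @param y0 initial TVC, log10 cfu cm^-2.
#' @param ymax asymptotic TVC, log10 cfu cm^-2.
#' @param mu_ref maximum specific growth rate at `T_ref`, log10 units per hour.
#' @param h0 dimensionless Baranyi lag parameter (physiological state).
#' @param T_min notional minimum growth temperature, degC.
#' @param T_ref reference temperature for `mu_ref`, degC.
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(y0 = 3.06, ymax = 9.89, mu_ref = 0.085,
                          h0 = 1.0, T_min = -10, T_ref = 16) {
  stopifnot(y0 < ymax, mu_ref > 0, h0 >= 0, T_ref > T_min)
  structure(list(y0 = y0, ymax = ymax, mu_ref = mu_ref, h0 = h0,
                 T_min = T_min, T_ref = T_ref),
            class = "growth_params")
}

#' Baranyi-Roberts TVC at a given storage time and temperature
#'
#' Computes `y(t) = y0 + mu*A(t) - log10(1 + (10^(mu*A(t)) - 1) /
#' 10^(ymax - y0))` with the Baranyi adjustment function
#' `A(t) = t + (1/mu_hat) * log(exp(-mu_hat*t) + exp(-h0) -
#' exp(-mu_hat*t - h0))`, where `mu_hat` is the natural-log-scale rate.
#' The square-root secondary model scales the rate with temperature:
#' `mu(T) = mu_ref * ((T - T_min)/(T_ref - T_min))^2`.
#'
#' @param t storage time in hours (vectorised), `>= 0`.
#' @param temperature storage temperature in degC, must exceed `gp$T_min`.
#' @param gp a [growth_params()] object.
#' @return TVC in log10 cfu cm^-2, same length as `t`.
#' @examples
#' gp <- growth_params()
#' baranyi_tvc(c(0, 100, 400), temperature = 4, gp = gp)
#' @export
baranyi_tvc <- function(t, temperature, gp = growth_params()) {
  stopifnot(inherits(gp, "growth_params"))
  if (any(t < 0)) stop("storage time must be non-negative", call. = FALSE)
  if (temperature <= gp$T_min) {
    stop(sprintf("temperature must exceed T_min = %g degC", gp$T_min),
         call. = FALSE)
  }
  mu <- gp$mu_ref * ((temperature - gp$T_min) / (gp$T_ref - gp$T_min))^2
  mu_hat <- mu * log(10)
  # log-sum-exp guard: exp(-mu_hat*t) underflows for large t
  a <- -mu_hat * t
  b <- rep(-gp$h0, length(t))
  ab <- pmax(a, b)
  lag_term <- ab + log(exp(a - ab) + exp(b - ab) - exp(a + b - ab))
  A <- t + lag_term / mu_hat
  muA <- mu * A
  # y = y0 + muA - log10(1 + (10^muA - 1)/10^(ymax - y0)), stabilised
  d <- gp$ymax - gp$y0
  y <- gp$y0 + muA - log10(1 + (10^muA - 1) / 10^d)
  # for very large muA the direct form saturates exactly at ymax
  y[!is.finite(y)] <- gp$ymax
  pmin(y, gp$ymax)
}

#' Spectral response parameters for the synthetic generator
#'
#' Describes how each waveband's reflectance features are coupled to the
#' underlying TVC: `feature = baseline + slope*tvc + quad*tvc^2 +
#' N(0, noise_sd)`.  Defaults give the visible bands (405-700 nm) of the
#' mean block a clear positive coupling, leave most near-infrared bands
#' flat, and give the sd block a weaker coupling concentrated on the
#' mid-visible bands, so that wavelength selection has genuine signal to
#' find and genuinely irrelevant bands to reject.
#'
#' @param baseline_mean,slope_mean,quad_mean length-18 vectors for the
#'   mean-reflectance block (intercept, linear and quadratic coupling in
#'   TVC, reflectance units).
#' @param baseline_sd,slope_sd,quad_sd analogous vectors for the
#'   standard-deviation block.
#' @param noise_sd_mean,noise_sd_sd additive Gaussian noise scale for
#'   each block, reflectance units.
#' @return A list of class `spectral_response_params`.
#' @export
spectral_response_params <- function(
    baseline_mean = c(12, 14, 15, 17, 20, 22, 25, 26, 28, 29, 30, 32,
                      45, 44, 43, 42, 41, 40),
    slope_mean = c(2.4, 2.0, 0.3, 0.0, 2.8, 0.3, 2.2, 1.8, 3.0, 0.4,
                   2.6, 3.2, 0.0, 0.0, -0.4, 0.0, 0.0, 0.0),
    quad_mean = rep(0, 18),
    baseline_sd = c(3.0, 3.2, 3.4, 3.6, 3.8, 4.0, 4.2, 4.4, 4.6, 4.8,
                    5.0, 5.2, 6.0, 6.0, 6.0, 6.0, 6.0, 6.0),
    slope_sd = c(0.0, 0.1, 0.0, 0.9, 0.7, 0.8, 0.6, 1.1, 0.0, 0.0,
                 0.1, 0.8, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    quad_sd = rep(0, 18),
    noise_sd_mean = 1.0,
    noise_sd_sd = 0.35) {
  for (v in list(baseline_mean, slope_mean, quad_mean,
                 baseline_sd, slope_sd, quad_sd)) {
    if (length(v) != 18) stop("response vectors must have length 18",
                              call. = FALSE)
  }
  stopifnot(noise_sd_mean >= 0, noise_sd_sd >= 0)
  structure(list(baseline_mean = baseline_mean, slope_mean = slope_mean,
                 quad_mean = quad_mean, baseline_sd = baseline_sd,
                 slope_sd = slope_sd, quad_sd = quad_sd,
                 noise_sd_mean = noise_sd_mean, noise_sd_sd = noise_sd_sd),
            class = "spectral_response_params")
}

#' Generate a synthetic multispectral spoilage dataset
#'
#' Simulates a storage trial: for each temperature, `n_per_temp`
#' specimens are sampled on an evenly spaced schedule spanning storage
#' from time zero until the growth curve at that temperature approaches
#' its plateau (capped at `t_max` hours), their TVC is computed from the
#' Baranyi-Roberts model and their 36 reflectance features from the
#' affine (optionally quadratic) spectral coupling plus Gaussian noise.
#'
#' @param n_per_temp specimens per storage temperature (default 17, so
#'   the default five temperatures give 85 samples).
#' @param temps storage temperatures in degC (default `c(0,4,8,12,16)`).
#' @param sampling_hours optional list (one numeric vector per
#'   temperature) of sampling times; `NULL` (default) derives an
#'   evenly spaced schedule per temperature as described above.
#' @param gp a [growth_params()] object.
#' @param sp a [spectral_response_params()] object.
#' @param seed integer seed; identical arguments give identical datasets.
#' @param t_max latest sampling time in hours (default 434).
#' @return A [spectral_dataset()] with `tvc` present for every sample.
#' @examples
#' ds <- generate_dataset(n_per_temp = 3, seed = 1)
#' nrow(ds)
#' @export
generate_dataset <- function(n_per_temp = 17, temps = c(0, 4, 8, 12, 16),
                             sampling_hours = NULL,
                             gp = growth_params(),
                             sp = spectral_response_params(),
                             seed = 1, t_max = 434) {
  if (length(temps) == 0) stop("temps must be non-empty", call. = FALSE)
  stopifnot(n_per_temp >= 1)
  if (!is.null(sampling_hours) && length(sampling_hours) != length(temps)) {
    stop("sampling_hours must have one schedule per temperature",
         call. = FALSE)
  }
  rows <- list()
  k <- 0L
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  for (i in seq_along(temps)) {
    temp <- temps[i]
    if (is.null(sampling_hours)) {
      # end the schedule where the curve reaches 99% of its span, capped
      mu <- gp$mu_ref * ((temp - gp$T_min) / (gp$T_ref - gp$T_min))^2
      t_end <- min(t_max, (gp$ymax - gp$y0) / mu + gp$h0 / (mu * log(10)))
      hours <- seq(0, t_end, length.out = n_per_temp)
    } else {
      hours <- sampling_hours[[i]]
    }
    tvc <- baranyi_tvc(hours, temperature = temp, gp = gp)
    for (j in seq_along(hours)) {
      k <- k + 1L
      mean_feat <- sp$baseline_mean + sp$slope_mean * tvc[j] +
        sp$quad_mean * tvc[j]^2 +
        stats::rnorm(18, 0, sp$noise_sd_mean)
      sd_feat <- sp$baseline_sd + sp$slope_sd * tvc[j] +
        sp$quad_sd * tvc[j]^2 +
        stats::rnorm(18, 0, sp$noise_sd_sd)
      row <- c(list(sample_id = sprintf("S%03d_T%02d", k, as.integer(round(temp))),
                    temperature_C = temp, storage_time_h = hours[j]),
               as.list(stats::setNames(mean_feat, feature_cols("mean"))),
               as.list(stats::setNames(sd_feat, feature_cols("sd"))),
               list(tvc = tvc[j]))
      rows[[k]] <- as.data.frame(row, check.names = FALSE)
    }
  }
  spectral_dataset(do.call(rbind, rows))
}

#' Generate data from a known zero-order TSK fuzzy system
#'
#' Draws inputs uniformly over a box and evaluates a fully specified
#' Takagi-Sugeno system (symmetric Gaussian memberships, product rules,
#' normalised defuzzification with affine consequents), adding Gaussian
#' noise to the targets.  Used for parameter-recovery tests of the
#' neuro-fuzzy regressor: the forward evaluation here is an independent,
#' loop-based implementation.
#'
#' @param n number of samples.
#' @param rules list of rules, each a list with `center` (length q),
#'   `spread` (length q, the total Gaussian spread b) and `weights`
#'   (length q+1: q linear coefficients then the bias).
#' @param noise_sd Gaussian noise standard deviation on the targets.
#' @param seed integer seed.
#' @param x_range length-2 numeric, the common sampling interval for
#'   every input coordinate.
#' @return List with matrix `X` (n x q) and numeric `y` (length n).
#' @export
generate_tsk_dataset <- function(n, rules, noise_sd = 0, seed = 1,
                                 x_range = c(-2, 2)) {
  if (length(rules) < 1) stop("at least one rule is required", call. = FALSE)
  q <- length(rules[[1]]$center)
  for (r in rules) {
    if (length(r$center) != q || length(r$spread) != q ||
        length(r$weights) != q + 1) {
      stop("rule dimensions are inconsistent", call. = FALSE)
    }
    if (any(r$spread <= 0)) stop("rule spreads must be positive", call. = FALSE)
  }
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  X <- matrix(stats::runif(n * q, x_range[1], x_range[2]), nrow = n)
  colnames(X) <- paste0("x", seq_len(q))
  y <- vapply(seq_len(n), function(k) {
    strengths <- vapply(rules, function(r) {
      prod(exp(-(X[k, ] - r$center)^2 / (2 * r$spread^2)))
    }, numeric(1))
    s <- sum(strengths)
    rbar <- if (s > 0) strengths / s else rep(1 / length(rules), length(rules))
    f <- vapply(rules, function(r) {
      sum(r$weights[seq_len(q)] * X[k, ]) + r$weights[q + 1]
    }, numeric(1))
    sum(rbar * f)
  }, numeric(1))
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  list(X = X, y = y)
}

# Save/restore .Random.seed so generators do not disturb the caller's RNG.
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
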