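#' Encoding-model rate functions
#'
#' Four rate models describe how a neuron's firing in the post-cue window
#' depends on the movement direction theta (degrees, measured from the
#' neuron's preferred direction and wrapped to (-180, 180]) and the start
#' position (x, y) (mm on the wall):
#'
#' * `direction`:  f(theta) = b0 + b1 * N(theta; 0, sigma)
#' * `start_plane`: f(x, y) = b0 + b1 x + b2 y
#' * `gain_field`: f(theta, x, y) = b0 + (b1 x + b2 y) * N(theta; 0, sigma)
#' * `additive`:   f(theta, x, y) = b0 + (b1 x + b2 y) + b3 * N(theta; 0, sigma)
#'
#' where N is the normalized Gaussian density (1 / (sigma sqrt(2 pi)))
#' exp(-theta^2 / (2 sigma^2)) with sigma in degrees, so the b coefficients
#' multiplying N carry Hz x degree units.
#'
#' @param kind Model kind.
#' @param par Named parameter vector (`b0`, `b1`, `b2`, `b3`, `sigma` as
#'   applicable).
#' @param theta Direction relative to preferred, degrees.
#' @param x,y Start-position coordinates, mm.
#' @return Predicted rate in Hz (may be negative for invalid parameters;
#'   the fitter penalizes and the predictor floors at a small positive
#'   value).
#' @export
encoding_rate <- function(kind, par, theta, x, y) {
  switch(kind,
    direction = par["b0"] + par["b1"] * gauss_angle(theta, par["sigma"]),
    start_plane = par["b0"] + par["b1"] * x + par["b2"] * y,
    gain_field = par["b0"] +
      (par["b1"] * x + par["b2"] * y) * gauss_angle(theta, par["sigma"]),
    additive = par["b0"] + par["b1"] * x + par["b2"] * y +
      par["b3"] * gauss_angle(theta, par["sigma"]),
    stop("unknown encoding model kind: ", kind)
  )
}

model_parnames <- function(kind) {
  switch(kind,
    direction = c("b0", "b1", "sigma"),
    start_plane = c("b0", "b1", "b2"),
    gain_field = c("b0", "b1", "b2", "sigma"),
    additive = c("b0", "b1", "b2", "b3", "sigma"))
}

model_bounds <- function(kind, scale, family = "poisson") {
  # scale: rough data scale (max mean rate, Hz) used to bound amplitudes
  amp <- max(10 * scale, 10)
  b0_lo <- if (family == "poisson") 0 else -100
  lower <- c(b0 = b0_lo, b1 = -amp, b2 = -amp, b3 = -amp * 300, sigma = 10)
  upper <- c(b0 = 100, b1 = amp, b2 = amp, b3 = amp * 300, sigma = 180)
  if (kind == "direction") {
    lower["b1"] <- -amp * 300; upper["b1"] <- amp * 300
  }
  nm <- model_parnames(kind)
  list(lower = lower[nm], upper = upper[nm])
}

model_start_values <- function(kind, y_rate, theta, x, y, restarts, scale) {
  # deterministic, moment-based first guess + random restarts
  nm <- model_parnames(kind)
  base <- c(b0 = mean(y_rate), b1 = 0, b2 = 0, b3 = 0, sigma = 45)
  if (kind == "direction") {
    base["b1"] <- (max(y_rate) - mean(y_rate)) * 45 * sqrt(2 * pi)
  }
  if (kind %in% c("start_plane", "additive")) {
    cf <- stats::coef(stats::lm(y_rate ~ x + y))
    base["b0"] <- max(cf[1], 0); base["b1"] <- cf[2]; base["b2"] <- cf[3]
    if (kind == "additive") {
      base["b3"] <- (max(y_rate) - mean(y_rate)) * 45 * sqrt(2 * pi)
    }
  }
  if (kind == "gain_field") {
    g <- gauss_angle(theta, 45)
    cf <- stats::coef(stats::lm(y_rate ~ I(x * g) + I(y * g)))
    base["b0"] <- max(cf[1], 0); base["b1"] <- cf[2]; base["b2"] <- cf[3]
  }
  inits <- list(base[nm])
  if (restarts > 1) {
    for (r in seq_len(restarts - 1)) {
      jit <- base[nm] * stats::runif(length(nm), 0.3, 1.7) +
        stats::rnorm(length(nm), 0, 0.2 * max(scale, 1))
      if ("sigma" %in% nm) jit["sigma"] <- stats::runif(1, 15, 120)
      if ("b0" %in% nm) jit["b0"] <- abs(jit["b0"])
      inits[[r + 1]] <- jit
    }
  }
  inits
}

fit_model_mle <- function(kind, y, theta, x, y_pos, width,
                          restarts = 5, family = c("poisson", "gaussian")) {
  family <- match.arg(family)
  scale <- max(abs(mean(y)) / width, 0.1)
  y_rate <- y / width
  bounds <- model_bounds(kind, scale, family)
  nll <- function(par) {
    names(par) <- model_parnames(kind)
    f <- encoding_rate(kind, par, theta, x, y_pos)
    if (family == "poisson") {
      # keep the rate non-negative on the data
      pen <- 1e4 * sum(pmin(f, 0)^2)
      lam <- pmax(f, 1e-6) * width
      sum(lam - y * log(lam)) + pen
    } else {
      sum((y - f * width)^2)
    }
  }
  inits <- model_start_values(kind, y_rate, theta, x, y_pos, restarts, scale)
  best <- NULL
  for (p0 in inits) {
    p0 <- pmin(pmax(p0, bounds$lower), bounds$upper)
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  par <- best$par
  names(par) <- model_parnames(kind)
  list(par = par, value = best$value)
}

stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    i <- which(strata == s)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Fit an encoding model to windowed spike counts
#'
#' Maximum-likelihood fit (Poisson spike counts, bounded quasi-Newton
#' optimization with multiple starts) of one of the four encoding models to
#' counts in a fixed window (canonically 0--500 ms after cue onset). The
#' preferred direction is computed first from the direction tuning curve
#' (vector sum) and held fixed; theta is each trial's direction minus it.
#' The cross-validated R-squared pools held-out predictions over
#' `k_folds` folds stratified by (direction x start) condition.
#'
#' @param counts A `count_matrix`.
#' @param kind `"direction"`, `"start_plane"`, `"gain_field"` or
#'   `"additive"`.
#' @param wall A `port_wall`.
#' @param k_folds Cross-validation folds (20 at full scale).
#' @param seed Integer seed (fold assignment and restart jitter).
#' @param restarts Optimizer restarts per fit.
#' @param theta0 Preferred direction in degrees; computed from the data if
#'   `NULL`.
#' @param family `"poisson"` (spike counts) or `"gaussian"` (continuous
#'   activity, e.g. network hidden units).
#' @return An `encoding_fit`: list with `kind`, `par`, `theta0`, `cv_r2`,
#'   `r2` (training R-squared), `width`.
#' @export
fit_encoding_model <- function(counts, kind, wall = build_port_wall(),
                               k_folds = 20, seed = 1, restarts = 5,
                               theta0 = NULL, family = "poisson") {
  w <- attr(counts, "window")
  width <- w$t1 - w$t0
  if (nrow(counts) < k_folds) stop("fewer trials than folds")
  if (is.null(theta0)) {
    theta0 <- preferred_direction(
      tuning_curve(counts, "direction", direction_angles()))
    if (is.na(theta0)) theta0 <- 0
  }
  co <- variable_coordinates(counts, wall)
  theta <- wrap_angle(counts$direction - theta0)
  y <- counts$count
  set.seed(seed)
  full <- fit_model_mle(kind, y, theta, co$start_x, co$start_y, width,
                        restarts = restarts, family = family)
  if (is.null(full)) {
    return(structure(list(kind = kind, failed = TRUE), class = "encoding_fit"))
  }
  floor_rate <- function(f) if (family == "poisson") pmax(f, 1e-6) else f
  fitted_rate <- floor_rate(encoding_rate(kind, full$par, theta, co$start_x,
                                          co$start_y))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - fitted_rate * width)^2) / sst
  strata <- paste(counts$direction, counts$start_port)
  fold <- stratified_folds(strata, k_folds)
  pred <- rep(NA_real_, length(y))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    fit <- fit_model_mle(kind, y[tr], theta[tr], co$start_x[tr],
                         co$start_y[tr], width, restarts = restarts,
                         family = family)
    if (is.null(fit)) next
    pred[!tr] <- floor_rate(encoding_rate(kind, fit$par, theta[!tr],
                                          co$start_x[!tr],
                                          co$start_y[!tr])) * width
  }
  ok <- !is.na(pred)
  cv_r2 <- 1 - sum((y[ok] - pred[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
  structure(
    list(kind = kind, par = full$par, theta0 = theta0, cv_r2 = cv_r2,
         r2 = r2, width = width, failed = FALSE),
    class = "encoding_fit"
  )
}

#' Fit and cross-validate all four encoding models for one neuron
#'
#' @inheritParams fit_encoding_model
#' @return Named numeric vector of CV R-squared for `direction`,
#'   `start_plane`, `gain_field`, `additive`, with the fits in the
#'   `"fits"` attribute.
#' @export
fit_all_encoding_models <- function(counts, wall = build_port_wall(),
                                    k_folds = 20, seed = 1, restarts = 5,
                                    family = "poisson") {
  theta0 <- preferred_direction(
    tuning_curve(counts, "direction", direction_angles()))
  if (is.na(theta0)) theta0 <- 0
  kinds <- c("direction", "start_plane", "gain_field", "additive")
  fits <- lapply(kinds, function(k) {
    fit_encoding_model(counts, k, wall, k_folds = k_folds, seed = seed,
                       restarts = restarts, theta0 = theta0,
                       family = family)
  })
  names(fits) <- kinds
  out <- vapply(fits, function(f) if (isTRUE(f$failed)) NA_real_ else f$cv_r2,
                numeric(1))
  attr(out, "fits") <- fits
  out
}

clip_unit <- function(x) pmin(pmax(x, -1 + 1e-10), 1 - 1e-10)

#' Population comparison of encoding models
#'
#' Neurons whose mean CV R-squared over the four models exceeds
#' `include_threshold` are compared pairwise: the statistic is the mean
#' difference of Fisher-z-transformed CV R-squared (values clipped into
#' (-1, 1) before atanh), with a one-sided bootstrap p (fraction of
#' bootstrap means at or below zero) and a 95% percentile CI. Best-model
#' fractions are reported with binomial CIs, plus a sweep of the inclusion
#' threshold.
#'
#' @param cv_r2 Matrix neurons x 4 models (columns `direction`,
#'   `start_plane`, `gain_field`, `additive`).
#' @param n_boot Bootstrap resamples (10^5 at full scale).
#' @param seed Integer seed.
#' @param include_threshold Inclusion threshold on the mean CV R-squared.
#' @param sweep Thresholds for the best-model-fraction sweep.
#' @return List with `pairs` (data frame: `m1`, `m2`, `mean_delta_z`, `lo`,
#'   `hi`, `p`, `p_floor`), `best` (per-included-neuron best model),
#'   `best_fractions`, `included` (logical), `sweep`.
#' @export
compare_models <- function(cv_r2, n_boot = 1e5, seed = 1,
                           include_threshold = 0.05,
                           sweep = seq(0, 0.2, by = 0.05)) {
  stopifnot(is.matrix(cv_r2), ncol(cv_r2) == 4)
  models <- colnames(cv_r2)
  included <- rowMeans(cv_r2) > include_threshold & !apply(is.na(cv_r2), 1, any)
  if (sum(included) < 2) stop("fewer than 2 neurons pass the inclusion rule")
  z <- atanh(clip_unit(cv_r2[included, , drop = FALSE]))
  set.seed(seed)
  n <- nrow(z)
  boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  pairs <- utils::combn(models, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    m1 <- pairs[1, k]; m2 <- pairs[2, k]
    d <- z[, m1] - z[, m2]
    if (mean(d) < 0) { tmp <- m1; m1 <- m2; m2 <- tmp; d <- -d }
    bm <- colMeans(matrix(d[boot_idx], n, n_boot))
    p <- mean(bm <= 0)
    data.frame(m1 = m1, m2 = m2, mean_delta_z = mean(d),
               lo = unname(stats::quantile(bm, 0.025)),
               hi = unname(stats::quantile(bm, 0.975)),
               p = p, p_floor = max(p, 1 / n_boot))
  })
  best <- models[max.col(cv_r2[included, , drop = FALSE], ties.method = "first")]
  bf <- vapply(models, function(m) mean(best == m), numeric(1))
  sweep_df <- do.call(rbind, lapply(sweep, function(th) {
    inc <- rowMeans(cv_r2) > th & !apply(is.na(cv_r2), 1, any)
    if (sum(inc) < 1) return(NULL)
    b <- models[max.col(cv_r2[inc, , drop = FALSE], ties.method = "first")]
    data.frame(threshold = th, n = sum(inc),
               t(vapply(models, function(m) mean(b == m), numeric(1))))
  }))
  list(pairs = do.call(rbind, rows), best = best, best_fractions = bf,
       included = included, sweep = sweep_df)
}

#' Synthetic recovery harness for the encoding-model comparison
#'
#' Generates additive- and gain-field-tuned synthetic populations, fits all
#' four encoding models to each neuron in the post-cue window, and reports
#' the best-model confusion among included neurons together with the
#' pairwise additive-vs-gain-field bootstrap comparison within each class.
#'
#' @param n_per_class Neurons per generative class.
#' @param design A [session_design()].
#' @param n_trials Trials in the generated session.
#' @param seed Integer seed.
#' @param k_folds,restarts,n_boot Passed through to the fitting and
#'   comparison routines.
#' @param window Count window (default 0--500 ms post cue).
#' @return List per class (`gain_field`, `additive`) with `cv_r2`,
#'   `comparison` and `majority_correct` (logical: generative model wins
#'   the best-fit vote among included neurons).
#' @export
recovery_harness <- function(n_per_class = 50, design = session_design("reference"),
                             n_trials = 480, seed = 1, k_folds = 10,
                             restarts = 3, n_boot = 2000,
                             window = window_spec("cue", 0, 0.5, "post_cue_500")) {
  out <- list()
  for (class in c("gain_field", "additive")) {
    pop <- generate_population(stats::setNames(n_per_class, class), design,
                               n_trials, seed = seed + (class == "additive"),
                               p_error = 0, p_violation = 0)
    cvr <- t(vapply(seq_along(pop$neurons), function(i) {
      cm <- count_spikes(pop$neurons[[i]], pop$trials, window)
      fit_all_encoding_models(cm, pop$wall, k_folds = k_folds,
                              seed = seed + i, restarts = restarts)
    }, numeric(4)))
    colnames(cvr) <- c("direction", "start_plane", "gain_field", "additive")
    cmp <- compare_models(cvr, n_boot = n_boot, seed = seed)
    out[[class]] <- list(
      cv_r2 = cvr, comparison = cmp,
      majority_correct = cmp$best_fractions[class] ==
        max(cmp$best_fractions) && cmp$best_fractions[class] > 0.5)
  }
  out
}
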