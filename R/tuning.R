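#' Peri-event time histograms with a causal kernel
#'
#' Single-trial spike trains are convolved with a causal half-Gaussian
#' kernel (400 ms standard deviation, support on the past only, normalized
#' to unit integral), so the rate estimate at time t is driven only by
#' spikes at or before t; the effective smoothing matches a ~200 ms full
#' Gaussian. Trials are then averaged within groups.
#'
#' @param spikes A `spike_data`.
#' @param trials A `trial_table`.
#' @param align Alignment event (see [window_spec()]).
#' @param t_grid Time grid in s relative to the event.
#' @param group Optional factor/vector (length = trials) to average within;
#'   default one group.
#' @param kernel_sd Kernel standard deviation in s (default 0.4).
#' @param correct_only Keep only correct trials.
#' @return List with `t` (grid), `rate` (matrix groups x time, Hz), `se`
#'   (matching standard errors) and `n` (trials per group).
#' @export
compute_peth <- function(spikes, trials, align = "go",
                         t_grid = seq(-1, 1, by = 0.02), group = NULL,
                         kernel_sd = 0.4, correct_only = TRUE) {
  keep <- if (correct_only) trials$outcome == "correct" else rep(TRUE, nrow(trials))
  ev <- trials[[align_column(align)]]
  keep <- keep & !is.na(ev)
  idx <- which(keep)
  g <- if (is.null(group)) rep("all", nrow(trials)) else group
  g <- factor(g[idx])
  # causal half-Gaussian: k(u) = 2 * dnorm(u, 0, sd) for u >= 0
  trial_rate <- t(vapply(idx, function(i) {
    ts <- spikes$spikes[[i]] - ev[i]
    if (!length(ts)) return(numeric(length(t_grid)))
    colSums(outer(ts, t_grid, function(s, t) {
      u <- t - s
      ifelse(u >= 0, 2 * stats::dnorm(u, 0, kernel_sd), 0)
    }))
  }, numeric(length(t_grid))))
  rate <- rowsum(trial_rate, g) / as.vector(table(g))
  se <- t(vapply(levels(g), function(l) {
    x <- trial_rate[g == l, , drop = FALSE]
    apply(x, 2, stats::sd) / sqrt(nrow(x))
  }, numeric(length(t_grid))))
  list(t = t_grid, rate = rate, se = se, n = as.vector(table(g)))
}

#' Tuning curve of a neuron over a spatial variable
#'
#' Mean firing rate (count / window width) per level of the variable.
#'
#' @param counts A `count_matrix`.
#' @param variable `"start"`, `"direction"` or `"target"`.
#' @param levels Optional complete level set (e.g. `0:6` for ports) so
#'   absent levels appear as `NA`.
#' @return A `tuning_curve`: data frame with `level`, `rate` (Hz), `n`.
#' @export
tuning_curve <- function(counts, variable, levels = NULL) {
  w <- attr(counts, "window")
  width <- w$t1 - w$t0
  lab <- variable_labels(counts, variable)
  if (!is.null(levels)) lab <- factor(as.character(lab), levels = as.character(levels))
  mu <- tapply(counts$count, lab, mean) / width
  out <- data.frame(level = names(mu), rate = as.numeric(mu),
                    n = as.integer(table(lab)))
  attr(out, "variable") <- variable
  class(out) <- c("tuning_curve", "data.frame")
  out
}

#' Preferred direction of a neuron
#'
#' The angle of the rate-weighted vector sum of the six movement-direction
#' unit vectors. If the resultant has (near-)zero length the preferred
#' direction is undefined and `NA` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param curve A [tuning_curve()] over the direction levels (angles in
#'   degrees), or a named numeric vector of rates with angle names.
#' @return Angle in degrees in (-180, 180], or `NA` if undefined.
#' @export
preferred_direction <- function(curve) {
  if (inherits(curve, "tuning_curve")) {
    ang <- as.numeric(curve$level); rate <- curve$rate
  } else {
    ang <- as.numeric(names(curve)); rate <- as.numeric(curve)
  }
  ok <- !is.na(rate)
  ang <- ang[ok]; rate <- rate[ok]
  vx <- sum(rate * cos(ang * pi / 180))
  vy <- sum(rate * sin(ang * pi / 180))
  len <- sqrt(vx^2 + vy^2)
  if (len < 1e-9 * max(sum(rate), 1e-12)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  wrap_angle(atan2(vy, vx) * 180 / pi)
}

#' Classify a preferred angle as horizontal / vertical, up / down
#'
#' Horizontal means within 45 degrees of 0 or 180; downward means within 90
#' degrees of straight down.
#'
#' @param angle Angle in degrees.
#' @return Named logical vector `horizontal`, `vertical`, `downward`,
#'   `upward`.
#' @export
classify_direction <- function(angle) {
  a <- wrap_angle(angle)
  horiz <- abs(a) <= 45 | abs(wrap_angle(a - 180)) <= 45
  down <- a < 0
  c(horizontal = unname(horiz), vertical = unname(!horiz),
    downward = unname(down), upward = unname(a > 0))
}

#' Preferred position of a neuron
#'
#' The port with the highest mean firing rate; ties go to the lowest port
#' id (flagged via the `tie` attribute).
#'
#' @param curve A [tuning_curve()] over the 7 ports.
#' @return Port id (integer).
#' @export
preferred_position <- function(curve) {
  rate <- curve$rate
  best <- which(rate == max(rate, na.rm = TRUE))
  structure(as.integer(curve$level[best[1]]), tie = length(best) > 1)
}

#' Start-target tuning correlation
#'
#' Pearson correlation between the start-position tuning curve in one
#' window (default pre-cue) and the target-position tuning curve in another
#' (default arrival), over the 7 ports. With `split_half = TRUE` trials are
#' randomly halved; start tuning from one half is correlated with target
#' tuning from the other half (and vice versa) and the two coefficients are
#' averaged, removing within-trial noise coupling.
#'
#' @param spikes A `spike_data`.
#' @param trials A `trial_table`.
#' @param window_start,window_target [window_spec()]s for the two tunings.
#' @param split_half Use the split-half estimator.
#' @param seed Seed for the random split.
#' @return Pearson r (NA with attribute `undefined = TRUE` if either tuning
#'   vector has zero variance).
#' @export
start_target_correlation <- function(spikes, trials,
                                     window_start = key_windows()$pre_cue,
                                     window_target = key_windows()$arrival,
                                     split_half = FALSE, seed = 1) {
  cs <- count_spikes(spikes, trials, window_start)
  ct <- count_spikes(spikes, trials, window_target)
  curve_pair_correlation(cs, ct, "start", "target", split_half, seed)
}

safe_cor <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(a, b)
}

curve_pair_correlation <- function(counts_a, counts_b, var_a, var_b,
                                   split_half, seed) {
  levels_a <- if (var_a == "direction") direction_angles() else 0:6
  levels_b <- if (var_b == "direction") direction_angles() else 0:6
  if (!split_half) {
    ca <- tuning_curve(counts_a, var_a, levels_a)
    cb <- tuning_curve(counts_b, var_b, levels_b)
    return(safe_cor(ca$rate, cb$rate))
  }
  set.seed(seed)
  ids <- union(counts_a$trial_id, counts_b$trial_id)
  half <- sample(ids, floor(length(ids) / 2))
  sub <- function(cm, in_half) {
    out <- cm[if (in_half) cm$trial_id %in% half else !cm$trial_id %in% half, ]
    attr(out, "window") <- attr(cm, "window")
    class(out) <- class(cm)
    out
  }
  r1 <- safe_cor(tuning_curve(sub(counts_a, TRUE), var_a, levels_a)$rate,
                 tuning_curve(sub(counts_b, FALSE), var_b, levels_b)$rate)
  r2 <- safe_cor(tuning_curve(sub(counts_a, FALSE), var_a, levels_a)$rate,
                 tuning_curve(sub(counts_b, TRUE), var_b, levels_b)$rate)
  mean(c(r1, r2), na.rm = TRUE)
}

#' Bootstrap test that a population's mean Fisher-z correlation exceeds zero
#'
#' Correlations are Fisher-z transformed (values at +-1 are clipped to
#' +-(1 - 1e-10)); the p value is the fraction of bootstrap resamples whose
#' mean z lies at or below zero, optionally Bonferroni-multiplied. `p_floor`
#' applies the 1/n_boot minimum-reportable-p convention.
#'
#' @param r Vector of correlation coefficients (one per neuron).
#' @param n_boot Number of bootstrap resamples (default 10^4).
#' @param seed Integer seed.
#' @param bonferroni Number of simultaneous comparisons.
#' @return List with `p` (raw fraction, times `bonferroni`, capped at 1),
#'   `p_floor`, `mean_z`, `n`.
#' @export
fisher_z_population_test <- function(r, n_boot = 10000, seed = 1,
                                     bonferroni = 1) {
  r <- r[!is.na(r)]
  z <- atanh(pmin(pmax(r, -1 + 1e-10), 1 - 1e-10))
  set.seed(seed)
  n <- length(z)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(z[sample.int(n, replace = TRUE)]),
                  numeric(1))
  p <- min(1, mean(means <= 0) * bonferroni)
  list(p = p, p_floor = max(p, min(1, bonferroni / n_boot)),
       mean_z = mean(z), n = n)
}

#' Time of switching from start-position to target-position coding
#'
#' Start- and target-position GLM R-squared curves are computed in causal
#' sliding windows, each smoothed with a 3-bin moving average; the switch
#' time is the first window after the positive peak of
#' `R2(start) - R2(target)` at which the difference turns negative. `NA`
#' (with attribute `reason`) is returned when there is no positive peak or
#' no subsequent crossing.
#'
#' @param spikes A `spike_data`.
#' @param trials A `trial_table`.
#' @param align Alignment event (default the go sound).
#' @param from,to,step,width Sliding-window layout in s.
#' @return Switch time in s relative to the event, or `NA`.
#' @export
switch_time <- function(spikes, trials, align = "go", from = -0.6, to = 1,
                        step = 0.05, width = 0.3) {
  wins <- sliding_windows(align, from, to, step, width)
  if (length(wins) < 5) stop("too few windows to estimate a switch time")
  tc <- selectivity_timecourse(spikes, trials, wins)
  smooth3 <- function(x) stats::filter(x, rep(1 / 3, 3), sides = 2)
  d <- as.numeric(smooth3(tc$r2_start) - smooth3(tc$r2_target))
  t <- tc$time
  ok <- which(!is.na(d))
  d <- d[ok]; t <- t[ok]
  if (!any(d > 0)) return(structure(NA_real_, reason = "no positive peak"))
  peak <- which.max(d)
  after <- which(d < 0 & seq_along(d) > peak)
  if (!length(after)) return(structure(NA_real_, reason = "no crossing"))
  t[after[1]]
}

#' Shrinkage (MAP) firing-rate estimate per movement trajectory
#'
#' Per-trajectory mean rates regularized toward the all-trial grand mean:
#' a conjugate gamma prior with mean equal to the grand mean rate and a
#' pseudo-count weight of `prior_weight` trials gives the posterior-mean
#' rate `(sum counts + prior_weight * grand mean count) / (n + prior_weight)`.
#' Trajectories with many trials stay near their sample mean; sparse ones
#' shrink toward the grand mean; absent trajectories are `NA`.
#'
#' @param counts A `count_matrix` (e.g. 0--500 ms post-cue).
#' @param wall A `port_wall` (to enumerate the trajectory grid).
#' @param prior_weight Prior pseudo-count in trials (default 1).
#' @return Data frame over the direction x target grid with `direction`,
#'   `target_port`, `n`, `rate_map` (Hz, `NA` where absent) and `rate_raw`.
#' @export
map_rate_heatmap <- function(counts, wall = build_port_wall(),
                             prior_weight = 1) {
  w <- attr(counts, "window")
  width <- w$t1 - w$t0
  grand <- mean(counts$count)
  grid <- expand.grid(direction = direction_angles(), target_port = 0:6)
  key <- paste(counts$direction, counts$target_port)
  gkey <- paste(grid$direction, grid$target_port)
  f <- factor(key, levels = gkey)
  grid$n <- as.integer(table(f))
  sums <- vapply(split(counts$count, f), sum, numeric(1))
  grid$rate_map <- ifelse(grid$n > 0,
                          (sums + prior_weight * grand) /
                            (grid$n + prior_weight) / width, NA_real_)
  grid$rate_raw <- ifelse(grid$n > 0, sums / pmax(grid$n, 1) / width, NA_real_)
  grid
}

#' Cross-time tuning-correlation matrix for a population
#'
#' For every pair of windows, computes each neuron's split-half correlation
#' between the tuning curve for `var_a` at window i and `var_b` at window j,
#' averages across neurons, and marks cells whose mean Fisher-z is
#' significantly above zero (bootstrap, Bonferroni-corrected over all
#' cells). With `var_a = var_b` and identical window sets this is the
#' tuning-stability matrix.
#'
#' @param neurons List of `spike_data`.
#' @param trials A `trial_table`.
#' @param windows List of [window_spec()]s.
#' @param var_a,var_b Variables for the row and column tuning curves.
#' @param n_boot Bootstrap resamples per cell.
#' @param alpha Significance level (before Bonferroni).
#' @param seed Integer seed.
#' @return List with `mean_r` (windows x windows), `p` (Bonferroni-scaled)
#'   and `significant` matrices.
#' @export
tuning_correlation_matrix <- function(neurons, trials, windows,
                                      var_a = "direction", var_b = var_a,
                                      n_boot = 2000, alpha = 0.05, seed = 1) {
  nw <- length(windows)
  counts_a <- lapply(windows, function(w) {
    lapply(neurons, count_spikes, trials = trials, window = w)
  })
  counts_b <- if (identical(var_a, var_b)) counts_a else counts_a
  mean_r <- p <- matrix(NA_real_, nw, nw)
  for (i in seq_len(nw)) {
    for (j in seq_len(nw)) {
      r <- vapply(seq_along(neurons), function(k) {
        curve_pair_correlation(counts_a[[i]][[k]], counts_b[[j]][[k]],
                               var_a, var_b, split_half = TRUE,
                               seed = seed + k)
      }, numeric(1))
      mean_r[i, j] <- mean(r, na.rm = TRUE)
      p[i, j] <- fisher_z_population_test(r, n_boot = n_boot,
                                          seed = seed + i * nw + j,
                                          bonferroni = nw * nw)$p
    }
  }
  labs <- vapply(windows, `[[`, character(1), "label")
  dimnames(mean_r) <- dimnames(p) <- list(labs, labs)
  list(mean_r = mean_r, p = p, significant = p < alpha)
}

#' @rdname tuning_correlation_matrix
#' @export
direction_stability_matrix <- function(neurons, trials, windows,
                                       n_boot = 2000, alpha = 0.05,
                                       seed = 1) {
  tuning_correlation_matrix(neurons, trials, windows, "direction",
                            "direction", n_boot = n_boot, alpha = alpha,
                            seed = seed)
}

#' Warped per-trial time windows spanning the whole trial
#'
#' Fourteen windows per trial: three fixed 300 ms windows covering the
#' 900 ms before cue onset, three equal divisions of cue-to-go, five equal
#' divisions of go-to-arrival, and three fixed 300 ms windows covering the
#' 900 ms after arrival.
#'
#' @param trials A `trial_table`.
#' @return List with `bounds` (array trials x 14 x 2 of absolute times) and
#'   `labels`.
#' @export
warped_windows <- function(trials) {
  n <- nrow(trials)
  cue <- trials$t_cue_on; go <- trials$t_go; arr <- trials$t_arrival
  bounds <- array(NA_real_, c(n, 14, 2))
  for (k in 1:3) {
    bounds[, k, 1] <- cue - 0.3 * (4 - k)
    bounds[, k, 2] <- cue - 0.3 * (3 - k)
  }
  for (k in 1:3) {
    bounds[, 3 + k, 1] <- cue + (go - cue) * (k - 1) / 3
    bounds[, 3 + k, 2] <- cue + (go - cue) * k / 3
  }
  for (k in 1:5) {
    bounds[, 6 + k, 1] <- go + (arr - go) * (k - 1) / 5
    bounds[, 6 + k, 2] <- go + (arr - go) * k / 5
  }
  for (k in 1:3) {
    bounds[, 11 + k, 1] <- arr + 0.3 * (k - 1)
    bounds[, 11 + k, 2] <- arr + 0.3 * k
  }
  labels <- c(paste0("pre_cue", 1:3), paste0("cue_go", 1:3),
              paste0("go_arr", 1:5), paste0("post_arr", 1:3))
  list(bounds = bounds, labels = labels)
}

#' Firing rates of one neuron in warped windows
#'
#' @param spikes A `spike_data`.
#' @param trials A `trial_table`.
#' @param correct_only Keep only correct trials.
#' @return Matrix trials x 14 of rates (Hz); rows for excluded trials are
#'   dropped. Row names give trial ids.
#' @export
warped_rates <- function(spikes, trials, correct_only = TRUE) {
  ww <- warped_windows(trials)
  keep <- if (correct_only) trials$outcome == "correct" else rep(TRUE, nrow(trials))
  keep <- keep & stats::complete.cases(ww$bounds[, , 1], ww$bounds[, , 2])
  idx <- which(keep)
  out <- matrix(NA_real_, length(idx), 14,
                dimnames = list(trials$trial_id[idx], ww$labels))
  for (r in seq_along(idx)) {
    i <- idx[r]
    ts <- spikes$spikes[[i]]
    a <- ww$bounds[i, , 1]; b <- ww$bounds[i, , 2]
    out[r, ] <- vapply(1:14, function(k) {
      sum(ts > a[k] & ts <= b[k]) / (b[k] - a[k])
    }, numeric(1))
  }
  out
}
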