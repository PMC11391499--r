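decoding_conditions <- function(variable, wall) {
  if (variable %in% c("start", "target")) {
    lv <- 0:6
    xy <- port_xy(wall, lv)
    data.frame(level = lv, x = xy[, 1], y = xy[, 2])
  } else if (variable == "direction") {
    ang <- direction_angles()
    data.frame(level = ang,
               x = wall$spacing * cos(ang * pi / 180),
               y = wall$spacing * sin(ang * pi / 180))
  } else stop("variable must be 'start', 'direction' or 'target'")
}

condition_column <- function(variable) {
  switch(variable, start = "start_port", direction = "direction",
         target = "target_port")
}

#' Build a pseudopopulation for decoding one spatial variable
#'
#' For each neuron (drawn with replacement from the eligible pool — the
#' neuron-level bootstrap, leaving about 63.2% unique neurons), correct
#' trials of each condition are split into two folds and `n_per_fold`
#' pseudo-trials are resampled with replacement per fold per condition,
#' with an independent seed per neuron so trial-by-trial correlations
#' across neurons are destroyed. Position variables have 7 conditions
#' (224 pseudo-trials per fold at the default 32); direction has 6
#' (192 per fold).
#'
#' @param population List with `trials`, `neurons`, `wall`.
#' @param variable `"start"`, `"direction"` or `"target"`.
#' @param seed Integer seed.
#' @param n_per_fold Pseudo-trials per fold per condition (default 32).
#' @param min_trials Minimum correct trials per condition for a neuron to be
#'   eligible (default 8).
#' @param bootstrap_neurons Resample neurons with replacement (default
#'   `TRUE`).
#' @return A `pseudopopulation`: list with `variable`, `labels` (condition
#'   per pseudo-trial), `coords` (x, y per pseudo-trial, mm), `fold`,
#'   `trial_rows` (pseudo-trials x neuron draws matrix of trial-table row
#'   indices), `neuron_draw` (indices into `population$neurons`).
#' @export
build_pseudopopulation <- function(population, variable, seed = 1,
                                   n_per_fold = 32, min_trials = 8,
                                   bootstrap_neurons = TRUE) {
  trials <- population$trials
  wall <- population$wall
  cond <- decoding_conditions(variable, wall)
  col <- condition_column(variable)
  correct <- which(trials$outcome == "correct")
  lab <- trials[[col]][correct]
  rows_per_cond <- lapply(cond$level, function(l) correct[lab == l])
  n_per_cond <- lengths(rows_per_cond)
  if (any(n_per_cond < min_trials)) {
    stop("session has fewer than ", min_trials,
         " correct trials for condition ", cond$level[which.min(n_per_cond)])
  }
  n_neurons <- length(population$neurons)
  set.seed(seed)
  draw <- if (bootstrap_neurons) sort(sample.int(n_neurons, replace = TRUE))
          else seq_len(n_neurons)
  k <- nrow(cond)
  n_pseudo <- 2 * k * n_per_fold
  fold <- rep(1:2, each = k * n_per_fold)
  cond_idx <- rep(rep(seq_len(k), each = n_per_fold), 2)
  trial_rows <- matrix(0L, n_pseudo, length(draw))
  for (j in seq_along(draw)) {
    set.seed(seed + 7919L * j)  # independent resampling per neuron
    for (c in seq_len(k)) {
      rows <- rows_per_cond[[c]]
      half <- sample(seq_along(rows), floor(length(rows) / 2))
      f1 <- rows[half]; f2 <- rows[-half]
      sel <- cond_idx == c
      trial_rows[sel & fold == 1, j] <- sample(f1, n_per_fold, replace = TRUE)
      trial_rows[sel & fold == 2, j] <- sample(f2, n_per_fold, replace = TRUE)
    }
  }
  structure(
    list(variable = variable, labels = cond$level[cond_idx],
         coords = cbind(x = cond$x[cond_idx], y = cond$y[cond_idx]),
         fold = fold, trial_rows = trial_rows, neuron_draw = draw,
         n_per_fold = n_per_fold),
    class = "pseudopopulation"
  )
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat("<pseudopopulation>", x$variable, "-",
      nrow(x$trial_rows) / 2, "pseudo-trials/fold,",
      length(x$neuron_draw), "neuron draws (",
      length(unique(x$neuron_draw)), "unique )\n")
  invisible(x)
}

# counts per trial-table row for every neuron at one window (NA where the
# event is missing); rows index the trial table directly
population_counts <- function(population, window) {
  trials <- population$trials
  ev <- trials[[align_column(window$align)]]
  vapply(population$neurons, function(nr) {
    out <- rep(NA_real_, nrow(trials))
    ok <- !is.na(ev)
    out[ok] <- vapply(which(ok), function(i) {
      ts <- nr$spikes[[i]]
      sum(ts > ev[i] + window$t0 & ts <= ev[i] + window$t1)
    }, numeric(1))
    out
  }, numeric(nrow(trials)))
}

pseudo_count_matrix <- function(pp, counts_by_row) {
  n <- nrow(pp$trial_rows)
  X <- matrix(0, n, length(pp$neuron_draw))
  for (j in seq_along(pp$neuron_draw)) {
    X[, j] <- counts_by_row[pp$trial_rows[, j], pp$neuron_draw[j]]
  }
  X
}

# combined z-score + PCA (train and test pooled, as in the source analyses),
# then multivariate OLS from PC scores to coordinates
pca_regression_errors <- function(X_train, Y_train, X_test, Y_test, n_pcs) {
  Z <- rbind(X_train, X_test)
  mu <- colMeans(Z)
  sd <- apply(Z, 2, stats::sd)
  keep <- sd > 0
  if (sum(keep) < n_pcs) stop("rank-deficient pseudopopulation counts")
  Z <- sweep(sweep(Z[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  S <- pc$x[, seq_len(n_pcs), drop = FALSE]
  n_tr <- nrow(X_train)
  S_tr <- S[seq_len(n_tr), , drop = FALSE]
  S_te <- S[-seq_len(n_tr), , drop = FALSE]
  B <- stats::lm.fit(cbind(1, S_tr), Y_train)$coefficients
  pred <- cbind(1, S_te) %*% B
  list(pred = pred, err = sqrt(rowSums((pred - Y_test)^2)))
}

#' Decode 2D coordinates from a pseudopopulation in one window
#'
#' Spike counts of the two folds are combined, z-scored and reduced to the
#' first `n_pcs` principal components; a multivariate linear regression
#' from PC scores to the (x, y) coordinates is trained on one fold and
#' tested on the other (both directions, two-fold cross-validation). The
#' summary error excludes conditions at the (0, 0) coordinate for position
#' variables (decoders collapse toward the origin, flattering that
#' condition).
#'
#' @param pp A [build_pseudopopulation()] result.
#' @param population The population it was built from.
#' @param window A [window_spec()].
#' @param n_pcs Number of principal components (default 4).
#' @param counts_by_row Optional precomputed [population] count matrix for
#'   this window (trials x neurons), to reuse across calls.
#' @return A `decoding_result`: list with `pred` (pseudo-trials x 2),
#'   `errors`, `mean_error` (excluding origin conditions where applicable),
#'   `variable`, `window`.
#' @export
decode_window <- function(pp, population, window, n_pcs = 4,
                          counts_by_row = NULL) {
  if (is.null(counts_by_row)) {
    counts_by_row <- population_counts(population, window)
  }
  X <- pseudo_count_matrix(pp, counts_by_row)
  if (anyNA(X)) stop("pseudo-trials reference trials missing the '",
                     window$align, "' event")
  f1 <- pp$fold == 1
  r1 <- pca_regression_errors(X[f1, ], pp$coords[f1, ], X[!f1, ],
                              pp$coords[!f1, ], n_pcs)
  r2 <- pca_regression_errors(X[!f1, ], pp$coords[!f1, ], X[f1, ],
                              pp$coords[f1, ], n_pcs)
  pred <- matrix(NA_real_, nrow(X), 2)
  err <- numeric(nrow(X))
  pred[!f1, ] <- r1$pred; err[!f1] <- r1$err
  pred[f1, ] <- r2$pred; err[f1] <- r2$err
  keep <- rep(TRUE, nrow(X))
  if (pp$variable %in% c("start", "target")) {
    keep <- !(pp$coords[, 1] == 0 & pp$coords[, 2] == 0)
  }
  structure(
    list(pred = pred, errors = err, mean_error = mean(err[keep]),
         excluded_origin = !all(keep), variable = pp$variable,
         window = window),
    class = "decoding_result"
  )
}

#' Decoding-error difference between two variables across time
#'
#' Builds `n_pseudo` paired pseudopopulations per variable, decodes both in
#' each sliding window, and summarizes the per-pseudopopulation paired
#' error difference (`var_a` minus `var_b`; positive favours `var_b`) as
#' mean +- s.d., with a sign-flip permutation p per window.
#'
#' @param population List with `trials`, `neurons`, `wall`.
#' @param var_a,var_b The two variables.
#' @param windows List of [window_spec()]s.
#' @param n_pseudo Number of pseudopopulations (100 at full scale).
#' @param n_pcs Principal components per decoder.
#' @param n_perm Sign-flip permutations for the per-window p value.
#' @param seed Integer seed.
#' @return Data frame per window: `time`, `label`, `mean_delta`, `sd_delta`,
#'   `p` (two-sided sign-flip).
#' @export
delta_error_timecourse <- function(population, var_a, var_b, windows,
                                   n_pseudo = 20, n_pcs = 4, n_perm = 5000,
                                   seed = 1) {
  err <- function(variable) {
    sapply(seq_len(n_pseudo), function(i) {
      pp <- build_pseudopopulation(population, variable,
                                   seed = seed + 131L * i)
      vapply(windows, function(w) {
        decode_window(pp, population, w, n_pcs = n_pcs)$mean_error
      }, numeric(1))
    })
  }
  ea <- err(var_a)  # windows x n_pseudo
  eb <- err(var_b)
  delta <- ea - eb
  set.seed(seed + 99991L)
  rows <- lapply(seq_along(windows), function(k) {
    d <- delta[k, ]
    obs <- mean(d)
    null <- vapply(seq_len(n_perm), function(i) {
      mean(d * sample(c(-1, 1), length(d), replace = TRUE))
    }, numeric(1))
    data.frame(time = windows[[k]]$t1, label = windows[[k]]$label,
               mean_delta = obs, sd_delta = stats::sd(d),
               p = mean(abs(null) >= abs(obs)))
  })
  out <- do.call(rbind, rows)
  attr(out, "delta") <- delta
  out
}

#' Cross-window (and cross-variable) decoding-error matrix
#'
#' Decoders are trained on counts from one window and tested on another
#' (two-fold cross-validation; the combined z-score/PCA basis is fit on the
#' pooled train and test counts). Significance uses the extreme-pixel
#' permutation test: one label-shuffled map is generated per
#' pseudopopulation; because smaller error is better, the extreme statistic
#' per shuffled map is its minimum error, and a cell of the averaged
#' observed map is significant when it beats every shuffled extreme
#' (p < 1/n_pseudo).
#'
#' @param population List with `trials`, `neurons`, `wall`.
#' @param variable Variable to decode (training variable in cross-variable
#'   mode).
#' @param windows_train,windows_test Lists of [window_spec()]s.
#' @param n_pseudo Number of pseudopopulations.
#' @param n_pcs Principal components.
#' @param test_variable Optional second variable: train on `variable`
#'   pseudo-trials, test on `test_variable` pseudo-trials (e.g. train start
#'   / test target).
#' @param seed Integer seed.
#' @return List with `mean_error` (train x test windows), `threshold` (the
#'   best shuffled extreme), `significant` and `per_pseudo` (array).
#' @export
cross_window_matrix <- function(population, variable, windows_train,
                                windows_test = windows_train, n_pseudo = 20,
                                n_pcs = 4, test_variable = NULL, seed = 1) {
  nt <- length(windows_train); ns <- length(windows_test)
  all_wins <- c(windows_train, windows_test)
  labs <- vapply(all_wins, `[[`, character(1), "label")
  uniq <- !duplicated(labs)
  counts_cache <- lapply(all_wins[uniq], function(w)
    population_counts(population, w))
  names(counts_cache) <- labs[uniq]
  obs <- array(NA_real_, c(n_pseudo, nt, ns))
  null_extreme <- numeric(n_pseudo)
  cross <- !is.null(test_variable)
  for (i in seq_len(n_pseudo)) {
    pp_tr <- build_pseudopopulation(population, variable,
                                    seed = seed + 131L * i)
    pp_te <- if (cross) {
      pe <- build_pseudopopulation(population, test_variable,
                                   seed = seed + 131L * i + 17L)
      pe$neuron_draw <- pp_tr$neuron_draw  # same neuron bootstrap both sides
      pe
    } else pp_tr
    run_map <- function(coords_tr, coords_te) {
      m <- matrix(NA_real_, nt, ns)
      keep <- rep(TRUE, sum(pp_te$fold == 1))
      if (pp_te$variable %in% c("start", "target")) {
        cte <- coords_te[pp_te$fold == 1, , drop = FALSE]
        keep <- !(cte[, 1] == 0 & cte[, 2] == 0)
      }
      for (a in seq_len(nt)) {
        Xa <- pseudo_count_matrix(pp_tr,
                counts_cache[[windows_train[[a]]$label]])
        for (b in seq_len(ns)) {
          Xb <- pseudo_count_matrix(pp_te,
                  counts_cache[[windows_test[[b]]$label]])
          e <- numeric(0)
          for (f in 1:2) {
            tr <- pp_tr$fold == f
            te <- pp_te$fold != f
            r <- pca_regression_errors(Xa[tr, , drop = FALSE],
                                       coords_tr[tr, , drop = FALSE],
                                       Xb[te, , drop = FALSE],
                                       coords_te[te, , drop = FALSE],
                                       n_pcs)
            e <- c(e, r$err[keep])
          }
          m[a, b] <- mean(e)
        }
      }
      m
    }
    obs[i, , ] <- run_map(pp_tr$coords, pp_te$coords)
    # one shuffled map per pseudopopulation: permute condition labels
    set.seed(seed + 131L * i + 31L)
    shuf_tr <- permute_condition_coords(pp_tr)
    shuf_te <- if (cross) permute_condition_coords(pp_te) else shuf_tr
    null_extreme[i] <- min(run_map(shuf_tr, shuf_te))
  }
  mean_error <- apply(obs, c(2, 3), mean)
  dimnames(mean_error) <- list(
    vapply(windows_train, `[[`, character(1), "label"),
    vapply(windows_test, `[[`, character(1), "label"))
  threshold <- min(null_extreme)
  list(mean_error = mean_error, threshold = threshold,
       significant = mean_error < threshold, per_pseudo = obs,
       null_extreme = null_extreme)
}

# randomly reassign which coordinate each condition label maps to
permute_condition_coords <- function(pp) {
  lv <- unique(pp$labels)
  coord_of <- pp$coords[match(lv, pp$labels), , drop = FALSE]
  perm <- sample(length(lv))
  coord_of[perm, , drop = FALSE][match(pp$labels, lv), , drop = FALSE]
}
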