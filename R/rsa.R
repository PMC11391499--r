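#' Condition-averaged population activity over the reference trajectories
#'
#' For each window, returns the mean firing rate of every neuron in each of
#' the 24 reference-design trajectory conditions (start-target pairs), the
#' condition set shared with the network simulations.
#'
#' @param population List with `trials`, `neurons`, `wall`.
#' @param windows Named list of [window_spec()]s (default the pre-cue,
#'   post-cue and go key windows).
#' @return Named list of matrices (conditions x neurons); the condition
#'   order matches `session_design("reference")$trajectories`.
#' @export
condition_activity_population <- function(population,
                                          windows = key_windows()[c("pre_cue", "post_cue", "go")]) {
  des <- session_design("reference", population$wall)
  trj <- des$trajectories
  lapply(windows, function(w) {
    width <- w$t1 - w$t0
    mats <- vapply(population$neurons, function(nr) {
      cm <- count_spikes(nr, population$trials, w)
      key <- paste(cm$start_port, cm$target_port)
      gkey <- paste(trj$start_port, trj$target_port)
      mu <- rowsum(cm$count, factor(key, levels = gkey)) /
        pmax(as.integer(table(factor(key, levels = gkey))), 1)
      mu[, 1] / width
    }, numeric(nrow(trj)))
    mats
  })
}

#' Condition-averaged hidden-unit activity per frame
#'
#' @param act Result of [network_trajectory_activity()].
#' @param frames Frames to keep (default 3, 7 and 11, matching the pre-cue,
#'   post-cue and go windows).
#' @return Named list of matrices (24 conditions x units).
#' @export
condition_activity_network <- function(act, frames = c(3, 7, 11)) {
  out <- lapply(frames, function(t) {
    rowsum(act$H[, t, ], act$cond) / as.integer(table(act$cond))
  })
  names(out) <- paste0("frame", frames)
  out
}

#' Representational dissimilarity matrix of condition-averaged activity
#'
#' Activity (conditions x units) is reduced to its first `n_pcs` principal
#' components; the RDM entry for a condition pair is 1 minus the Pearson
#' correlation of their PC-score vectors (zero diagonal, symmetric).
#'
#' @param act Matrix conditions x units.
#' @param n_pcs Principal components (default 4).
#' @return Square dissimilarity matrix.
#' @export
representational_dissimilarity <- function(act, n_pcs = 4) {
  S <- stats::prcomp(act)$x[, seq_len(min(n_pcs, ncol(act))), drop = FALSE]
  1 - stats::cor(t(S))
}

#' Similarity between two representations
#'
#' Pearson correlation between the linearized lower triangles of the two
#' RDMs (built over the same condition set).
#'
#' @param act_a,act_b Matrices conditions x units (unit counts may differ;
#'   condition sets must match).
#' @param n_pcs Principal components per side.
#' @return Pearson r.
#' @export
rsa_similarity <- function(act_a, act_b, n_pcs = 4) {
  if (nrow(act_a) != nrow(act_b)) {
    stop("condition sets differ: ", nrow(act_a), " vs ", nrow(act_b),
         " conditions")
  }
  ra <- representational_dissimilarity(act_a, n_pcs)
  rb <- representational_dissimilarity(act_b, n_pcs)
  stats::cor(ra[lower.tri(ra)], rb[lower.tri(rb)])
}

#' Window-by-frame RSA matrix between a population and a network
#'
#' @param pop_acts List of condition-averaged population matrices (from
#'   [condition_activity_population()]).
#' @param net_acts List of condition-averaged network matrices (from
#'   [condition_activity_network()]).
#' @param n_pcs Principal components per side.
#' @return Matrix windows x frames of similarities; its diagonal is the
#'   matched-epoch profile.
#' @export
rsa_matrix <- function(pop_acts, net_acts, n_pcs = 4) {
  out <- matrix(NA_real_, length(pop_acts), length(net_acts),
                dimnames = list(names(pop_acts), names(net_acts)))
  for (i in seq_along(pop_acts)) {
    for (j in seq_along(net_acts)) {
      out[i, j] <- rsa_similarity(pop_acts[[i]], net_acts[[j]], n_pcs)
    }
  }
  out
}

cv_gaussian_encoding <- function(y, theta, x, ypos, kind, k = 5, seed = 1,
                                 restarts = 3) {
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(y)))
  pred <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_model_mle(kind, y[tr], theta[tr], x[tr], ypos[tr], width = 1,
                         restarts = restarts, family = "gaussian")
    if (is.null(fit)) next
    pred[!tr] <- encoding_rate(kind, fit$par, theta[!tr], x[!tr], ypos[!tr])
  }
  ok <- !is.na(pred)
  1 - sum((y[ok] - pred[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
}

#' Detect gain-field-like hidden units in a trained network
#'
#' Probes the network on a factorial grid of start positions and movement
#' directions, then fits the additive and the gain-field (multiplicative)
#' start-by-direction models to each unit's final-frame activity
#' (Gaussian noise, cross-validated). Units where the multiplicative model
#' generalizes better are flagged as gain-field-like.
#'
#' @param net An `rnn_network`.
#' @param repeats Renderings per grid cell (distractors redrawn).
#' @param seed Integer seed.
#' @param k CV folds.
#' @param restarts Optimizer restarts.
#' @return Data frame per unit: `unit`, `cv_r2_gain`, `cv_r2_additive`,
#'   `score` (gain minus additive) and `gain_field` (logical).
#' @export
detect_gain_field_units <- function(net, repeats = 2, seed = 1, k = 5,
                                    restarts = 3) {
  task <- net$task
  half <- task$world_px / 2
  g <- half * c(-0.4, 0, 0.4)
  starts <- as.matrix(expand.grid(x = g, y = g))
  dirs <- direction_angles()
  vlen <- 0.5 * half
  grid <- expand.grid(s = seq_len(nrow(starts)), d = seq_along(dirs))
  grid <- grid[rep(seq_len(nrow(grid)), repeats), ]
  n <- nrow(grid)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  X <- array(0, c(n, task$n_frames, task$n_input))
  for (i in seq_len(n)) {
    s <- starts[grid$s[i], ]
    v <- vlen * c(cos(dirs[grid$d[i]] * pi / 180),
                  sin(dirs[grid$d[i]] * pi / 180))
    X[i, , ] <- render_trial(task, s, s + v, seed = seeds[i])
  }
  fw <- rnn_forward(net, X)
  H <- fw$H[[task$n_frames]]
  ang <- dirs[grid$d]
  sx <- starts[grid$s, 1]; sy <- starts[grid$s, 2]
  rows <- lapply(seq_len(ncol(H)), function(u) {
    y <- H[, u]
    if (stats::sd(y) < 1e-8) {
      return(data.frame(unit = u, cv_r2_gain = NA, cv_r2_additive = NA,
                        score = NA, gain_field = FALSE))
    }
    w <- rowsum(y, ang)[, 1]
    w <- w - min(w)  # vector-sum weights must be non-negative
    theta0 <- preferred_direction(stats::setNames(w, sort(unique(ang))))
    if (is.na(theta0)) theta0 <- 0
    theta <- wrap_angle(ang - theta0)
    rg <- cv_gaussian_encoding(y, theta, sx, sy, "gain_field", k = k,
                               seed = seed + u, restarts = restarts)
    ra <- cv_gaussian_encoding(y, theta, sx, sy, "additive", k = k,
                               seed = seed + u, restarts = restarts)
    data.frame(unit = u, cv_r2_gain = rg, cv_r2_additive = ra,
               score = rg - ra, gain_field = isTRUE(rg > ra & rg > 0.05))
  })
  do.call(rbind, rows)
}
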