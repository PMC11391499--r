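#' Analysis time windows
#'
#' `key_windows()` returns the four canonical 300 ms windows: *pre-cue*
#' (-300 to 0 ms from cue onset), *post-cue* (0--300 ms from cue onset),
#' *go* (0--300 ms from the go sound) and *arrival* (-150 to 150 ms from the
#' target poke). `sliding_windows()` builds causal windows: the value at
#' time `t` covers `(t - width, t]` relative to the alignment event.
#'
#' @param align Alignment event: `"cue"`, `"go"`, `"arrival"` or
#'   `"fixation_out"`.
#' @param from,to Range of window *right edges* in s relative to the event.
#' @param step,width Step and width in s.
#' @return A list of window specs (`align`, `t0`, `t1`, `label`).
#' @export
key_windows <- function() {
  list(
    pre_cue = window_spec("cue", -0.3, 0, "pre_cue"),
    post_cue = window_spec("cue", 0, 0.3, "post_cue"),
    go = window_spec("go", 0, 0.3, "go"),
    arrival = window_spec("arrival", -0.15, 0.15, "arrival")
  )
}

#' @rdname key_windows
#' @export
sliding_windows <- function(align = "go", from = -1, to = 1,
                            step = 0.05, width = 0.3) {
  edges <- seq(from, to, by = step)
  lapply(edges, function(t) window_spec(align, t - width, t,
                                        sprintf("%s%+0.2f", align, t)))
}

#' @rdname key_windows
#' @param t0,t1 Window bounds in s relative to the event (spikes in
#'   `(event + t0, event + t1]` are counted).
#' @param label Window label.
#' @export
window_spec <- function(align, t0, t1, label = NULL) {
  stopifnot(t1 > t0)
  list(align = align, t0 = t0, t1 = t1,
       label = if (is.null(label)) sprintf("%s[%g,%g]", align, t0, t1) else label)
}

align_column <- function(align) {
  switch(align,
         cue = "t_cue_on", go = "t_go", arrival = "t_arrival",
         fixation_out = "t_fixation_out", fixation_in = "t_fixation_in",
         stop("unknown alignment event: ", align))
}

#' Count spikes in an analysis window
#'
#' Counts spikes per trial in `(event + t0, event + t1]` (causal convention:
#' a window ending at the event includes spikes up to and including the
#' event time). Only correct trials are kept by default; trials missing the
#' alignment event are dropped with a warning.
#'
#' @param spikes A `spike_data` object.
#' @param trials A `trial_table`.
#' @param window A [window_spec()].
#' @param correct_only Keep only correct trials (default `TRUE`).
#' @return A `count_matrix`: data frame with `trial_id`, `count`,
#'   `start_port`, `direction`, `target_port`; the window spec is attached
#'   as the `"window"` attribute.
#' @export
count_spikes <- function(spikes, trials, window, correct_only = TRUE) {
  keep <- if (correct_only) trials$outcome == "correct" else rep(TRUE, nrow(trials))
  ev <- trials[[align_column(window$align)]]
  missing_ev <- keep & is.na(ev)
  if (any(missing_ev)) {
    warning(sum(missing_ev), " trial(s) missing event '", window$align,
            "' were dropped")
    keep <- keep & !missing_ev
  }
  idx <- which(keep)
  counts <- vapply(idx, function(i) {
    ts <- spikes$spikes[[i]]
    sum(ts > ev[i] + window$t0 & ts <= ev[i] + window$t1)
  }, integer(1))
  out <- data.frame(
    trial_id = trials$trial_id[idx],
    count = counts,
    start_port = trials$start_port[idx],
    direction = trials$direction[idx],
    target_port = trials$target_port[idx]
  )
  attr(out, "window") <- window
  attr(out, "neuron_id") <- spikes$neuron_id
  class(out) <- c("count_matrix", "data.frame")
  out
}

variable_labels <- function(counts, variable) {
  col <- switch(variable, start = "start_port", direction = "direction",
                target = "target_port",
                stop("variable must be 'start', 'direction' or 'target'"))
  factor(counts[[col]])
}

#' Leave-one-out cross-validated Poisson log-likelihood
#'
#' The test statistic of the selectivity permutation test, for a one-way
#' layout: the held-out prediction for trial i is the mean count of the
#' remaining trials at the same level (closed form, no refitting), and the
#' statistic is the summed Poisson log-probability of the held-out counts.
#' Zero predictions are floored at 1e-6 so the log stays finite.
#'
#' @param y Integer vector of spike counts.
#' @param labels Factor of condition levels (each level needs >= 2 trials).
#' @return Summed held-out log-likelihood.
#' @export
loo_poisson_loglik <- function(y, labels) {
  sums <- rowsum(y, labels)[, 1]
  cnt <- tabulate(labels, nbins = nlevels(labels))
  names(cnt) <- levels(labels)
  li <- as.integer(labels)
  pred <- (sums[li] - y) / (cnt[li] - 1)
  pred <- pmax(pred, 1e-6)
  sum(stats::dpois(y, pred, log = TRUE))
}

#' Fit a single-variable Poisson GLM to windowed spike counts
#'
#' The model `counts ~ level(variable)` with dummy coding and a Poisson
#' likelihood has its MLE at the per-level mean counts, which is how the fit
#' is computed. Reported are the level means, the non-cross-validated
#' variance-explained R-squared, and the leave-one-out cross-validated
#' log-likelihood (the held-out prediction for a trial is the mean of the
#' remaining trials at its level).
#'
#' @param counts A `count_matrix`.
#' @param variable `"start"`, `"direction"` or `"target"`.
#' @return A `glm_result`: list with `variable`, `level_means` (Hz-free,
#'   mean counts per level), `r2`, `cv_loglik`, `n_trials`.
#' @export
fit_variable_glm <- function(counts, variable) {
  labels <- variable_labels(counts, variable)
  if (any(table(labels) < 2)) {
    stop("every level of '", variable,
         "' needs at least 2 trials for leave-one-out cross-validation")
  }
  y <- counts$count
  mu <- tapply(y, labels, mean)
  fitted <- mu[as.integer(labels)]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - fitted)^2) / sst
  structure(
    list(variable = variable, level_means = mu, r2 = r2,
         cv_loglik = loo_poisson_loglik(y, labels),
         n_trials = length(y)),
    class = "glm_result"
  )
}

#' Permutation test for single-variable selectivity
#'
#' Trial labels of the variable are shuffled `n_perm` times; the test
#' statistic is the leave-one-out cross-validated Poisson log-likelihood,
#' and the p value is the fraction of shuffled statistics strictly greater
#' than the observed one (so a perfectly tuned neuron can attain p = 0).
#'
#' @param counts A `count_matrix`.
#' @param variable `"start"`, `"direction"` or `"target"`.
#' @param n_perm Number of label shuffles (5000 in full-scale analyses).
#' @param seed Integer seed.
#' @return List with `p`, `observed` (CV log-likelihood), `null` (vector of
#'   shuffled statistics) and `n_perm`.
#' @export
permutation_test <- function(counts, variable, n_perm = 5000, seed = 1) {
  labels <- variable_labels(counts, variable)
  y <- counts$count
  obs <- loo_poisson_loglik(y, labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    loo_poisson_loglik(y, labels[sample.int(length(y))])
  }, numeric(1))
  list(p = mean(null > obs), observed = obs, null = null, n_perm = n_perm)
}

#' Assign the best-explaining spatial variable to a neuron
#'
#' The neuron is assigned to the variable with the smallest permutation
#' p value; if the minimum p is not below `alpha` the neuron is labelled
#' `"none"`. Ties in p (possible because p is a permutation fraction) are
#' broken by the larger cross-validated log-likelihood.
#'
#' @param p Named numeric vector of permutation p values for `start`,
#'   `direction`, `target`.
#' @param cv_loglik Named numeric vector of the matching CV log-likelihoods.
#' @param alpha Significance threshold (default 0.01).
#' @return One of `"start"`, `"direction"`, `"target"`, `"none"`.
#' @export
assign_best_variable <- function(p, cv_loglik, alpha = 0.01) {
  vars <- c("start", "direction", "target")
  stopifnot(all(vars %in% names(p)), all(vars %in% names(cv_loglik)))
  p <- p[vars]; cv_loglik <- cv_loglik[vars]
  if (min(p) >= alpha) return("none")
  best <- which(p == min(p))
  if (length(best) > 1) best <- best[which.max(cv_loglik[best])]
  vars[best]
}

#' Full selectivity assignment for one neuron in one window
#'
#' Runs the three single-variable GLMs and permutation tests on one count
#' matrix and applies [assign_best_variable()].
#'
#' @param counts A `count_matrix`.
#' @param n_perm,seed,alpha See [permutation_test()] and
#'   [assign_best_variable()].
#' @return List with `best`, `p` (named vector), `cv_loglik`, `r2`.
#' @export
classify_selectivity <- function(counts, n_perm = 5000, seed = 1,
                                 alpha = 0.01) {
  vars <- c("start", "direction", "target")
  p <- cvll <- r2 <- stats::setNames(numeric(3), vars)
  for (v in vars) {
    fit <- fit_variable_glm(counts, v)
    pt <- permutation_test(counts, v, n_perm = n_perm, seed = seed)
    p[v] <- pt$p; cvll[v] <- fit$cv_loglik; r2[v] <- fit$r2
  }
  list(best = assign_best_variable(p, cvll, alpha = alpha),
       p = p, cv_loglik = cvll, r2 = r2)
}

#' R-squared time course of the three spatial GLMs
#'
#' For each sliding window, fits the three single-variable Poisson GLMs and
#' records the (non-cross-validated) R-squared of each, plus which variable
#' has the largest R-squared — the per-neuron selectivity time course.
#'
#' @param spikes A `spike_data`.
#' @param trials A `trial_table`.
#' @param windows List of [window_spec()]s (e.g. [sliding_windows()]).
#' @return Data frame with one row per window: `label`, `time` (window right
#'   edge), `r2_start`, `r2_direction`, `r2_target`, `best_r2` (the argmax
#'   variable) and `max_r2`.
#' @export
selectivity_timecourse <- function(spikes, trials, windows) {
  rows <- lapply(windows, function(w) {
    cm <- count_spikes(spikes, trials, w)
    r2 <- vapply(c("start", "direction", "target"),
                 function(v) fit_variable_glm(cm, v)$r2, numeric(1))
    data.frame(label = w$label, time = w$t1,
               r2_start = r2[["start"]], r2_direction = r2[["direction"]],
               r2_target = r2[["target"]],
               best_r2 = c("start", "direction", "target")[which.max(r2)],
               max_r2 = max(r2))
  })
  do.call(rbind, rows)
}

#' Population fractions of best-selective neurons per window
#'
#' For each window, classifies every neuron with [classify_selectivity()]
#' and reports the fraction assigned to each variable with a 95% binomial
#' (Wilson) confidence interval — the population summary behind the
#' sequential-encoding result.
#'
#' @param population List with `trials` and `neurons`
#'   (as from [generate_population()]).
#' @param windows List of [window_spec()]s (default [key_windows()]).
#' @param n_perm,alpha,seed See [classify_selectivity()].
#' @return Data frame with `window`, `variable`, `fraction`, `lo`, `hi`,
#'   `n`.
#' @export
selectivity_fractions <- function(population, windows = key_windows(),
                                  n_perm = 1000, alpha = 0.01, seed = 1) {
  vars <- c("start", "direction", "target", "none")
  rows <- list()
  for (w in windows) {
    best <- vapply(seq_along(population$neurons), function(i) {
      cm <- count_spikes(population$neurons[[i]], population$trials, w)
      classify_selectivity(cm, n_perm = n_perm, seed = seed + i,
                           alpha = alpha)$best
    }, character(1))
    n <- length(best)
    for (v in vars) {
      k <- sum(best == v)
      ci <- binom_ci(k, n)
      rows[[length(rows) + 1]] <- data.frame(
        window = w$label, variable = v, fraction = k / n,
        lo = ci[1], hi = ci[2], n = n)
    }
  }
  do.call(rbind, rows)
}

#' Synthetic recovery of single-variable selectivity assignment
#'
#' Generates `n_per_class` Poisson neurons per tuning class (`start`,
#' `direction`, `target`) with randomized baselines and modulation depths
#' (see [random_tuning_spec()]), runs the three-GLM permutation assignment
#' on each neuron in the key window lying inside its tuned epoch (pre-cue
#' for start, post-cue for direction, arrival for target), and scores the
#' assignments against the generative classes. Sessions are error- and
#' violation-free so every trajectory keeps its full trial count.
#'
#' @param n_per_class Neurons per generative class.
#' @param design A [session_design()].
#' @param n_trials Trials in each class's session.
#' @param n_perm Label shuffles per test (1000 at reduced scale, 5000 at
#'   full scale).
#' @param alpha Significance threshold for the `"none"` label.
#' @param seed Integer seed; all randomness (sessions, tuning draws,
#'   spiking, shuffles) derives from it.
#' @return List with `assignments` (data frame: `kind`, `neuron`,
#'   `assigned`), `overall` (fraction assigned to the generative class) and
#'   `excluding_none` (same fraction among neurons assigned a non-none
#'   label).
#' @export
selectivity_recovery <- function(n_per_class = 100,
                                 design = session_design("reference"),
                                 n_trials = 240, n_perm = 1000,
                                 alpha = 0.01, seed = 1) {
  kinds <- c("start", "direction", "target")
  wins <- key_windows()[c("pre_cue", "post_cue", "arrival")]
  names(wins) <- kinds
  rows <- vector("list", 3L * n_per_class)
  r <- 0L
  for (kind in kinds) {
    pop <- generate_population(
      stats::setNames(n_per_class, kind), design, n_trials,
      seed = seed + 100003L * match(kind, kinds),
      p_error = 0, p_violation = 0)
    for (i in seq_along(pop$neurons)) {
      cm <- count_spikes(pop$neurons[[i]], pop$trials, wins[[kind]])
      cls <- classify_selectivity(cm, n_perm = n_perm, seed = seed + i,
                                  alpha = alpha)
      r <- r + 1L
      rows[[r]] <- data.frame(kind = kind, neuron = i, assigned = cls$best)
    }
  }
  out <- do.call(rbind, rows)
  sel <- out$assigned != "none"
  list(assignments = out,
       overall = mean(out$assigned == out$kind),
       excluding_none = mean(out$assigned[sel] == out$kind[sel]))
}

# Wilson score interval for a binomial proportion
binom_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
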