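#' Generate a behavioural session for a task design
#'
#' Simulates the trial-by-trial structure of a recording session: trajectory
#' allocation is balanced across the design's trajectories (equal counts up to
#' a random remainder, then shuffled), and event times follow the task
#' timeline: the target cue illuminates 0--0.29 s after fixation onset, the
#' jittered fixation period lasts up to 1.2 s and always outlasts the cue
#' delay (target visible during fixation), the go sound ends fixation, and
#' the movement ends with the target poke.
#'
#' @param design A [session_design()].
#' @param n_trials Number of trials; must allow at least
#'   `design$min_trials_per_condition` trials per trajectory.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param p_error Probability that a completed trial ends at a wrong port.
#' @param p_violation Probability of a fixation violation (early withdrawal;
#'   the trial is aborted, so go and arrival times are missing).
#' @param weights Optional per-trajectory sampling weights (default uniform).
#'
#' @return A `trial_table` data frame, one row per trial, with columns
#'   `trial_id`, `start_port`, `target_port`, `direction`, `distance_class`,
#'   event times in seconds relative to trial start (`t_fixation_in`,
#'   `t_cue_on`, `t_go`, `t_fixation_out`, `t_arrival`, `t_trial_end`) and
#'   `outcome` (`"correct"`, `"error"` or `"violation"`).
#' @export
generate_session <- function(design, n_trials, seed = 1,
                             p_error = 0.05, p_violation = 0.05,
                             weights = NULL) {
  stopifnot(inherits(design, "session_design"))
  trj <- design$trajectories
  k <- nrow(trj)
  m <- design$min_trials_per_condition
  if (n_trials < m * k) {
    stop(sprintf(
      "n_trials = %d cannot give %d trials for each of the %d trajectories (need >= %d)",
      n_trials, m, k, m * k))
  }
  set.seed(seed)
  if (is.null(weights)) {
    base <- rep(seq_len(k), n_trials %/% k)
    extra <- sample(seq_len(k), n_trials %% k, replace = FALSE,
                    prob = rep(1 / k, k))
    idx <- sample(c(base, extra))
  } else {
    stopifnot(length(weights) == k, all(weights >= 0))
    idx <- sample(seq_len(k), n_trials, replace = TRUE,
                  prob = weights / sum(weights))
    short <- table(factor(idx, levels = seq_len(k))) < m
    if (any(short)) {
      stop("weighted sampling left trajectory ",
           which(short)[1], " with fewer than ", m, " trials")
    }
  }
  n <- n_trials
  t_fix_in <- runif(n, 0.9, 1.2)
  cue_delay <- runif(n, 0, 0.29)
  fix_dur <- runif(n, pmin(cue_delay + 0.05, 1.2), 1.2)
  t_cue <- t_fix_in + cue_delay
  t_go <- t_fix_in + fix_dur
  rt <- runif(n, 0.05, 0.3)
  move <- ifelse(trj$distance_class[idx] == "long",
                 runif(n, 0.30, 0.50), runif(n, 0.15, 0.35))
  t_out <- t_go + rt
  t_arr <- t_out + move
  u <- runif(n)
  outcome <- ifelse(u < p_violation, "violation",
                    ifelse(u < p_violation + p_error, "error", "correct"))
  viol <- outcome == "violation"
  # a violation ends fixation before the go sound; the trial is aborted
  t_out[viol] <- t_fix_in[viol] + runif(sum(viol), 0, fix_dur[viol])
  t_go[viol] <- NA_real_
  t_arr[viol] <- NA_real_
  t_end <- ifelse(viol, t_out + 0.5, t_arr + 1.0)
  out <- data.frame(
    trial_id = seq_len(n),
    start_port = trj$start_port[idx],
    target_port = trj$target_port[idx],
    direction = trj$direction[idx],
    distance_class = trj$distance_class[idx],
    t_fixation_in = t_fix_in,
    t_cue_on = t_cue,
    t_go = t_go,
    t_fixation_out = t_out,
    t_arrival = t_arr,
    t_trial_end = t_end,
    outcome = outcome
  )
  class(out) <- c("trial_table", "data.frame")
  attr(out, "design") <- design$name
  out
}

#' Tuning specification for a synthetic neuron
#'
#' Describes the generative firing-rate function of a synthetic neuron over
#' the task's condition set. Pure spatial kinds (`"start"`, `"direction"`,
#' `"target"`) use a Gaussian bump of relative amplitude `depth` around a
#' preferred port or direction on top of the baseline. The `"additive"` and
#' `"gain_field"` kinds use the encoding-model rate functions (see
#' [fit_encoding_model()]) with parameters `b0..b3`, `sigma` (degrees) and
#' the preferred direction `theta0`.
#'
#' @param kind One of `"start"`, `"direction"`, `"target"`, `"additive"`,
#'   `"gain_field"`, `"none"`.
#' @param baseline Baseline firing rate in Hz (outside the tuned epoch, and
#'   the untuned floor within it).
#' @param ... Kind-specific parameters: `pref_port` and `sigma_mm` for
#'   position kinds; `pref_angle` (deg) and `sigma_deg` for direction;
#'   `depth` (peak modulation as a multiple of baseline) for all pure kinds;
#'   `b0`, `b1`, `b2`, `b3`, `sigma`, `theta0` for the mixed kinds.
#' @return An object of class `tuning_spec`.
#' @export
tuning_spec <- function(kind = c("start", "direction", "target",
                                 "additive", "gain_field", "none"),
                        baseline = 5, ...) {
  kind <- match.arg(kind)
  spec <- c(list(kind = kind, baseline = baseline), list(...))
  defaults <- list(depth = 1.5, sigma_mm = 50, sigma_deg = 40,
                   pref_port = 0L, pref_angle = 0)
  for (nm in names(defaults)) {
    if (is.null(spec[[nm]])) spec[[nm]] <- defaults[[nm]]
  }
  if (kind %in% c("additive", "gain_field")) {
    need <- c("b0", "b1", "b2", "sigma", "theta0",
              if (kind == "additive") "b3")
    miss <- setdiff(need, names(spec))
    if (length(miss)) stop("missing parameters for ", kind, " spec: ",
                           paste(miss, collapse = ", "))
  }
  structure(spec, class = "tuning_spec")
}

#' Draw a random tuning specification
#'
#' Baselines are log-uniform on 1--20 Hz and modulation depths uniform on
#' 0.5--3 times the baseline (mixed kinds cap the position depth at 1 so the
#' rate stays non-negative); preferred ports, directions and position-slope
#' orientations are uniform over their ranges.
#'
#' @param kind Tuning kind as in [tuning_spec()].
#' @param wall A `port_wall` (sets the position scale).
#' @return A `tuning_spec`.
#' @export
random_tuning_spec <- function(kind, wall = build_port_wall()) {
  baseline <- exp(runif(1, log(1), log(20)))
  if (kind == "none") return(tuning_spec("none", baseline = baseline))
  if (kind %in% c("start", "target")) {
    return(tuning_spec(kind, baseline = baseline,
                       depth = runif(1, 0.5, 3),
                       pref_port = sample(0:6, 1),
                       sigma_mm = wall$spacing))
  }
  if (kind == "direction") {
    return(tuning_spec(kind, baseline = baseline,
                       depth = runif(1, 0.5, 3),
                       pref_angle = sample(direction_angles(), 1),
                       sigma_deg = runif(1, 30, 60)))
  }
  # mixed kinds: parameterized so peak modulations are `depth_*` x baseline
  sigma <- runif(1, 30, 60)
  theta0 <- sample(direction_angles(), 1)
  phi <- runif(1, 0, 2 * pi)
  depth_pos <- runif(1, 0.5, 1)
  m <- depth_pos * baseline / wall$spacing
  peak_gauss <- 1 / (sigma * sqrt(2 * pi))
  if (kind == "gain_field") {
    # orient the position slope opposite the preferred direction so the
    # session-marginal direction tuning peaks at theta0 (movements along a
    # direction start, on average, on the opposite side of the wall); the
    # tuning centre is then identifiable from the marginal tuning curve,
    # as it is for recorded neurons selected for direction tuning
    phi <- theta0 * pi / 180 + pi + runif(1, -pi / 3, pi / 3)
    tuning_spec("gain_field", baseline = baseline, b0 = baseline,
                b1 = m * cos(phi) / peak_gauss, b2 = m * sin(phi) / peak_gauss,
                sigma = sigma, theta0 = theta0)
  } else {
    depth_dir <- runif(1, 0.5, 3)
    tuning_spec("additive", baseline = baseline, b0 = baseline,
                b1 = m * cos(phi), b2 = m * sin(phi),
                b3 = depth_dir * baseline / peak_gauss,
                sigma = sigma, theta0 = theta0)
  }
}

gauss_angle <- function(theta_deg, sigma_deg) {
  exp(-theta_deg^2 / (2 * sigma_deg^2)) / (sigma_deg * sqrt(2 * pi))
}

#' Generative firing rate of a tuning spec at trial conditions
#'
#' @param spec A [tuning_spec()].
#' @param trials A `trial_table` (or any data frame with `start_port`,
#'   `target_port`, `direction`).
#' @param wall A `port_wall`.
#' @return Numeric vector, rate in Hz per trial (within the tuned epoch).
#' @export
tuning_rate <- function(spec, trials, wall = build_port_wall()) {
  stopifnot(inherits(spec, "tuning_spec"))
  co <- variable_coordinates(trials, wall)
  rate <- switch(spec$kind,
    none = rep(spec$baseline, nrow(trials)),
    start = ,
    target = {
      p <- port_xy(wall, spec$pref_port)
      xy <- if (spec$kind == "start") cbind(co$start_x, co$start_y)
            else cbind(co$target_x, co$target_y)
      d2 <- (xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2
      spec$baseline * (1 + spec$depth * exp(-d2 / (2 * spec$sigma_mm^2)))
    },
    direction = {
      dtheta <- wrap_angle(trials$direction - spec$pref_angle)
      g <- exp(-dtheta^2 / (2 * spec$sigma_deg^2))
      spec$baseline * (1 + spec$depth * g)
    },
    additive = ,
    gain_field = {
      dtheta <- wrap_angle(trials$direction - spec$theta0)
      g <- gauss_angle(dtheta, spec$sigma)
      pos <- spec$b1 * co$start_x + spec$b2 * co$start_y
      if (spec$kind == "gain_field") spec$b0 + pos * g
      else spec$b0 + pos + spec$b3 * g
    }
  )
  if (any(rate < 0)) {
    stop("tuning spec predicts a negative firing rate on the task conditions")
  }
  rate
}

default_epochs <- function() {
  # which part of the trial each tuning kind occupies
  list(
    start = list(from = c("t_fixation_in", -1.0), to = c("t_go", 0.3)),
    direction = list(from = c("t_cue_on", 0), to = c("t_arrival", 0)),
    target = list(from = c("t_go", 0), to = c("t_trial_end", 0)),
    additive = list(from = c("t_cue_on", 0), to = c("t_trial_end", 0)),
    gain_field = list(from = c("t_cue_on", 0), to = c("t_trial_end", 0)),
    none = list(from = c("t_fixation_in", -1.0), to = c("t_trial_end", 0))
  )
}

epoch_bounds <- function(trials, ep) {
  from <- trials[[ep$from[[1]]]] + as.numeric(ep$from[[2]])
  to <- trials[[ep$to[[1]]]] + as.numeric(ep$to[[2]])
  cbind(pmax(from, 0), pmin(to, trials$t_trial_end))
}

#' Generate a Poisson-spiking synthetic neuron
#'
#' Spike counts in any analysis window are Poisson with mean
#' `rate(condition) x window length`. The tuned rate occupies a
#' kind-specific epoch of the trial (start tuning from trial start to
#' 0.3 s after the go sound, direction tuning from cue onset to arrival,
#' target tuning from the go sound to the trial end); outside its epoch the
#' neuron fires at baseline. Spikes are placed uniformly within each
#' constant-rate segment.
#'
#' @param spec A [tuning_spec()].
#' @param trials A `trial_table`.
#' @param wall A `port_wall`.
#' @param seed Integer seed.
#' @param epochs Epoch table as produced by `default_epochs()` (exposed for
#'   customised temporal profiles).
#' @return An object of class `spike_data`: list with `neuron_id`, `spikes`
#'   (list of sorted spike-time vectors, one per trial, in s from trial
#'   start) and `spec`.
#' @export
generate_neuron <- function(spec, trials, wall = build_port_wall(), seed = 1,
                            epochs = default_epochs()) {
  set.seed(seed)
  n <- nrow(trials)
  rate <- tuning_rate(spec, trials, wall)
  ep <- epochs[[spec$kind]]
  bounds <- epoch_bounds(trials, ep)
  spikes <- vector("list", n)
  for (i in seq_len(n)) {
    t_end <- trials$t_trial_end[i]
    a <- bounds[i, 1]; b <- bounds[i, 2]
    if (is.na(a) || is.na(b) || b <= a) { # aborted trial: baseline throughout
      segs <- cbind(0, t_end, spec$baseline)
    } else {
      segs <- rbind(c(0, a, spec$baseline),
                    c(a, b, rate[i]),
                    c(b, t_end, spec$baseline))
      segs <- segs[segs[, 2] > segs[, 1], , drop = FALSE]
    }
    counts <- rpois(nrow(segs), segs[, 3] * (segs[, 2] - segs[, 1]))
    ts <- unlist(lapply(seq_len(nrow(segs)), function(j) {
      runif(counts[j], segs[j, 1], segs[j, 2])
    }))
    spikes[[i]] <- sort(ts)
  }
  structure(list(neuron_id = 1L, spikes = spikes, spec = spec),
            class = "spike_data")
}

#' Generate a synthetic population with a mixture of tuning kinds
#'
#' @param n_per_kind Named integer vector, e.g. `c(start = 100, none = 50)`:
#'   number of neurons drawn from [random_tuning_spec()] per kind. Specs can
#'   instead be supplied explicitly through `specs`.
#' @param design A [session_design()].
#' @param n_trials Trials in the shared session.
#' @param seed Integer seed; neuron `i` uses seed `seed + i` so the
#'   population is reproducible and neurons are independent.
#' @param specs Optional list of `tuning_spec` objects overriding
#'   `n_per_kind`.
#' @param ... Passed to [generate_session()].
#' @return List with `trials` (the shared `trial_table`), `neurons` (list of
#'   `spike_data`, with `neuron_id` set and generative `spec` attached) and
#'   `wall`.
#' @export
generate_population <- function(n_per_kind, design, n_trials, seed = 1,
                                specs = NULL, ...) {
  wall <- design$wall
  trials <- generate_session(design, n_trials, seed = seed, ...)
  if (is.null(specs)) {
    set.seed(seed + 1000003L)
    specs <- unlist(lapply(names(n_per_kind), function(k) {
      replicate(n_per_kind[[k]], random_tuning_spec(k, wall),
                simplify = FALSE)
    }), recursive = FALSE)
  }
  neurons <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    nr <- generate_neuron(specs[[i]], trials, wall, seed = seed + i)
    nr$neuron_id <- i
    neurons[[i]] <- nr
  }
  list(trials = trials, neurons = neurons, wall = wall)
}

#' Write / read a session directory
#'
#' The on-disk format is plain text: `trials.csv` (the trial table) and
#' `spikes.csv` with one row per spike (`neuron_id`, `trial_id`, `t`).
#'
#' @param population List as returned by [generate_population()].
#' @param dir Directory to create/read.
#' @return `write_session` returns `dir` invisibly; `read_session` returns a
#'   list with `trials` and `neurons` (generative specs are not persisted).
#' @export
write_session <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(population$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  rows <- lapply(population$neurons, function(nr) {
    n_sp <- lengths(nr$spikes)
    data.frame(neuron_id = nr$neuron_id,
               trial_id = rep(seq_along(nr$spikes), n_sp),
               t = unlist(nr$spikes, use.names = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  class(trials) <- c("trial_table", "data.frame")
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  stopifnot(all(c("neuron_id", "trial_id", "t") %in% names(sp)))
  if (any(sp$t < 0)) stop("spike times must be non-negative")
  neurons <- lapply(sort(unique(sp$neuron_id)), function(id) {
    rows <- sp[sp$neuron_id == id, ]
    spikes <- lapply(seq_len(nrow(trials)), function(i) {
      sort(rows$t[rows$trial_id == i])
    })
    structure(list(neuron_id = id, spikes = spikes, spec = NULL),
              class = "spike_data")
  })
  list(trials = trials, neurons = neurons)
}
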