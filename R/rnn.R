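#' Reference-frame task configuration for network simulations
#'
#' Defines one of the four input/output reference-frame tasks. The input at
#' each of `n_frames` time frames is a `native_px` x `native_px` image
#' down-sampled to `down_px` x `down_px` and flattened. The image shows the
#' visual-frame border, the world-frame border (a `world_px` square
#' centred on the world origin), the start port, static distractors, and —
#' on `target_frame` only — the target port. With egocentric input the
#' start port is pinned to the image centre (so the world frame shifts with
#' the start position); with allocentric input the world frame is pinned to
#' the centre. The required output at the final frame is the movement
#' vector (ego output) or the target position in world coordinates (allo
#' output).
#'
#' @param input_frame,output_frame `"ego"` or `"allo"`.
#' @param native_px Native image size (default 100).
#' @param down_px Down-sampled size (default 40).
#' @param world_px World-frame size in native px (default 50); world
#'   coordinates are centred at (0, 0).
#' @param n_frames Time frames per trial (default 11).
#' @param target_frame Frame on which the target is visible (default 4).
#' @param n_distractors Static distractor pixels (default 3).
#' @param intensities Named list of pixel intensities.
#' @return A `frame_task` object.
#' @export
frame_task <- function(input_frame = c("ego", "allo"),
                       output_frame = c("ego", "allo"),
                       native_px = 100, down_px = 40, world_px = 50,
                       n_frames = 11, target_frame = 4, n_distractors = 3,
                       intensities = list(start = 0.7, target = 1.0,
                                          distractor = 0.2,
                                          world_frame = 0.4,
                                          visual_frame = 0.3)) {
  input_frame <- match.arg(input_frame)
  output_frame <- match.arg(output_frame)
  structure(
    list(input_frame = input_frame, output_frame = output_frame,
         native_px = native_px, down_px = down_px, world_px = world_px,
         n_frames = n_frames, target_frame = target_frame,
         n_distractors = n_distractors, intensities = intensities,
         n_input = down_px^2),
    class = "frame_task"
  )
}

task_name <- function(task) paste0(task$input_frame, "-", task$output_frame)

# area-average down-sampling of a square image
down_sample <- function(img, down_px) {
  n <- nrow(img)
  g <- ceiling(seq_len(n) * down_px / n)
  rowsum(t(rowsum(img, g) / tabulate(g)), g) / tabulate(g)
}

draw_square <- function(img, row, col, half, value) {
  n <- nrow(img)
  r <- max(1, round(row) - half):min(n, round(row) + half)
  c <- max(1, round(col) - half):min(n, round(col) + half)
  if (round(row) + half < 1 || round(row) - half > n ||
      round(col) + half < 1 || round(col) - half > n) return(img)
  img[r, c] <- value
  img
}

draw_border <- function(img, row, col, half, value) {
  n <- nrow(img)
  rs <- round(row) + c(-half, half); cs <- round(col) + c(-half, half)
  rr <- max(1, rs[1]):min(n, rs[2]); cc <- max(1, cs[1]):min(n, cs[2])
  for (r in rs) if (r >= 1 && r <= n) img[r, cc] <- value
  for (c in cs) if (c >= 1 && c <= n) img[rr, c] <- value
  img
}

world_to_pixel <- function(task, xy, start_xy) {
  # world point -> native pixel (row, col); image row 1 is the top
  ctr <- (task$native_px + 1) / 2
  xy <- unname(as.numeric(xy))
  start_xy <- unname(as.numeric(start_xy))
  off <- if (task$input_frame == "ego") xy - rep(start_xy, length.out = 2)
         else xy
  c(row = ctr - off[2], col = ctr + off[1])
}

#' Render the input tensor for one trial
#'
#' @param task A [frame_task()].
#' @param start_xy,target_xy World coordinates (px, within the world
#'   frame).
#' @param seed Seed for distractor placement.
#' @param down Down-sample and flatten (default). With `down = FALSE` the
#'   native-resolution images are returned as an array
#'   `n_frames x native_px x native_px` (exact drawn intensities).
#' @return Matrix `n_frames` x `down_px^2` of flattened frames (or the
#'   native array).
#' @export
render_trial <- function(task, start_xy, target_xy, seed = 1, down = TRUE) {
  half_w <- task$world_px / 2
  if (any(abs(start_xy) > half_w) || any(abs(target_xy) > half_w)) {
    stop("start and target must lie inside the world frame")
  }
  set.seed(seed)
  n <- task$native_px
  ints <- task$intensities
  distr <- cbind(stats::runif(task$n_distractors, 3, n - 2),
                 stats::runif(task$n_distractors, 3, n - 2))
  base <- matrix(0, n, n)
  base <- draw_border(base, (n + 1) / 2, (n + 1) / 2, (n - 1) / 2,
                      ints$visual_frame)
  wf <- world_to_pixel(task, c(0, 0), start_xy)
  base <- draw_border(base, wf["row"], wf["col"], round(task$world_px / 2),
                      ints$world_frame)
  for (d in seq_len(task$n_distractors)) {
    base <- draw_square(base, distr[d, 1], distr[d, 2], 1, ints$distractor)
  }
  sp <- world_to_pixel(task, start_xy, start_xy)
  base <- draw_square(base, sp["row"], sp["col"], 1, ints$start)
  tp <- world_to_pixel(task, target_xy, start_xy)
  with_target <- draw_square(base, tp["row"], tp["col"], 1, ints$target)
  if (!down) {
    out <- array(0, c(task$n_frames, n, n))
    for (f in seq_len(task$n_frames)) {
      out[f, , ] <- if (f == task$target_frame) with_target else base
    }
    return(out)
  }
  out <- matrix(0, task$n_frames, task$n_input)
  flat_base <- as.vector(down_sample(base, task$down_px))
  flat_tgt <- as.vector(down_sample(with_target, task$down_px))
  for (f in seq_len(task$n_frames)) {
    out[f, ] <- if (f == task$target_frame) flat_tgt else flat_base
  }
  out
}

trial_output <- function(task, start_xy, target_xy) {
  if (task$output_frame == "ego") target_xy - start_xy else target_xy
}

random_trials <- function(task, n, margin = 2) {
  half <- task$world_px / 2 - margin
  list(start = cbind(stats::runif(n, -half, half),
                     stats::runif(n, -half, half)),
       target = cbind(stats::runif(n, -half, half),
                      stats::runif(n, -half, half)))
}

render_batch <- function(task, starts, targets, seeds) {
  n <- nrow(starts)
  X <- array(0, c(n, task$n_frames, task$n_input))
  Y <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    X[i, , ] <- render_trial(task, starts[i, ], targets[i, ], seed = seeds[i])
    Y[i, ] <- trial_output(task, starts[i, ], targets[i, ])
  }
  list(X = X, Y = Y)
}

init_network <- function(task, n_hidden, seed) {
  set.seed(seed)
  ni <- task$n_input
  list(
    W_in = matrix(stats::rnorm(n_hidden * ni, 0, 1 / sqrt(ni)), n_hidden, ni),
    W_rec = matrix(stats::rnorm(n_hidden^2, 0, 0.9 / sqrt(n_hidden)),
                   n_hidden, n_hidden),
    b = numeric(n_hidden),
    W_out = matrix(stats::rnorm(2 * n_hidden, 0, 0.1 / sqrt(n_hidden)),
                   2, n_hidden),
    b_out = numeric(2),
    n_hidden = n_hidden, task = task,
    out_scale = task$world_px / 2  # readout trained in normalized units
  )
}

# forward pass; X is [batch x frames x inputs]; returns hidden states per
# frame and the readout at the final frame (normalized units)
rnn_forward <- function(net, X) {
  batch <- dim(X)[1]
  Tn <- dim(X)[2]
  H <- vector("list", Tn)
  h <- matrix(0, batch, net$n_hidden)
  for (t in seq_len(Tn)) {
    a <- X[, t, , drop = TRUE]
    if (batch == 1) a <- matrix(a, 1)
    h <- tanh(a %*% t(net$W_in) +
                h %*% t(net$W_rec) +
                matrix(net$b, batch, net$n_hidden, byrow = TRUE))
    H[[t]] <- h
  }
  out <- h %*% t(net$W_out) + matrix(net$b_out, batch, 2, byrow = TRUE)
  list(H = H, out = out)
}

#' Train a reference-frame recurrent network
#'
#' A vanilla recurrent network (tanh hidden layer, linear two-unit readout
#' of the (x, y) coordinates) trained by stochastic gradient descent with
#' momentum through time on freshly sampled trials (start and target drawn
#' uniformly inside the world frame). The loss is the mean squared readout
#' error at the final frame; coordinates are normalized by half the world
#' size during training and predictions are reported in px.
#'
#' @param task A [frame_task()].
#' @param n_hidden Hidden units (100 at full scale).
#' @param steps Gradient steps.
#' @param batch Batch size.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param seed Integer seed.
#' @param target_error Early-stopping test error in px (checked every 50
#'   steps on a fresh batch); `NULL` disables.
#' @return An `rnn_network` (list of weights plus a `history` of training
#'   loss and the final `test_error` in px).
#' @export
train_network <- function(task, n_hidden = 100, steps = 1500, batch = 32,
                          lr = 0.05, momentum = 0.9, seed = 1,
                          target_error = NULL) {
  net <- init_network(task, n_hidden, seed)
  vel <- lapply(net[c("W_in", "W_rec", "b", "W_out", "b_out")],
                function(w) w * 0)
  set.seed(seed + 1L)
  history <- numeric(0)
  scl <- net$out_scale
  for (step in seq_len(steps)) {
    tr <- random_trials(task, batch)
    bt <- render_batch(task, tr$start, tr$target,
                       seeds = sample.int(.Machine$integer.max, batch))
    Yn <- bt$Y / scl
    fw <- rnn_forward(net, bt$X)
    dO <- (fw$out - Yn) / batch
    loss <- sum((fw$out - Yn)^2) / (2 * batch)
    history <- c(history, loss)
    g <- list(W_in = net$W_in * 0, W_rec = net$W_rec * 0,
              b = numeric(net$n_hidden),
              W_out = t(dO) %*% fw$H[[task$n_frames]],
              b_out = colSums(dO))
    dh <- dO %*% net$W_out
    for (t in rev(seq_len(task$n_frames))) {
      da <- dh * (1 - fw$H[[t]]^2)
      Xt <- bt$X[, t, , drop = TRUE]
      if (batch == 1) Xt <- matrix(Xt, 1)
      g$W_in <- g$W_in + t(da) %*% Xt
      h_prev <- if (t > 1) fw$H[[t - 1]] else matrix(0, batch, net$n_hidden)
      g$W_rec <- g$W_rec + t(da) %*% h_prev
      g$b <- g$b + colSums(da)
      dh <- da %*% net$W_rec
    }
    gn <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
    if (gn > 1) g <- lapply(g, function(x) x / gn)  # clip global norm
    for (nm in names(g)) {
      vel[[nm]] <- momentum * vel[[nm]] - lr * g[[nm]]
      net[[nm]] <- net[[nm]] + vel[[nm]]
    }
    if (!is.null(target_error) && step %% 50 == 0) {
      if (network_test_error(net, n = 32) < target_error) break
    }
  }
  net$history <- history
  net$test_error <- network_test_error(net, n = 64)
  class(net) <- "rnn_network"
  net
}

#' Mean readout error of a network on fresh random trials
#'
#' @param net An `rnn_network`.
#' @param n Test trials.
#' @param seed Integer seed.
#' @return Mean Euclidean error in px.
#' @export
network_test_error <- function(net, n = 64, seed = 12345) {
  set.seed(seed)
  tr <- random_trials(net$task, n)
  bt <- render_batch(net$task, tr$start, tr$target,
                     seeds = sample.int(.Machine$integer.max, n))
  pred <- rnn_forward(net, bt$X)$out * net$out_scale
  mean(sqrt(rowSums((pred - bt$Y)^2)))
}

#' Map the reference-session trajectories into the world frame
#'
#' The 24 short trajectories are laid out on a hexagon inscribed in the
#' world frame: the port spacing is scaled to `scale` times half the world
#' size so all ports fall inside it.
#'
#' @param task A [frame_task()].
#' @param scale Port spacing as a fraction of half the world size.
#' @return Data frame with `start_port`, `target_port`, `direction` and
#'   world coordinates `start_x/y`, `target_x/y` (px).
#' @export
reference_trajectories_world <- function(task, scale = 0.8) {
  spacing <- scale * task$world_px / 2
  wall <- build_port_wall(spacing = spacing, port_radius = spacing / 5)
  des <- session_design("reference", wall)
  co <- variable_coordinates(des$trajectories, wall)
  cbind(des$trajectories[c("start_port", "target_port", "direction")],
        co[c("start_x", "start_y", "target_x", "target_y")])
}

#' Hidden-state activity of a network over the test trajectories
#'
#' Runs each of the 24 reference trajectories through the network
#' (`repeats` renderings with fresh distractors each) and collects hidden
#' unit activity per frame.
#'
#' @param net An `rnn_network`.
#' @param repeats Renderings per trajectory.
#' @param seed Integer seed.
#' @param probe_distractors Number of distractor pixels on the probe
#'   renders, or `NULL` to keep the training task's count. Distractors
#'   are visible on every frame, so they add variance to condition-mean
#'   activity; `probe_distractors = 0` gives clean probe trials for
#'   representational analyses while leaving training untouched.
#' @return List with `H` (array trials x frames x units), `info` (trial
#'   table with world coordinates) and `cond` (trajectory index per trial).
#' @export
network_trajectory_activity <- function(net, repeats = 2, seed = 1,
                                        probe_distractors = NULL) {
  task <- net$task
  if (!is.null(probe_distractors)) task$n_distractors <- probe_distractors
  trj <- reference_trajectories_world(task)
  n <- nrow(trj) * repeats
  idx <- rep(seq_len(nrow(trj)), repeats)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  X <- array(0, c(n, task$n_frames, task$n_input))
  for (i in seq_len(n)) {
    k <- idx[i]
    X[i, , ] <- render_trial(task, c(trj$start_x[k], trj$start_y[k]),
                             c(trj$target_x[k], trj$target_y[k]),
                             seed = seeds[i])
  }
  fw <- rnn_forward(net, X)
  H <- array(0, c(n, task$n_frames, net$n_hidden))
  for (t in seq_len(task$n_frames)) H[, t, ] <- fw$H[[t]]
  list(H = H, info = trj[idx, ], cond = idx)
}

cv_linear_r2 <- function(S, Y, k = 6, seed = 1) {
  # k-fold CV R-squared of OLS from features S to 2D coordinates Y
  set.seed(seed)
  n <- nrow(S)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- matrix(NA_real_, n, 2)
  for (f in seq_len(k)) {
    tr <- fold != f
    B <- stats::lm.fit(cbind(1, S[tr, , drop = FALSE]),
                       Y[tr, , drop = FALSE])$coefficients
    pred[!tr, ] <- cbind(1, S[!tr, , drop = FALSE]) %*% B
  }
  1 - sum((Y - pred)^2) / sum(sweep(Y, 2, colMeans(Y))^2)
}

#' Linear decodability of spatial variables from hidden units per frame
#'
#' For each frame, projects hidden activity onto its first `n_pcs`
#' principal components and linearly decodes the start position, movement
#' vector and target position (world coordinates), reporting the k-fold
#' cross-validated R-squared.
#'
#' @param net An `rnn_network` (or the result of
#'   [network_trajectory_activity()]).
#' @param repeats,seed Passed to [network_trajectory_activity()].
#' @param n_pcs Principal components kept per frame.
#' @param k CV folds.
#' @return Matrix frames x 3 (`start`, `vector`, `target`) of CV R-squared.
#' @export
decode_hidden <- function(net, repeats = 3, seed = 1, n_pcs = 4, k = 6) {
  act <- if (inherits(net, "rnn_network")) {
    network_trajectory_activity(net, repeats = repeats, seed = seed)
  } else net
  info <- act$info
  targets <- list(
    start = cbind(info$start_x, info$start_y),
    vector = cbind(info$target_x - info$start_x,
                   info$target_y - info$start_y),
    target = cbind(info$target_x, info$target_y)
  )
  Tn <- dim(act$H)[2]
  out <- matrix(NA_real_, Tn, 3, dimnames = list(NULL, names(targets)))
  for (t in seq_len(Tn)) {
    S <- stats::prcomp(act$H[, t, ])$x[, seq_len(n_pcs), drop = FALSE]
    for (v in names(targets)) {
      out[t, v] <- cv_linear_r2(S, targets[[v]], k = k, seed = seed + t)
    }
  }
  out
}
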