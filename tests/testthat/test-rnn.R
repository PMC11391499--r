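test_that("frame tasks describe the four input/output combinations", {
  task <- frame_task("ego", "allo")
  expect_equal(task$n_input, task$down_px^2)
  expect_equal(egoallo:::task_name(task), "ego-allo")
  expect_error(frame_task("world", "ego"))
})

test_that("world-to-pixel mapping pins the correct frame to the centre", {
  task <- tiny_task("ego", "ego")
  ctr <- (task$native_px + 1) / 2
  # ego input: the start port projects to the image centre
  p <- egoallo:::world_to_pixel(task, c(5, -3), start_xy = c(5, -3))
  expect_equal(unname(p), c(ctr, ctr))
  # allo input: the world origin projects to the centre regardless of start
  ta <- tiny_task("allo", "ego")
  p0 <- egoallo:::world_to_pixel(ta, c(0, 0), start_xy = c(5, -3))
  expect_equal(unname(p0), c(ctr, ctr))
  # y points up, rows grow downward
  py <- egoallo:::world_to_pixel(ta, c(0, 4), start_xy = c(0, 0))
  expect_equal(unname(py["row"]), ctr - 4)
})

test_that("rendered trials show the target on the target frame only", {
  task <- tiny_task("ego", "ego")
  native <- render_trial(task, c(2, 1), c(-6, 1), seed = 3, down = FALSE)
  expect_equal(dim(native), c(task$n_frames, 50, 50))
  ints <- task$intensities
  expect_equal(max(native[task$target_frame, , ]), ints$target)
  expect_equal(max(native[1, , ]), ints$start)
  # all frames other than the target frame are identical
  for (f in seq_len(task$n_frames)[-task$target_frame]) {
    expect_equal(native[f, , ], native[1, , ])
  }
  # down-sampled frames: same structure, flattened
  flat <- render_trial(task, c(2, 1), c(-6, 1), seed = 3)
  expect_equal(dim(flat), c(task$n_frames, task$down_px^2))
  expect_false(isTRUE(all.equal(flat[task$target_frame, ], flat[1, ])))
  # out-of-frame ports are rejected
  expect_error(render_trial(task, c(0, 0), c(99, 0), seed = 1),
               "world frame")
})

test_that("down-sampling averages blocks and preserves the mean", {
  img <- matrix(runif(100), 10, 10)
  ds <- egoallo:::down_sample(img, 5)
  expect_equal(dim(ds), c(5, 5))
  expect_equal(mean(ds), mean(img))
  expect_equal(ds[1, 1], mean(img[1:2, 1:2]))
  # constant images stay constant
  expect_equal(egoallo:::down_sample(matrix(2, 12, 12), 4),
               matrix(2, 4, 4), ignore_attr = TRUE)
})

test_that("the forward pass is deterministic with bounded hidden states", {
  task <- tiny_task()
  net <- egoallo:::init_network(task, n_hidden = 12, seed = 4)
  tr <- egoallo:::random_trials(task, 5)
  bt <- egoallo:::render_batch(task, tr$start, tr$target, seeds = 1:5)
  fw1 <- egoallo:::rnn_forward(net, bt$X)
  fw2 <- egoallo:::rnn_forward(net, bt$X)
  expect_identical(fw1$out, fw2$out)
  expect_length(fw1$H, task$n_frames)
  expect_true(all(abs(fw1$H[[task$n_frames]]) <= 1))
  expect_equal(dim(fw1$out), c(5, 2))
})

test_that("training reduces the readout error", {
  task <- tiny_task("ego", "ego")
  net <- train_network(task, n_hidden = 24, steps = 150, seed = 5)
  expect_s3_class(net, "rnn_network")
  # loss goes down over training
  h <- net$history
  expect_lt(mean(tail(h, 20)), mean(head(h, 20)))
  # better than an untrained network on held-out trials
  net0 <- egoallo:::init_network(task, n_hidden = 24, seed = 5)
  net0$history <- numeric(0)
  class(net0) <- "rnn_network"
  expect_lt(net$test_error, network_test_error(net0))
})

test_that("reference trajectories map inside the world frame", {
  task <- tiny_task()
  trj <- reference_trajectories_world(task, scale = 0.8)
  expect_equal(nrow(trj), 24)
  half <- task$world_px / 2
  expect_true(all(abs(trj[, c("start_x", "start_y", "target_x",
                              "target_y")]) <= half))
  # port spacing scaled to 0.8 x half the world size
  d <- sqrt((trj$target_x - trj$start_x)^2 + (trj$target_y - trj$start_y)^2)
  expect_equal(unique(round(d, 9)), round(0.8 * half, 9))
})

test_that("trajectory activity has one row per rendered trial", {
  task <- tiny_task()
  net <- egoallo:::init_network(task, n_hidden = 8, seed = 6)
  class(net) <- "rnn_network"
  act <- network_trajectory_activity(net, repeats = 2, seed = 7)
  expect_equal(dim(act$H), c(48, task$n_frames, 8))
  expect_equal(act$cond, rep(1:24, 2))
  expect_equal(nrow(act$info), 48)
  # distractor-free probes make repeats of a condition identical
  act0 <- network_trajectory_activity(net, repeats = 2, seed = 7,
                                      probe_distractors = 0)
  expect_equal(act0$H[1, , ], act0$H[25, , ])
  expect_false(isTRUE(all.equal(act$H[1, , ], act$H[25, , ])))
})

test_that("cross-validated linear decoding is exact for linear targets", {
  set.seed(71)
  S <- matrix(rnorm(200), 50, 4)
  B <- matrix(rnorm(8), 4, 2)
  Y <- S %*% B + 3
  expect_gt(egoallo:::cv_linear_r2(S, Y, k = 5), 0.999)
  # unrelated targets give near-zero (possibly negative) CV R^2
  expect_lt(egoallo:::cv_linear_r2(S, matrix(rnorm(100), 50, 2), k = 5), 0.3)
})

test_that("RDMs and RSA similarity behave as correlations", {
  set.seed(72)
  act <- matrix(rnorm(24 * 10), 24, 10)
  rdm <- representational_dissimilarity(act)
  expect_equal(dim(rdm), c(24, 24))
  expect_equal(unname(diag(rdm)), rep(0, 24), tolerance = 1e-12)
  expect_equal(rdm, t(rdm))
  expect_equal(rsa_similarity(act, act), 1)
  # unit scaling leaves the RDM unchanged
  expect_equal(rsa_similarity(act, act * 3), 1)
  expect_error(rsa_similarity(act, act[1:20, ]), "condition sets differ")
})

test_that("population condition activity averages the right trials", {
  pop <- generate_population(c(direction = 3), small_design, 240, seed = 73,
                             p_error = 0, p_violation = 0)
  acts <- condition_activity_population(pop)
  expect_named(acts, c("pre_cue", "post_cue", "go"))
  expect_equal(dim(acts$post_cue), c(24, 3))
  # manual check of one cell
  des <- session_design("reference", pop$wall)
  cm <- count_spikes(pop$neurons[[1]], pop$trials, key_windows()$post_cue)
  cond1 <- des$trajectories[1, ]
  rows <- cm$start_port == cond1$start_port &
    cm$target_port == cond1$target_port
  expect_equal(unname(acts$post_cue[1, 1]), mean(cm$count[rows]) / 0.3)
})

test_that("network condition activity keeps the requested frames", {
  task <- tiny_task()
  net <- egoallo:::init_network(task, n_hidden = 8, seed = 74)
  class(net) <- "rnn_network"
  act <- network_trajectory_activity(net, repeats = 2, seed = 7)
  ca <- condition_activity_network(act, frames = c(3, 7, 11))
  expect_named(ca, c("frame3", "frame7", "frame11"))
  expect_equal(dim(ca$frame7), c(24, 8))
  expect_equal(unname(ca$frame7[2, ]),
               unname(colMeans(act$H[act$cond == 2, 7, ])))
})

test_that("gain-field unit detection returns a scored table", {
  task <- tiny_task("ego", "ego")
  net <- train_network(task, n_hidden = 8, steps = 80, seed = 75)
  gf <- detect_gain_field_units(net, repeats = 1, seed = 8, k = 3,
                                restarts = 1)
  expect_equal(nrow(gf), 8)
  expect_named(gf, c("unit", "cv_r2_gain", "cv_r2_additive", "score",
                     "gain_field"))
  ok <- !is.na(gf$score)
  expect_equal(gf$score[ok], gf$cv_r2_gain[ok] - gf$cv_r2_additive[ok])
  expect_true(is.logical(gf$gain_field))
})
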