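test_that("pseudopopulations have the documented size and structure", {
  pop <- generate_population(c(direction = 6, start = 4), small_design, 240,
                             seed = 61, p_error = 0, p_violation = 0)
  pp_pos <- build_pseudopopulation(pop, "start", seed = 1)
  pp_dir <- build_pseudopopulation(pop, "direction", seed = 1)
  # 7 position conditions x 32 -> 224 per fold; 6 directions -> 192
  expect_equal(sum(pp_pos$fold == 1), 224)
  expect_equal(sum(pp_pos$fold == 2), 224)
  expect_equal(sum(pp_dir$fold == 1), 192)
  expect_equal(table(pp_pos$labels[pp_pos$fold == 1]),
               table(factor(0:6, levels = sort(unique(pp_pos$labels)))) * 32)
  # coordinates match the wall geometry
  xy <- port_xy(pop$wall, pp_pos$labels)
  expect_equal(unname(pp_pos$coords), unname(xy))
  # neuron bootstrap resamples with replacement from the pool
  expect_equal(length(pp_pos$neuron_draw), length(pop$neurons))
  expect_true(all(pp_pos$neuron_draw %in% seq_along(pop$neurons)))
})

test_that("pseudo-trial folds draw from disjoint trial halves", {
  pop <- generate_population(c(direction = 3), small_design, 240,
                             seed = 62, p_error = 0, p_violation = 0)
  pp <- build_pseudopopulation(pop, "direction", seed = 2,
                               bootstrap_neurons = FALSE)
  for (j in seq_along(pp$neuron_draw)) {
    t1 <- unique(pp$trial_rows[pp$fold == 1, j])
    t2 <- unique(pp$trial_rows[pp$fold == 2, j])
    expect_length(intersect(t1, t2), 0)
  }
  # only correct trials are ever referenced
  expect_true(all(pop$trials$outcome[pp$trial_rows] == "correct"))
})

test_that("under-sampled conditions are refused", {
  tiny <- generate_session(small_design, 240, seed = 63,
                           p_error = 0, p_violation = 0)
  tiny <- tiny[tiny$start_port != 3 | tiny$outcome != "correct", ]
  class(tiny) <- c("trial_table", "data.frame")
  # port 3 never a correct start -> cannot build a start pseudopopulation
  pop <- list(trials = tiny, neurons = list(), wall = small_wall)
  expect_error(build_pseudopopulation(pop, "start", min_trials = 8),
               "fewer than")
})

test_that("a noiseless linear population decodes exactly", {
  pop <- generate_population(c(none = 4), small_design, 240, seed = 64,
                             p_error = 0, p_violation = 0)
  pp <- build_pseudopopulation(pop, "start", seed = 3,
                               bootstrap_neurons = FALSE)
  # synthetic responses: exact functions of the trial's start coordinates,
  # spanning a 4-dimensional feature space that contains (x, y)
  co <- variable_coordinates(pop$trials, pop$wall)
  counts <- cbind(co$start_x,
                  co$start_y,
                  (co$start_x / 50)^2 + 3,
                  co$start_x * co$start_y / 100)
  res <- decode_window(pp, pop, key_windows()$pre_cue, n_pcs = 4,
                       counts_by_row = counts)
  expect_lt(max(res$errors), 1e-6 * pop$wall$spacing)
  expect_true(res$excluded_origin)
})

test_that("origin conditions are excluded from position error summaries", {
  pop <- generate_population(c(start = 8), small_design, 240, seed = 65,
                             p_error = 0, p_violation = 0)
  pp <- build_pseudopopulation(pop, "start", seed = 4)
  res <- decode_window(pp, pop, key_windows()$pre_cue)
  at_origin <- pp$coords[, 1] == 0 & pp$coords[, 2] == 0
  expect_equal(res$mean_error, mean(res$errors[!at_origin]))
  # direction decoding keeps every condition
  ppd <- build_pseudopopulation(pop, "direction", seed = 4)
  resd <- decode_window(ppd, pop, key_windows()$post_cue)
  expect_equal(resd$mean_error, mean(resd$errors))
  expect_false(resd$excluded_origin)
})

test_that("decoding error is low only where the variable is coded", {
  pop <- generate_population(c(direction = 10), small_design, 240, seed = 66,
                             p_error = 0, p_violation = 0)
  pp <- build_pseudopopulation(pop, "direction", seed = 5)
  res <- decode_window(pp, pop, key_windows()$post_cue)
  # direction information present: error well below the uninformed level
  # (mean distance between condition coordinates ~ spacing)
  expect_lt(res$mean_error, pop$wall$spacing)
  # pre-cue window carries no direction information yet
  res0 <- decode_window(pp, pop, key_windows()$pre_cue)
  expect_gt(res0$mean_error, res$mean_error)
})

test_that("delta-error timecourse favours the coded variable", {
  pop <- generate_population(c(direction = 10), small_design, 240, seed = 67,
                             p_error = 0, p_violation = 0)
  wins <- list(key_windows()$post_cue, key_windows()$go)
  dt <- delta_error_timecourse(pop, "target", "direction", wins,
                               n_pseudo = 6, n_perm = 500, seed = 7)
  expect_equal(nrow(dt), 2)
  # target error minus direction error positive in a direction-coding
  # population
  expect_true(all(dt$mean_delta > 0))
  expect_true(all(dt$p < 0.05))
  delta <- attr(dt, "delta")
  expect_equal(dim(delta), c(2, 6))
})

test_that("cross-window decoding matrix flags informative cells only", {
  pop <- generate_population(c(direction = 10), small_design, 240, seed = 68,
                             p_error = 0, p_violation = 0)
  wins <- list(key_windows()$pre_cue, key_windows()$post_cue)
  cw <- cross_window_matrix(pop, "direction", wins, n_pseudo = 5, seed = 8)
  expect_equal(dim(cw$mean_error), c(2, 2))
  # direction decodes post-cue (train = test = window 2) but not pre-cue
  expect_lt(cw$mean_error[2, 2], cw$mean_error[1, 1])
  expect_true(cw$significant[2, 2])
  expect_false(cw$significant[1, 1])
  expect_length(cw$null_extreme, 5)
  expect_equal(cw$threshold, min(cw$null_extreme))
})

test_that("condition-coordinate shuffles permute the mapping only", {
  pop <- generate_population(c(start = 4), small_design, 240, seed = 69,
                             p_error = 0, p_violation = 0)
  pp <- build_pseudopopulation(pop, "start", seed = 9)
  set.seed(10)
  shuf <- egoallo:::permute_condition_coords(pp)
  # same multiset of condition coordinates, consistent within label
  expect_equal(sort(shuf[, 1]), sort(pp$coords[, 1]))
  for (l in unique(pp$labels)) {
    rows <- shuf[pp$labels == l, , drop = FALSE]
    expect_equal(max(rows[, 1]) - min(rows[, 1]), 0)
    expect_equal(max(rows[, 2]) - min(rows[, 2]), 0)
  }
})
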