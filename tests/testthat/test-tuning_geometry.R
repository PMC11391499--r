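test_that("the PETH kernel is causal and integrates to one", {
  trials <- small_trials[1, , drop = FALSE]
  class(trials) <- class(small_trials)
  go <- trials$t_go[1]
  sp <- structure(list(neuron_id = 1L, spikes = list(go + 0.2), spec = NULL),
                  class = "spike_data")
  peth <- compute_peth(sp, trials, align = "go",
                       t_grid = seq(-0.5, 1.5, by = 0.05))
  # no contribution before the spike (causal kernel)
  expect_true(all(peth$rate[1, peth$t < 0.2] == 0))
  expect_gt(peth$rate[1, which.min(abs(peth$t - 0.25))], 0)
  # the kernel integrates to ~1 spike over the grid
  expect_equal(sum(peth$rate[1, ]) * 0.05, 1, tolerance = 0.05)
})

test_that("tuning curves convert counts to rates per level", {
  cm <- count_spikes(dir_neuron, small_trials, key_windows()$post_cue)
  tc <- tuning_curve(cm, "direction", direction_angles())
  expect_equal(nrow(tc), 6)
  mu <- tapply(cm$count, factor(cm$direction), mean) / 0.3
  expect_equal(sort(tc$rate), sort(as.numeric(mu)))
  # absent levels appear as NA
  sub <- cm[cm$direction != 0, ]
  class(sub) <- class(cm)
  attr(sub, "window") <- attr(cm, "window")
  tc0 <- tuning_curve(sub, "direction", direction_angles())
  expect_true(is.na(tc0$rate[tc0$level == "0"]))
})

test_that("preferred direction is the rate-weighted vector sum", {
  r <- setNames(c(10, 1, 1, 1, 1, 1), direction_angles())
  expect_equal(preferred_direction(r), 0)
  r2 <- setNames(c(1, 10, 1, 1, 1, 1), direction_angles())
  expect_equal(preferred_direction(r2), 60)
  # two equal opposite bumps: undefined
  r3 <- setNames(c(5, 0, 0, 5, 0, 0), direction_angles())
  pd <- preferred_direction(r3)
  expect_true(is.na(pd))
  expect_true(attr(pd, "undefined"))
  # the generative preference is recovered from data
  cm <- count_spikes(dir_neuron, small_trials, key_windows()$post_cue)
  est <- preferred_direction(tuning_curve(cm, "direction", direction_angles()))
  expect_lt(abs(wrap_angle(est - 60)), 30)
})

test_that("preferred position takes the argmax port and flags ties", {
  curve <- data.frame(level = as.character(0:6),
                      rate = c(1, 5, 2, 2, 2, 2, 2), n = 10)
  class(curve) <- c("tuning_curve", "data.frame")
  expect_equal(as.integer(preferred_position(curve)), 1L)
  curve$rate <- c(5, 5, 1, 1, 1, 1, 1)
  pp <- preferred_position(curve)
  expect_equal(as.integer(pp), 0L)
  expect_true(attr(pp, "tie"))
})

test_that("direction class labels are consistent", {
  expect_true(classify_direction(10)["horizontal"])
  expect_true(classify_direction(170)["horizontal"])
  expect_true(classify_direction(90)["vertical"])
  expect_true(classify_direction(-60)["downward"])
  expect_true(classify_direction(120)["upward"])
})

test_that("start-target correlation is high for matched spatial tuning", {
  # one neuron tuned to the same port as start (pre-cue) and target
  # (post-movement): merge a start-tuned and a target-tuned neuron with the
  # same preferred port
  tspec <- tuning_spec("target", baseline = 8, depth = 2.5, pref_port = 1L,
                       sigma_mm = small_wall$spacing)
  tneuron <- generate_neuron(tspec, small_trials, small_wall, seed = 30)
  merged <- start_neuron
  merged$spikes <- lapply(seq_along(merged$spikes), function(i) {
    sort(c(start_neuron$spikes[[i]], tneuron$spikes[[i]]))
  })
  r <- start_target_correlation(merged, small_trials)
  expect_gt(r, 0.5)
  rs <- start_target_correlation(merged, small_trials, split_half = TRUE,
                                 seed = 4)
  expect_gt(rs, 0.3)
})

test_that("population Fisher-z bootstrap detects shared positive tuning", {
  set.seed(31)
  r_pos <- tanh(rnorm(40, 0.6, 0.2))
  res <- fisher_z_population_test(r_pos, n_boot = 500, seed = 1)
  expect_equal(res$p, 0)
  expect_equal(res$p_floor, 1 / 500)
  r_null <- tanh(rnorm(40, 0, 0.3))
  res0 <- fisher_z_population_test(r_null, n_boot = 500, seed = 1)
  expect_gt(res0$p, 0.05)
  # Bonferroni multiplies and caps
  res_b <- fisher_z_population_test(r_null, n_boot = 500, seed = 1,
                                    bonferroni = 16)
  expect_equal(res_b$p, min(1, res0$p * 16))
})

test_that("switch time finds the start-to-target handover", {
  # merge a start-tuned neuron (epoch ends at go + 0.3) with a target-tuned
  # one (epoch starts at go): coding switches shortly after the go sound
  tspec <- tuning_spec("target", baseline = 8, depth = 2.5, pref_port = 4L,
                       sigma_mm = small_wall$spacing)
  tneuron <- generate_neuron(tspec, small_trials, small_wall, seed = 33)
  merged <- start_neuron
  merged$spikes <- lapply(seq_along(merged$spikes), function(i) {
    sort(c(start_neuron$spikes[[i]], tneuron$spikes[[i]]))
  })
  st <- switch_time(merged, small_trials, align = "go", from = -0.4, to = 1)
  expect_false(is.na(st))
  expect_true(st > 0 && st <= 1)
  # a pure start neuron never crosses
  st0 <- switch_time(start_neuron, small_trials, align = "go",
                     from = -0.4, to = 1)
  expect_true(is.na(st0) || st0 > 0.3)
})

test_that("shrinkage heatmap pulls sparse cells toward the grand mean", {
  cm <- count_spikes(dir_neuron, small_trials, key_windows()$post_cue)
  hm <- map_rate_heatmap(cm, small_wall, prior_weight = 1)
  expect_equal(nrow(hm), 42)  # 6 directions x 7 target ports
  grand <- mean(cm$count)
  filled <- hm[hm$n > 0, ]
  # manual check of the posterior-mean formula on one cell
  cell <- filled[1, ]
  rows <- cm$direction == cell$direction & cm$target_port == cell$target_port
  expect_equal(cell$rate_map,
               (sum(cm$count[rows]) + grand) / (cell$n + 1) / 0.3)
  # shrinkage moves cells toward the grand mean rate
  expect_true(all(abs(filled$rate_map - grand / 0.3) <=
                    abs(filled$rate_raw - grand / 0.3) + 1e-9))
  expect_true(all(is.na(hm$rate_map[hm$n == 0])))
})

test_that("warped windows tile the trial and rates match by hand", {
  ww <- warped_windows(small_trials)
  expect_equal(dim(ww$bounds), c(nrow(small_trials), 14, 2))
  i <- which(small_trials$outcome == "correct")[1]
  b <- ww$bounds[i, , ]
  # contiguous within each block and across cue/go/arrival joins
  expect_equal(b[1:13, 2], b[2:14, 1], tolerance = 1e-12)
  expect_equal(b[4, 1], small_trials$t_cue_on[i])
  expect_equal(b[7, 1], small_trials$t_go[i])
  expect_equal(b[12, 1], small_trials$t_arrival[i])
  wr <- warped_rates(dir_neuron, small_trials)
  expect_equal(ncol(wr), 14)
  ts <- dir_neuron$spikes[[i]]
  k <- 8  # second fifth of go-to-arrival
  expect_equal(wr[as.character(i), k],
               sum(ts > b[k, 1] & ts <= b[k, 2]) / (b[k, 2] - b[k, 1]))
})

test_that("direction tuning is stable across windows for a direction cell", {
  wins <- list(key_windows()$post_cue, key_windows()$go)
  pop <- list(dir_neuron, generate_neuron(dir_spec, small_trials, small_wall,
                                          seed = 44))
  m <- direction_stability_matrix(pop, small_trials, wins, n_boot = 300,
                                  seed = 6)
  expect_equal(dim(m$mean_r), c(2, 2))
  expect_true(all(m$mean_r > 0.3))
})
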