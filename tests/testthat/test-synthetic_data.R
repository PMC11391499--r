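test_that("session generation balances trajectories and orders events", {
  tr <- small_trials
  expect_equal(nrow(tr), 240)
  # balanced allocation: 240 = 10 x 24 trajectories exactly
  key <- paste(tr$start_port, tr$target_port)
  expect_true(all(table(key) == 10))
  # timeline on completed trials
  done <- tr$outcome != "violation"
  expect_true(all(tr$t_fixation_in > 0))
  delay <- tr$t_cue_on - tr$t_fixation_in
  expect_true(all(delay >= 0 & delay <= 0.29))
  expect_true(all(tr$t_go[done] >= tr$t_cue_on[done]))
  expect_true(all(tr$t_fixation_out[done] > tr$t_go[done]))
  expect_true(all(tr$t_arrival[done] > tr$t_fixation_out[done]))
  expect_true(all(tr$t_trial_end[done] > tr$t_arrival[done]))
  # fixation never exceeds 1.2 s
  expect_true(all(tr$t_go[done] - tr$t_fixation_in[done] <= 1.2 + 1e-12))
})

test_that("violations abort the trial before the go sound", {
  tr <- generate_session(small_design, 480, seed = 3,
                         p_error = 0.05, p_violation = 0.2)
  viol <- tr$outcome == "violation"
  expect_gt(sum(viol), 0)
  expect_true(all(is.na(tr$t_go[viol])))
  expect_true(all(is.na(tr$t_arrival[viol])))
  expect_true(all(!is.na(tr$t_fixation_out[viol])))
})

test_that("too few trials for the design is an error", {
  expect_error(generate_session(small_design, 100, seed = 1), "cannot give")
})

test_that("session generation is reproducible by seed", {
  a <- generate_session(small_design, 240, seed = 9)
  b <- generate_session(small_design, 240, seed = 9)
  expect_identical(a, b)
  c <- generate_session(small_design, 240, seed = 10)
  expect_false(identical(a, c))
})

test_that("tuning specs validate their parameters", {
  expect_error(tuning_spec("gain_field", baseline = 5), "missing parameters")
  expect_error(tuning_spec("additive", baseline = 5, b0 = 5, b1 = 0, b2 = 0,
                           sigma = 40, theta0 = 0)$b3, "missing parameters")
  sp <- tuning_spec("direction", baseline = 4, depth = 2, pref_angle = 120)
  expect_s3_class(sp, "tuning_spec")
  expect_equal(sp$pref_angle, 120)
})

test_that("generative rates match the tuning functions", {
  wall <- small_wall
  trj <- session_design("reference", wall)$trajectories
  # direction kind: baseline * (1 + depth * gaussian in angle)
  sp <- tuning_spec("direction", baseline = 10, depth = 2, pref_angle = 60,
                    sigma_deg = 40)
  r <- tuning_rate(sp, trj, wall)
  expect_equal(r[trj$direction == 60][1], 30)
  d180 <- wrap_angle(trj$direction - 60) == 180
  expect_equal(r[d180][1], 10 * (1 + 2 * exp(-180^2 / (2 * 40^2))))
  # start kind peaks at the preferred port
  sps <- tuning_spec("start", baseline = 5, depth = 3, pref_port = 2L,
                     sigma_mm = wall$spacing)
  rs <- tuning_rate(sps, trj, wall)
  expect_equal(max(rs), 20)
  expect_true(all(which(rs == 20) %in% which(trj$start_port == 2)))
  # negative generative rates are refused
  bad <- tuning_spec("additive", baseline = 1, b0 = 1, b1 = -10, b2 = 0,
                     b3 = 0, sigma = 40, theta0 = 0)
  expect_error(tuning_rate(bad, trj, wall), "negative")
})

test_that("random tuning specs stay inside the documented ranges", {
  set.seed(11)
  for (k in c("start", "direction", "target", "none")) {
    for (i in 1:20) {
      sp <- random_tuning_spec(k, small_wall)
      expect_true(sp$baseline >= 1 && sp$baseline <= 20)
      if (k != "none") expect_true(sp$depth >= 0.5 && sp$depth <= 3)
    }
  }
  # mixed kinds produce valid (non-negative) rates on the task conditions
  trj <- small_design$trajectories
  for (k in c("additive", "gain_field")) {
    for (i in 1:20) {
      sp <- random_tuning_spec(k, small_wall)
      expect_true(all(tuning_rate(sp, trj, small_wall) >= 0))
    }
  }
})

test_that("synthetic spiking is Poisson at the generative rate", {
  # direction-tuned neuron, post-cue window inside the tuned epoch
  w <- key_windows()$post_cue
  cm <- count_spikes(dir_neuron, small_trials, w)
  rate <- tuning_rate(dir_spec, cm, small_wall)
  mu <- tapply(cm$count, cm$direction, mean) / (w$t1 - w$t0)
  gen <- tapply(rate, cm$direction, mean)
  # means within 4 standard errors of the generative rates
  n <- table(cm$direction)
  se <- sqrt(gen / (w$t1 - w$t0) / as.numeric(n))
  expect_true(all(abs(mu - gen) < 4 * se))
  # outside the tuned epoch the neuron sits at baseline
  pre <- count_spikes(dir_neuron, small_trials, key_windows()$pre_cue)
  expect_lt(abs(mean(pre$count) / 0.3 - dir_spec$baseline),
            4 * sqrt(dir_spec$baseline / 0.3 / nrow(pre)))
})

test_that("spike times are sorted and inside the trial", {
  ok <- vapply(seq_along(dir_neuron$spikes), function(i) {
    ts <- dir_neuron$spikes[[i]]
    !is.unsorted(ts) && all(ts >= 0) && all(ts <= small_trials$t_trial_end[i])
  }, logical(1))
  expect_true(all(ok))
})

test_that("session round-trips through the plain-text format", {
  pop <- generate_population(c(direction = 2, none = 1), small_design, 240,
                             seed = 5)
  dir <- tempfile("session")
  write_session(pop, dir)
  back <- read_session(dir)
  expect_equal(back$trials$t_cue_on, pop$trials$t_cue_on)
  expect_equal(back$trials$outcome, pop$trials$outcome)
  for (j in seq_along(pop$neurons)) {
    expect_equal(lengths(back$neurons[[j]]$spikes),
                 lengths(pop$neurons[[j]]$spikes))
    expect_equal(unlist(back$neurons[[j]]$spikes),
                 unlist(pop$neurons[[j]]$spikes), tolerance = 1e-12)
  }
  unlink(dir, recursive = TRUE)
})
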