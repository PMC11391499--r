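# Shared small fixtures, built once per test run.

small_wall <- build_port_wall()
small_design <- session_design("reference", small_wall)

# a clean (no errors/violations) reference session, 10 trials per trajectory
small_trials <- generate_session(small_design, 240, seed = 42,
                                 p_error = 0, p_violation = 0)

# a strongly direction-tuned neuron on that session
dir_spec <- tuning_spec("direction", baseline = 8, depth = 2.5,
                        pref_angle = 60, sigma_deg = 40)
dir_neuron <- generate_neuron(dir_spec, small_trials, small_wall, seed = 7)

# a strongly start-tuned neuron
start_spec <- tuning_spec("start", baseline = 8, depth = 2.5,
                          pref_port = 1L, sigma_mm = small_wall$spacing)
start_neuron <- generate_neuron(start_spec, small_trials, small_wall, seed = 8)

# a tiny reduced-scale network task (fast to train, same structure)
tiny_task <- function(input = "ego", output = "ego") {
  frame_task(input, output, native_px = 50, down_px = 20, world_px = 26,
             n_distractors = 2)
}

# brute-force leave-one-out CV Poisson log-likelihood (oracle for the
# closed form): refit the per-level mean with each trial held out
loo_loglik_bruteforce <- function(y, labels) {
  ll <- 0
  for (i in seq_along(y)) {
    same <- setdiff(which(labels == labels[i]), i)
    pred <- max(mean(y[same]), 1e-6)
    ll <- ll + dpois(y[i], pred, log = TRUE)
  }
  ll
}
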