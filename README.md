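# egoallo

Tools for studying self-centered (egocentric) versus world-centered
(allocentric) spatial coding in cortical populations during a visually
guided orienting task, together with a synthetic spiking-data generator
and a small recurrent-network model for comparing reference frames in
artificial agents.

## The task and the scientific question

A subject faces a wall of seven nose ports: one at the centre and six at
the vertices of a hexagon (spacing 50 mm, port radius 11 mm). Each trial
starts with fixation at a lit **start** port; after a short random delay
a **target** port lights up; after a variable fixation period a go sound
releases the subject, which pokes the target. The 7 × 6 = 42 ordered
port pairs collapse onto 30 distinct straight-line **trajectories**
(24 short steps between adjacent ports and 6 long diameters through the
centre), and every trajectory points along one of six **directions**,
60° apart.

Because start port, target port and movement direction are partially
de-confounded by the design (many start–target pairs share a direction,
and many directions occur from several starts), single-neuron firing can
be attributed to:

- **start** — where the subject currently is (a position, world-centered),
- **target** — where it is about to go (a position, world-centered),
- **direction** — which way it will move (self-centered), or
- **none** — no reliable spatial modulation.

The package implements the full analysis chain for this attribution,
plus population-level decoding and a network model, in seven modules:

1. **Task geometry** — the port wall, trajectory sets and session
   designs (`build_port_wall()`, `session_design()`; designs
   `"reference"` with 24 trajectories, `"distance"` with 18, and
   `"four_direction"` with 16).
2. **Synthetic data** — a generative model of trials and epoch-gated
   Poisson spike trains with known tuning (`generate_session()`,
   `tuning_spec()`, `generate_neuron()`, `generate_population()`).
3. **Selectivity analysis** — single-variable Poisson regressions with
   closed-form leave-one-out cross-validation and label-shuffle
   permutation tests (`classify_selectivity()`, `selectivity_fractions()`,
   `selectivity_recovery()`).
4. **Tuning geometry** — preferred directions and positions, start–target
   tuning correlations, coding-handover times and stability matrices
   (`preferred_direction()`, `start_target_correlation()`,
   `switch_time()`, `tuning_correlation_matrix()`).
5. **Mixed selectivity** — nonlinear encoding models (pure direction,
   start-position plane, multiplicative gain field, additive
   direction + position) compared by cross-validated R²
   (`fit_all_encoding_models()`, `compare_models()`).
6. **Population decoding** — condition-balanced pseudopopulations and
   linear decoding of target position and movement direction from
   z-scored, PCA-reduced activity (`build_pseudopopulation()`,
   `decode_window()`, `delta_error_timecourse()`, `cross_window_matrix()`).
7. **Network reference frames** — a small recurrent network trained on a
   pixel-level version of the task in all four combinations of
   self-/world-centered input and output, compared to neural data by
   representational similarity analysis (`frame_task()`,
   `train_network()`, `rsa_similarity()`, `detect_gain_field_units()`).

## Model notation

For a neuron with spike count \(y_i\) in a fixed window on trial \(i\):

- **Single-variable Poisson model.** For a labelling \(\ell(i)\) by one
  variable (start, direction or target), the maximum-likelihood rate per
  level is the level mean. Model quality is the leave-one-out
  cross-validated log-likelihood, computed in closed form: with level
  sum \(S_\ell\) and level count \(n_\ell\), the held-out prediction for
  trial \(i\) is \((S_{\ell(i)} - y_i)/(n_{\ell(i)} - 1)\), floored at
  \(10^{-6}\). Significance is assessed by shuffling labels across
  trials; the p value is the fraction of shuffles whose statistic is
  strictly greater than the observed one. A neuron's label is the
  variable with the smallest p value (ties broken by cross-validated
  log-likelihood), or `"none"` if the minimum p is ≥ 0.01.
- **Encoding models.** With movement direction \(\theta\), start
  coordinates \((x, y)\) and a normalized circular Gaussian
  \(N(\theta; \sigma)\) peaking at a fixed preferred direction
  \(\theta_0\) (the rate-weighted vector sum of the empirical tuning
  curve):
  - direction: \(r = b_0 + b_1\,N(\theta;\sigma)\)
  - start plane: \(r = b_0 + b_x x + b_y y\)
  - gain field: \(r = (b_0 + b_x x + b_y y)\,(1 + b_1 N(\theta;\sigma))\)
  - additive: \(r = b_0 + b_x x + b_y y + b_1 N(\theta;\sigma)\)

  Each is fit by maximum likelihood (Poisson by default) with
  multi-start box-constrained quasi-Newton optimization, and scored by
  stratified k-fold cross-validated R² on held-out trials. Models are
  compared by bootstrapping the paired difference of Fisher-z
  transformed CV R² across neurons.
- **Pseudopopulations.** Neurons recorded in separate sessions are
  combined by resampling a fixed number of trials per condition within
  each of two disjoint trial folds, z-scoring, pooling, and projecting
  onto the top principal components; target position or direction is
  then read out by multivariate linear regression fit on one fold and
  evaluated on the other.

## Worked example

Generate a synthetic session on the reference design, simulate a
direction-tuned neuron, and recover its tuning:

```r
library(egoallo)

wall   <- build_port_wall()
design <- session_design("reference", wall)
design
#> <session_design> reference - 24 trajectories, 6 directions, >= 8 trials/condition

trials <- generate_session(design, n_trials = 240, seed = 1)
table(trials$outcome)
#>   correct     error violation
#>       210        13        17

# a neuron tuned to movement direction 60 deg, 8 Hz baseline, 2.5x depth
spec   <- tuning_spec("direction", baseline = 8, depth = 2.5,
                      pref_angle = 60, sigma_deg = 40)
neuron <- generate_neuron(spec, trials, wall, seed = 2)

# classify its selectivity in the 300 ms after target-cue onset
counts <- count_spikes(neuron, trials, key_windows()$post_cue)
sel    <- classify_selectivity(counts, n_perm = 1000, seed = 3)
sel$best
#> [1] "direction"
round(sel$p, 4)
#>     start direction    target
#>     0.002     0.000     0.000

# direction is preferred over the (correlated) position variables, and
# the preferred angle is recovered from the empirical tuning curve
curve <- tuning_curve(counts, "direction", direction_angles())
round(curve$rate, 2)   # rates at 0, 60, 120, 180, -120, -60 deg
#> [1] 14.67 25.29 14.65  6.57  7.41  7.35
round(preferred_direction(curve), 1)
#> [1] 58.4
```

All three permutation p values are small — start, direction and target
are geometrically correlated, so a direction-tuned neuron also carries
some position information — but direction has both the smallest p and
the best cross-validated fit, so the neuron is correctly labelled.

## License

MIT (see `LICENSE`).
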