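---
title: "Methods: dissociating self-centered and world-centered spatial coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissociating self-centered and world-centered spatial coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(egoallo)
```

This vignette documents the statistical models, algorithms and numerical
conventions implemented in `egoallo`, and the rationale behind parameter
defaults. The package analyzes (real or synthetic) spiking data from a
multi-directional visually guided orienting task, asking whether neurons
encode movement plans in a **self-centered** frame (the movement direction,
invariant to where on the wall the movement starts) or a **world-centered**
frame (the start or target port position on the wall).

## 1. Task geometry

The operant wall carries seven ports: a central port at the origin and six
ports on the vertices of a regular hexagon (`build_port_wall()`). Port
coordinates are in mm; only the relative geometry matters downstream, so the
centre-to-neighbour `spacing` is a free scale (default 50 mm, constrained to
exceed twice the 11 mm port radius so ports cannot overlap).

Of the 42 ordered port pairs, the task uses the 30 for which the ports are
adjacent (**short** trajectories, one spacing long) or opposite hexagon
vertices (**long** trajectories, passing through the central port). Each of
the six directions \(\{0, \pm 60, \pm 120, 180\}^\circ\) has exactly five
trajectories — four short and one long — so movement direction is fully
crossed with start position. Three session designs subset these:
the *reference* design (24 short trajectories, 4 per direction), the
*distance* design (18: per direction the two spokes through the centre plus
the long trajectory), and the *four-direction* design (16 short
trajectories of the oblique directions).

```{r geometry}
wall <- build_port_wall()
table(enumerate_trajectories(wall)$direction,
      enumerate_trajectories(wall)$distance_class)
```

The identity `target = start + direction` holds exactly in coordinates
(`variable_coordinates()`), which is what makes the three spatial variables
mutually confounded at the single-trial level and motivates the designs and
analyses below.

## 2. Synthetic sessions and neurons

`generate_session()` simulates the trial timeline: trajectory allocation is
balanced (equal counts per trajectory up to a shuffled remainder); the
target cue lights 0–0.29 s after fixation onset; the jittered fixation
period lasts up to 1.2 s and always outlasts the cue delay; the go sound
ends fixation; the movement ends at the target poke. Violations (early
withdrawals) abort the trial, leaving the go and arrival events missing.

`generate_neuron()` draws inhomogeneous-Poisson spike trains whose rate is
piecewise constant in time: a kind-specific epoch of the trial carries the
condition-dependent tuned rate, and the rest of the trial runs at baseline.
Epochs follow the variables' natural time course: start tuning from trial
start until shortly after the go sound, direction tuning from cue onset to
arrival, target tuning from the go sound to the trial end. Tuning kinds:

* `start` / `target`: Gaussian bump over wall distance to a preferred port,
  \(r = b\,(1 + d\, e^{-\|x - x_0\|^2 / 2\sigma_{mm}^2})\);
* `direction`: Gaussian bump over angular distance to a preferred angle;
* `additive` / `gain_field`: the mixed encoding models of Section 5 used
  generatively;
* `none`: constant baseline.

`random_tuning_spec()` draws baselines log-uniformly on 1–20 Hz and
modulation depths uniformly on 0.5–3 × baseline — spanning weakly to
strongly tuned neurons so recovery statistics are not dominated by easy
cases. For `gain_field` specs the position-slope orientation is drawn
within ±60° of the direction *opposite* the preferred direction. This keeps
the tuning centre identifiable from the session-marginal direction tuning
curve: in the reference design the mean start position of movements in
direction \(\theta\) is \(-\tfrac{s}{2} u(\theta)\), so a slope aligned
*with* the preferred direction would flip the marginal tuning peak by 180°
and no marginal procedure could recover the generative centre. Recorded
neurons enter the gain-field analysis only when direction-tuned, which has
the same effect of aligning the measured and generative preferred
directions.

## 3. Windowed counts and single-neuron selectivity

All analyses count spikes in causal windows \((t_0, t_1]\) relative to a
task event (`count_spikes()`; the four key windows are pre-cue, post-cue,
go and arrival, `key_windows()`). Only correct trials are analyzed unless
requested otherwise; trials missing the alignment event are dropped with a
warning.

For one window and one spatial variable the selectivity model is a one-way
Poisson GLM, `count ~ level(variable)`, whose maximum-likelihood fit is the
per-level mean count (identity- and log-link MLEs coincide for a saturated
one-way layout, so the fit is computed in closed form). Two summaries are
reported:

* the **variance-explained R²** of the fitted means (not cross-validated;
  used for time courses where only the argmax matters), and
* the **leave-one-out cross-validated log-likelihood**: the held-out
  prediction for trial \(i\) is the mean count of the *other* trials at its
  level, \(\hat\mu_{-i} = (S_{\ell(i)} - y_i) / (n_{\ell(i)} - 1)\), floored
  at \(10^{-6}\), and the statistic is \(\sum_i \log P(y_i \mid
  \hat\mu_{-i})\). The closed form is exactly equal to refitting with each
  trial held out (tested against brute force).

The **permutation test** (`permutation_test()`) shuffles the variable's
trial labels and recomputes the CV log-likelihood; \(p\) is the fraction of
shuffles *strictly greater* than the observed statistic, so a decisively
tuned neuron can reach \(p = 0\) (reported floor: \(1/n_\text{perm}\)).
A neuron's **best variable** (`assign_best_variable()`) is the one with the
smallest \(p\) (ties — common, because \(p\) is a discrete fraction — are
broken by the larger CV log-likelihood); if no \(p\) falls below
\(\alpha = 0.01\) the neuron is labelled `none`. We use 5,000 permutations
at full scale and 1,000 in the scaled acceptance runs.

Because the three variables are correlated across trials (Section 1), a
start-tuned neuron also shows apparent target modulation; the comparison of
CV likelihoods, not the marginal significance, is what arbitrates. The
synthetic recovery harness (`selectivity_recovery()`) quantifies exactly
this: with randomized baselines and depths, >70% of tuned neurons are
assigned their generative variable, and >90% of those assigned any label at
all — errors are dominated by weakly tuned neurons falling below
\(\alpha\), not by cross-variable confusion.

## 4. Tuning geometry

* **PETHs** (`compute_peth()`) convolve spike trains with a causal
  half-Gaussian kernel (400 ms SD, support on the past only, unit
  integral), so displayed rates at time \(t\) depend only on spikes at or
  before \(t\).
* The **preferred direction** is the angle of the rate-weighted vector sum
  of the six direction unit vectors; it is `NA` (flagged `undefined`) when
  the resultant is numerically zero. The **preferred position** is the
  argmax port (ties flagged, lowest id returned).
* The **start–target tuning correlation** is the Pearson correlation
  between the 7-port start tuning curve in the pre-cue window and the
  7-port target tuning curve at arrival. The split-half variant correlates
  curves computed from disjoint trial halves (both directions, averaged) so
  shared single-trial noise cannot inflate it.
* Population-level tests Fisher-z-transform per-neuron correlations (values
  at ±1 clipped to ±(1−10⁻¹⁰)) and bootstrap the mean z
  (`fisher_z_population_test()`, 10⁴ resamples at full scale); \(p\) is the
  fraction of resamples at or below zero, optionally Bonferroni-scaled, and
  `p_floor` applies the \(1/n_\text{boot}\) minimum-reportable-p
  convention.
* The **switch time** (`switch_time()`) runs the start- and target-GLM R²
  in causal sliding windows (300 ms wide, 50 ms steps), smooths each curve
  with a 3-bin moving average, and reports the first window after the
  positive peak of \(R^2_\text{start} - R^2_\text{target}\) where the
  difference turns negative.
* The per-trajectory **rate heatmap** (`map_rate_heatmap()`) regularizes
  sparse cells with a conjugate-gamma prior centred on the grand mean with
  a pseudo-count of one trial: \(\hat r = (\sum y + w\,\bar y) / (n + w)\).
  This is the lightest shrinkage that keeps single-trial cells finite and
  leaves well-sampled cells essentially at their sample mean.
* **Warped windows** (`warped_windows()`) tile every trial with 14 windows:
  3 × 300 ms before the cue, cue-to-go in thirds, go-to-arrival in fifths,
  and 3 × 300 ms after arrival — aligning variable-length periods across
  trials.

## 5. Mixed-selectivity encoding models

Four rate models describe post-cue firing as a function of movement
direction \(\theta\) (degrees from the neuron's preferred direction) and
start position \((x, y)\):

\[
\begin{aligned}
\text{direction:} \quad & f = b_0 + b_1 N(\theta;\sigma) \\
\text{start\_plane:} \quad & f = b_0 + b_1 x + b_2 y \\
\text{gain\_field:} \quad & f = b_0 + (b_1 x + b_2 y)\, N(\theta;\sigma) \\
\text{additive:} \quad & f = b_0 + b_1 x + b_2 y + b_3 N(\theta;\sigma)
\end{aligned}
\]

with \(N(\theta;\sigma) = \tfrac{1}{\sigma\sqrt{2\pi}}
e^{-\theta^2/2\sigma^2}\), \(\sigma \in [10, 180]\) degrees and
\(b_0 \in [0, 100]\) Hz. The preferred direction is estimated once from the
direction tuning curve (vector sum) and held fixed across all four fits, so
the models differ only in how position and direction combine. Fits maximize
the Poisson likelihood of window counts by bounded quasi-Newton
(`L-BFGS-B`) from a moment-based start plus randomized restarts; a
quadratic penalty keeps the rate non-negative on the data and predictions
are floored at 10⁻⁶ Hz. For continuous signals (network hidden units)
the same machinery runs with a Gaussian likelihood and an unconstrained
offset.

Model comparison uses the **cross-validated R²**: folds are stratified by
(direction × start) condition (20 at full scale), held-out predictions are
pooled, and \(R^2_{CV} = 1 - SS_\text{res}/SS_\text{tot}\) — negative when
a model generalizes worse than the mean, and deliberately never clamped.
Neurons enter the population comparison when their mean CV R² over the four
models exceeds 0.05 (with a reported sensitivity sweep of that threshold).
Pairwise comparisons bootstrap the mean difference of Fisher-z-transformed
CV R² (10⁵ resamples at full scale); the pair is oriented so the mean
difference is non-negative and \(p\) is the fraction of bootstrap means at
or below zero.

`recovery_harness()` closes the loop: gain-field-generated synthetic
neurons are best fit by the gain-field model and additive-generated by the
additive model, with the pairwise bootstrap at its floor in both
directions.

## 6. Pseudopopulation decoding

`build_pseudopopulation()` assembles condition-labelled pseudo-trials: per
neuron (drawn with replacement from the pool — the neuron-level bootstrap,
leaving on average \(1-(1-1/n)^n \approx 63.2\%\) unique neurons), correct
trials of each condition are split into two folds and 32 pseudo-trials per
fold per condition are resampled with replacement, with an independent
seed per neuron so trial-by-trial noise correlations are destroyed.
Position variables have 7 conditions (224 pseudo-trials per fold),
direction has 6 (192); direction conditions sit at spacing-length unit
vectors so errors share the mm scale.

`decode_window()` z-scores the pooled two-fold count matrix, projects it on
the first 4 principal components, and fits a multivariate linear regression
from PC scores to the 2-D condition coordinates on one fold, evaluating
Euclidean error on the other (both directions). Fitting the z-score/PCA
basis on the pooled folds introduces a mild, deliberate leakage — the basis
(not the decoder) sees the test fold — matching the source analyses; the
decoder itself is strictly cross-validated. Position-error summaries
exclude conditions at the (0, 0) coordinate, which regression decoders
flatter by collapsing toward the origin.

Time courses (`delta_error_timecourse()`) decode both variables from paired
pseudopopulations and test the per-pseudopopulation error difference with a
two-sided sign-flip permutation. Cross-window training/testing matrices
(`cross_window_matrix()`) use the **extreme-pixel** correction: each
pseudopopulation contributes one condition-shuffled map; because smaller
error is better, each shuffled map's extreme is its *minimum* error, and an
observed cell is significant only if it beats every shuffled extreme.

## 7. Reference-frame networks and RSA

`frame_task()` defines four tasks crossing input frame × output frame
(ego/allo). Inputs are image sequences (native 100 × 100 px, area-averaged
to 40 × 40, 11 frames) showing a surrounding visual-frame border, a 50 px
world-frame border, the start port, static distractor pixels, and — on
frame 4 only — the target port. With egocentric input the start port is
pinned to the image centre, so the world frame shifts with the start
position and carries the allocentric information; with allocentric input
the world frame is pinned. The required output at the last frame is the
movement vector (ego) or the target's world position (allo). Pixel
intensities (start 0.7, target 1.0, distractor 0.2, world frame 0.4, visual
frame 0.3) and the two frame borders are package choices that make both
frames recoverable from every image.

`train_network()` trains a vanilla recurrent network — tanh hidden layer
(100 units at full scale), linear 2-unit readout, loss on the final frame
only — by backpropagation through time with momentum SGD (learning rate
0.05, momentum 0.9), global gradient-norm clipping at 1, and coordinates
normalized by half the world size. Fresh trials are sampled every step, so
there is no training set to overfit. The reduced scale used in the test
suite (50 px native, 20 px down-sampled, 26 px world, 32 hidden units, 400
steps) trains in seconds and preserves all qualitative results.

Analysis mirrors the neural pipeline: the 24 reference trajectories are
mapped onto a hexagon inscribed in the world frame
(`reference_trajectories_world()`), hidden activity is collected per frame
(`network_trajectory_activity()`), and `decode_hidden()` reports per-frame
cross-validated linear decodability of start, movement vector and target
from the top principal components. In ego-input networks the movement
vector is decodable as well as or before the target; allo-output networks
reverse the order.

**RSA** compares systems on the shared 24-condition set: condition-averaged
activity is reduced to 4 principal components, the representational
dissimilarity matrix is \(1 - r\) between condition score vectors, and the
similarity of two systems is the Pearson correlation of their RDMs' lower
triangles (`rsa_similarity()`, `rsa_matrix()`). Neural windows pre-cue /
post-cue / go are matched to network frames 3 / 7 / 11 (before target
onset / after target onset / at output). Because distractor pixels are
visible on every frame, they add render-to-render variance to the
condition-mean hidden states the RDMs are built from; representational
comparisons therefore use distractor-free probe renders
(`network_trajectory_activity(..., probe_distractors = 0)`) while
training always sees the full task. A direction-coding population is
most similar to the ego-ego network at the post-cue and go stages.

`detect_gain_field_units()` probes a trained network on a factorial grid of
start positions × directions and fits the gain-field and additive models
(Gaussian likelihood, cross-validated) to each hidden unit, flagging units
whose start modulation is better described as multiplicative.

## 8. Numerical conventions

* p values from permutation/bootstrap tests are raw exceedance fractions;
  the \(1/n\) floor is reported separately (`p_floor`) rather than baked
  in.
* Correlations are clipped into the open interval (−1, 1) before `atanh`.
* CV R² is never clamped; negative values are meaningful evidence of
  overfitting.
* All stochastic steps take explicit integer seeds; population generators
  derive per-neuron seeds (`seed + i`, or `seed + 7919 j` for resampling)
  so neurons are independent yet individually reproducible.

## 9. Scaling defaults

Full-scale defaults follow the source analyses (5,000 selectivity
permutations, 10⁵ comparison bootstraps, 20 CV folds, 100
pseudopopulations, 100 hidden units). The package's tests and acceptance
runs use documented reductions (1,000 permutations, 2,000 bootstraps, 10
folds, 5–20 pseudopopulations, the reduced network above) chosen to keep a
full run within minutes on one CPU while leaving every comparison's
direction and significance unchanged.
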