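# reachclust

Clustering-based analysis of exploration and exploitation in reward-based
motor learning.

## The problem

In reward-based reaching tasks, people learn from binary success/failure
feedback alone: they must *explore* new movement patterns to find a hidden
target zone and *exploit* a pattern once it pays off. Classifying each trial
as exploration or exploitation directly from kinematics — rather than from
reward history — is the analysis this package implements:

1. Every trial's 2-D hand trajectory is time-normalized to 30 points per
   axis and concatenated into a 60-element feature vector; trials from all
   participants and conditions are pooled into one `trials × 60` matrix.
2. The pooled matrix is clustered with a **Gaussian mixture model** fitted
   by multi-restart EM. The mixture with `K` components has density
   `f(x) = Σₖ πₖ N(x | μₖ, Σₖ)`, and each trial gets the label of its
   maximum-posterior component.
3. `K` is chosen by the **Bayesian information criterion**, oriented so that
   higher is better (`BIC = 2ℓ − ν·log n`), taking the first `K` at which
   the BIC curve reaches a plateau (marginal gain below 5% of the BIC range
   over the grid).
4. A transition between consecutive trials is **exploitation** when the
   cluster repeats and **exploration** when it changes. The
   **exploration–exploitation ratio** `EER = #explorations / #exploitations`
   summarizes a session (1.0 = balance); transition matrices,
   visited-cluster counts, cumulative curves, reward-conditioned
   probabilities and trial-to-trial direction changes (Δm) complete the
   picture.
5. The whole chain is validated on simulated data with known structure: a
   four-group functional dataset (piecewise logistic + linear curves with
   group-wise Gaussian parameters), four hypothetical sampling behaviors,
   and a bootstrap that scores cluster agreement (Adjusted Rand Index and
   matched-assignment %) and compares true vs. estimated EER.

Because no human reaching data are bundled, the package also ships a
synthetic reaching-task generator (`simulate_session()`): minimum-jerk
reaches at 400 Hz toward a 15 cm target stripe, a hidden reward zone with
Fixed (1.00 cm) or large-to-small width schedules, and a Markov
mode-switching policy whose switch probabilities depend on reward. User
data in the documented tidy CSV layout drop into the same pipeline via
`read_trajectories()`.

## Worked example

```r
library(reachclust)

## 1. Simulated-curve validation: four hypothetical behaviors
dataset <- simulate_curves(seed = 1)              # 4 groups x 1500 curves
rules   <- sampling_rules()                       # the four sampling cases
cases <- purrr::pmap(rules, function(case, clusters, probs, K, length) {
  run_case_validation(dataset, probs, clusters, B = 50, length = length,
                      case_id = case, seed = 100 + case)
})
summarize_validation(cases)
#>    case     K mean_agreement_pct mean_true_eer mean_est_eer mean_diff
#> 1     1     4               99.2         3.11         3.08    -0.0290
#> 2     2     4               97.5         0.926        1.01     0.0884
#> 3     3     2              100           0.488        0.488    0
#> 4     4     2              100           0.994        0.994    0

## 2. Model selection on the full dataset
grid <- fit_gmm_grid(curve_matrix(dataset), K_grid = 2:8, seed = 2)
select_K(grid)
#> [1] 4
```

The emergent clusters reproduce the known groups in 97–100% of trials, the
estimated ratios track the ground truth, and the BIC plateau lands on the
four generating groups. The same stages run on a synthetic session:

```r
policy  <- reach_policy(mode_angles_deg = c(-5, 0, 5),
                        motor_noise_sd_deg = 0.3, curvature_sd_deg = 0.5)
session <- simulate_session(policy, make_schedule("Fixed"), seed = 42)
tm  <- build_trial_matrix(session)
fit <- order_clusters(fit_gmm(trial_features(tm), K = 3, seed = 3))
labelled <- assign_clusters(tm, fit)
eer(labelled$cluster)
#>   scope   block n_explore n_exploit   eer
#> 1 session    NA        80       119 0.672
adjusted_rand_index(session$mode, labelled$cluster)
#> [1] 1
reward_conditioned_measures(labelled$cluster, labelled$reward)
#>   measure                 value     n
#> 1 p_exploit_given_reward  0.609    69
#> 2 p_exploit_given_fail    0.592   130
#> ...
```

Here the three generating movement modes are recovered perfectly (ARI = 1),
the session-level EER of 0.672 says exploitation dominated, and repeating a
cluster is slightly more likely after a rewarded trial than after a failure
— the signature the reward-conditioned measures are designed to expose.

`autoplot()` methods draw the BIC/AIC selection curve and the cluster
transition diagram; `plot_cumulative_curves()` and `plot_validation_diff()`
cover the cumulative exploration/exploitation totals and the bootstrap
mismatch distribution.

## Package layout

| Module | Contents |
| --- | --- |
| `R/simdata.R` | group specs, piecewise curve generator, labelled datasets, sampling rules |
| `R/reachsim.R` | target schedules, reach policies, minimum-jerk trial/session simulator |
| `R/prep.R` | time normalization, trial vectorization, pooled trial matrix, PD measures |
| `R/cluster.R`, `R/fisher-em.R` | mixture EM (diagonal / pooled / full, optional Fisher subspace), BIC/AIC, plateau selection, cluster ordering |
| `R/explore.R` | transitions, EER, transition matrices, reward-conditioned measures, Δm, sensitivity analysis |
| `R/validate.R` | ARI, matched-assignment %, bootstrap case validation, summary report |
| `R/pipeline.R` | stage runners that write TSV/CSV outputs + JSON manifests |

See the methods vignette (`vignettes/reachclust-methods.Rmd`) for the model
details, parameter choices, and known limitations.
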