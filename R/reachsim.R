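# Synthetic reward-based reaching task.
#
# Workspace convention: start circle at the origin, straight-ahead along +y,
# ideal reach direction 45 degrees to the left (135 degrees in standard x/y
# coordinates), target stripe at 15 cm.  The lateral (stripe) axis points to
# the right of the reach line, so leftward deviations are negative.

TARGET_ANGLE_DEG <- 135
REACH_AMPLITUDE_CM <- 15

# signed lateral coordinate (cm) of workspace points: projection onto the
# stripe direction, positive to the right of the ideal reach line
lateral_coordinate <- function(x, y, target_angle_deg = TARGET_ANGLE_DEG) {
  lat_deg <- (target_angle_deg - 90) * pi / 180
  x * cos(lat_deg) + y * sin(lat_deg)
}

# minimum-jerk position fraction on normalized time tau in [0, 1]
minjerk_fraction <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Build a per-block target-zone width schedule
#'
#' In the Fixed condition the hidden target zone keeps a constant width
#' (1.00 cm by default) across all training blocks.  In the large-to-small
#' (`"LS"`) condition the width narrows over blocks: block 1 covers the
#' central 50% interquantile span of the baseline endpoint deviations (so
#' about half the baseline movements would be rewarded), block 2 is halfway
#' between the first and the final width, and the remaining blocks use the
#' final width (0.80 cm by default).
#'
#' @param condition `"Fixed"` or `"LS"`.
#' @param baseline_pd Numeric vector of baseline endpoint perpendicular
#'   deviations (cm); required for `"LS"`.
#' @param final_width_cm Final (narrowest) width for `"LS"` (default 0.80).
#' @param fixed_width_cm Width for the Fixed condition (default 1.00).
#' @param blocks,trials_per_block Training-block layout (defaults 4 x 50).
#' @param center_offset_cm Lateral position of the zone center relative to
#'   the ideal reach line (default 0).
#' @param min_width_cm Floor applied to a degenerate block-1 width when the
#'   baseline sample has no spread (default 0.1, with a warning).
#' @return A tibble with columns `block`, `width_cm` and attributes
#'   `condition`, `center_offset_cm`, `trials_per_block`.
#' @export
#' @examples
#' make_schedule("Fixed")
#' make_schedule("LS", baseline_pd = rnorm(50, 0, 0.89))
make_schedule <- function(condition = c("Fixed", "LS"), baseline_pd = NULL,
                          final_width_cm = 0.8, fixed_width_cm = 1.0,
                          blocks = 4, trials_per_block = 50,
                          center_offset_cm = 0, min_width_cm = 0.1) {
  condition <- match.arg(condition)
  if (condition == "Fixed") {
    widths <- rep(fixed_width_cm, blocks)
  } else {
    if (is.null(baseline_pd) || length(baseline_pd) == 0) {
      abort("`baseline_pd` must be a non-empty numeric vector for the LS condition")
    }
    w1 <- unname(diff(quantile(baseline_pd, c(0.25, 0.75))))
    if (w1 <= 0) {
      warn(sprintf(
        "baseline deviations have no spread; flooring block-1 width at %.2f cm",
        min_width_cm
      ))
      w1 <- min_width_cm
    }
    w2 <- (w1 + final_width_cm) / 2
    widths <- c(w1, w2, rep(final_width_cm, max(0, blocks - 2)))[seq_len(blocks)]
  }
  out <- tibble::tibble(block = seq_len(blocks), width_cm = widths)
  attr(out, "condition") <- condition
  attr(out, "center_offset_cm") <- center_offset_cm
  attr(out, "trials_per_block") <- as.integer(trials_per_block)
  out
}

#' Define a discrete-mode reaching policy
#'
#' The simulated participant keeps a repertoire of discrete reach-direction
#' modes (angular deviations from the ideal reach line).  After each trial
#' the mode is kept or switched with a probability that depends on the
#' reward outcome; a switch moves to one of the other modes uniformly at
#' random.  Within a trial the executed direction is the mode angle plus
#' Gaussian motor noise, and a smooth mid-movement curvature perturbation
#' (vanishing at both endpoints) bends the path.
#'
#' The defaults mirror the scale of human reward-based reaching: mode
#' spacing of 2 degrees gives endpoint deviations roughly 0.5 cm apart at a
#' 15 cm amplitude, the stationary endpoint spread is close to the 0.89 cm
#' baseline standard deviation observed in such experiments, and the switch
#' probabilities reproduce exploitation rates of about 63% after reward and
#' 58% after failure.
#'
#' @param mode_angles_deg Distinct mode angles in degrees (deviation from
#'   the ideal reach line; positive = rightward).
#' @param motor_noise_sd_deg Within-mode angular noise SD (degrees).
#' @param curvature_sd_deg SD of the smooth mid-movement angular
#'   perturbation (degrees); 0 gives straight reaches.
#' @param p_switch_given_reward,p_switch_given_fail Probability of changing
#'   mode on the next trial after a rewarded / failed trial.
#' @return An object of class `reach_policy`.
#' @export
reach_policy <- function(mode_angles_deg = seq(-6, 6, by = 2),
                         motor_noise_sd_deg = 0.5,
                         curvature_sd_deg = 2,
                         p_switch_given_reward = 0.37,
                         p_switch_given_fail = 0.42) {
  if (length(mode_angles_deg) < 1) abort("at least one mode angle is required")
  for (p in c(p_switch_given_reward, p_switch_given_fail)) {
    if (p < 0 || p > 1) abort("switch probabilities must lie in [0, 1]")
  }
  if (motor_noise_sd_deg < 0 || curvature_sd_deg < 0) {
    abort("noise standard deviations must be >= 0")
  }
  structure(
    list(
      mode_angles_deg = mode_angles_deg,
      motor_noise_sd_deg = motor_noise_sd_deg,
      curvature_sd_deg = curvature_sd_deg,
      p_switch_given_reward = p_switch_given_reward,
      p_switch_given_fail = p_switch_given_fail
    ),
    class = "reach_policy"
  )
}

#' Simulate a single reaching trial
#'
#' The hand follows a minimum-jerk radial speed profile to the 15 cm target
#' stripe along the current mode direction (plus motor noise), with a smooth
#' angular perturbation that bends the path mid-flight but leaves the
#' endpoint untouched.  Movement duration is drawn uniformly from 500-700 ms
#' and positions are sampled at 400 Hz.  The trial is rewarded iff the
#' endpoint perpendicular deviation falls within the target zone, i.e.
#' `|pd_end - center_offset| <= width / 2` (closed interval); reward does not
#' depend on speed or distance.
#'
#' @param policy A [reach_policy()].
#' @param mode Index of the current mode in `policy$mode_angles_deg`.
#' @param width_cm Target-zone width (cm).
#' @param center_offset_cm Lateral target-zone center (cm, default 0).
#' @param hz Sampling rate (default 400).
#' @return A one-row tibble with columns `mode`, `angle_deg`, `duration_ms`,
#'   `pd_end`, `pd_mid`, `reward` and a list-column `samples` holding a
#'   tibble of `t_ms`, `x_cm`, `y_cm` from movement onset.
#' @export
simulate_trial <- function(policy, mode, width_cm, center_offset_cm = 0,
                           hz = 400) {
  stopifnot(inherits(policy, "reach_policy"))
  angle <- policy$mode_angles_deg[mode] + rnorm(1, 0, policy$motor_noise_sd_deg)
  kappa <- rnorm(1, 0, policy$curvature_sd_deg)
  # duration snapped to the sampling frame so the recording ends exactly at
  # movement offset
  dt <- 1000 / hz
  duration_ms <- dt * round(runif(1, 500, 700) / dt)
  t_ms <- seq(0, duration_ms, by = dt)
  tau <- t_ms / duration_ms
  s <- minjerk_fraction(tau)
  # direction in workspace coordinates: positive `angle` deviates rightward
  phi <- (TARGET_ANGLE_DEG - angle - kappa * sin(pi * s)) * pi / 180
  r <- REACH_AMPLITUDE_CM * s
  samples <- tibble::tibble(t_ms = t_ms, x_cm = r * cos(phi), y_cm = r * sin(phi))
  km <- kinematic_measures(samples, center_offset_cm = center_offset_cm)
  reward <- abs(km$pd_end) <= width_cm / 2
  tibble::tibble(
    mode = mode,
    angle_deg = angle,
    duration_ms = duration_ms,
    pd_end = km$pd_end,
    pd_mid = km$pd_mid,
    reward = reward,
    samples = list(samples)
  )
}

#' Simulate a full training session of the reaching task
#'
#' Runs the Markov mode-switching policy through all blocks of a schedule:
#' the first mode is drawn uniformly, and after each trial the mode is
#' re-drawn (uniformly among the other modes) with probability
#' `p_switch_given_reward` or `p_switch_given_fail` depending on the trial's
#' outcome.
#'
#' @param policy A [reach_policy()].
#' @param schedule A schedule from [make_schedule()].
#' @param participant Participant identifier (default `"P01"`).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per trial: `participant`, `condition`,
#'   `block`, `trial`, `mode`, `angle_deg`, `duration_ms`, `pd_end`,
#'   `pd_mid`, `reward`, and the nested `samples` list-column.
#' @export
#' @examples
#' s <- simulate_session(reach_policy(), make_schedule("Fixed"), seed = 1)
#' nrow(s)  # blocks x trials_per_block
simulate_session <- function(policy, schedule, participant = "P01",
                             seed = NULL) {
  stopifnot(inherits(policy, "reach_policy"))
  if (!is.null(seed)) withr::local_seed(seed)
  condition <- attr(schedule, "condition") %||% "Fixed"
  offset <- attr(schedule, "center_offset_cm") %||% 0
  tpb <- attr(schedule, "trials_per_block") %||% 50L
  n_modes <- length(policy$mode_angles_deg)
  mode <- sample.int(n_modes, 1L)
  out <- vector("list", nrow(schedule) * tpb)
  i <- 0L
  for (b in seq_len(nrow(schedule))) {
    for (tr in seq_len(tpb)) {
      i <- i + 1L
      rec <- simulate_trial(policy, mode, schedule$width_cm[b], offset)
      out[[i]] <- dplyr::bind_cols(
        tibble::tibble(
          participant = participant, condition = condition,
          block = schedule$block[b], trial = i
        ),
        rec
      )
      p_switch <- if (rec$reward) policy$p_switch_given_reward else policy$p_switch_given_fail
      if (n_modes > 1L && runif(1) < p_switch) {
        others <- setdiff(seq_len(n_modes), mode)
        mode <- others[sample.int(length(others), 1L)]
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Unnest the trajectory samples of one or more sessions
#'
#' @param trials Session tibble from [simulate_session()].
#' @return A tidy tibble with one row per sample: `participant`, `condition`,
#'   `block`, `trial`, `t_ms`, `x_cm`, `y_cm`.
#' @export
session_samples <- function(trials) {
  trials |>
    dplyr::select(dplyr::any_of(c("participant", "condition", "block", "trial")),
                  "samples") |>
    tidyr::unnest("samples")
}

#' Write a session to tidy CSV files
#'
#' Writes the trajectory samples (`<stem>_samples.csv`: participant,
#' condition, block, trial, t_ms, x_cm, y_cm) and the per-trial table
#' (`<stem>_trials.csv`: pd_end, pd_mid, reward and identifiers).
#'
#' @param trials Session tibble from [simulate_session()].
#' @param stem File-path stem (no extension).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(trials, stem) {
  p1 <- paste0(stem, "_samples.csv")
  p2 <- paste0(stem, "_trials.csv")
  readr::write_csv(session_samples(trials), p1)
  readr::write_csv(dplyr::select(trials, -"samples"), p2)
  invisible(c(samples = p1, trials = p2))
}

#' Read trajectory samples written by [write_session()] (or user data in the
#' same layout) back into a nested session tibble
#'
#' @param path CSV of samples with columns `participant`, `condition`,
#'   `block`, `trial`, `t_ms`, `x_cm`, `y_cm`.
#' @return A tibble with one row per trial and a `samples` list-column.
#' @export
read_trajectories <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    tidyr::nest(samples = c("t_ms", "x_cm", "y_cm"))
}
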