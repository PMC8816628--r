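# Conversion of trial trajectories to fixed-length feature vectors.

#' Time-normalize a sampled signal to a fixed number of points
#'
#' Linearly interpolates the signal at `n_points` equally spaced fractions of
#' the movement duration, endpoints included.  Already-uniform data of length
#' `n_points` pass through unchanged (idempotence).
#'
#' @param t Sample times (any monotone increasing unit).
#' @param x Sampled values, same length as `t`.
#' @param n_points Number of output points (default 30).
#' @return Numeric vector of length `n_points`.
#' @export
#' @examples
#' time_normalize(0:9, seq(0, 1, length.out = 10), n_points = 30)
time_normalize <- function(t, x, n_points = 30) {
  if (length(t) < 2 || length(x) < 2) {
    abort("at least 2 samples are required for time normalization")
  }
  if (length(t) != length(x)) abort("`t` and `x` must have the same length")
  approx(t, x, xout = seq(t[1], t[length(t)], length.out = n_points))$y
}

#' Vectorize one trial into a 2 x n_points feature row
#'
#' Time-normalizes the X and Y positions separately and concatenates them
#' (X first, then Y) into a single feature vector, the row format consumed
#' by the mixture model.
#'
#' @param samples Tibble with columns `t_ms`, `x_cm`, `y_cm` (onset-aligned).
#' @param n_points Points per axis (default 30, giving 60 features).
#' @return Named numeric vector `x01..x30, y01..y30`.
#' @export
vectorize_trial <- function(samples, n_points = 30) {
  v <- c(
    time_normalize(samples$t_ms, samples$x_cm, n_points),
    time_normalize(samples$t_ms, samples$y_cm, n_points)
  )
  names(v) <- c(
    sprintf("x%02d", seq_len(n_points)),
    sprintf("y%02d", seq_len(n_points))
  )
  v
}

#' Pool sessions into the trials x features matrix used for clustering
#'
#' Vectorizes every trial of every session and stacks them, preserving the
#' (participant, block, trial) row order and pooling all participants and
#' conditions into one matrix, with the metadata carried along by row.
#'
#' @param sessions A session tibble (or `bind_rows()` of several) from
#'   [simulate_session()] / [read_trajectories()], with a `samples`
#'   list-column.
#' @param n_points Points per axis (default 30).
#' @return A tibble: metadata columns (`participant`, `condition`, `block`,
#'   `trial`, and `reward` if present) followed by the feature columns
#'   `x01..y30`.  Use [trial_features()] to extract the numeric matrix.
#' @export
build_trial_matrix <- function(sessions, n_points = 30) {
  if (!"samples" %in% names(sessions)) abort("`sessions` must have a `samples` list-column")
  feats <- purrr::map(sessions$samples, vectorize_trial, n_points = n_points)
  F <- do.call(rbind, feats)
  meta <- dplyr::select(
    sessions,
    dplyr::any_of(c("participant", "condition", "block", "trial", "reward"))
  )
  dplyr::bind_cols(meta, tibble::as_tibble(F))
}

#' Extract the numeric feature matrix from a trial matrix tibble
#'
#' @param trial_matrix Tibble from [build_trial_matrix()].
#' @return Numeric matrix (trials x features).
#' @export
trial_features <- function(trial_matrix) {
  as.matrix(trial_matrix[, grep("^[xy][0-9]+$", names(trial_matrix)),
                         drop = FALSE])
}

#' Endpoint and mid-flight perpendicular deviation of a trial
#'
#' The perpendicular deviation (PD) is the signed lateral distance of the
#' hand from the target-zone center, measured along the stripe direction
#' (positive to the right of the ideal reach line).  `pd_end` is the PD of
#' the movement endpoint; `pd_mid` is the mean PD over the middle third of
#' the time-normalized movement (points 11-20 of 30 by default).
#'
#' @param samples Tibble with `t_ms`, `x_cm`, `y_cm` from movement onset.
#' @param center_offset_cm Lateral position of the target-zone center
#'   (default 0).
#' @param n_points Time-normalization length (default 30).
#' @param mid_points Indices forming the "middle third" (default `11:20`).
#' @param target_angle_deg Ideal reach direction (default 135, i.e. 45
#'   degrees to the left of straight ahead).
#' @return A one-row tibble with `pd_end`, `pd_mid` (cm).
#' @export
kinematic_measures <- function(samples, center_offset_cm = 0, n_points = 30,
                               mid_points = 11:20,
                               target_angle_deg = TARGET_ANGLE_DEG) {
  xn <- time_normalize(samples$t_ms, samples$x_cm, n_points)
  yn <- time_normalize(samples$t_ms, samples$y_cm, n_points)
  lat <- lateral_coordinate(xn, yn, target_angle_deg) - center_offset_cm
  tibble::tibble(pd_end = lat[n_points], pd_mid = mean(lat[mid_points]))
}

#' Write / read a trial matrix with its metadata sidecar
#'
#' The features go to `<stem>_features.csv` (60 columns) and the row-aligned
#' metadata to `<stem>_metadata.csv`.
#'
#' @param trial_matrix Tibble from [build_trial_matrix()].
#' @param stem File-path stem.
#' @return Invisibly, the paths written.
#' @export
write_trial_matrix <- function(trial_matrix, stem) {
  fcols <- grep("^[xy][0-9]+$", names(trial_matrix), value = TRUE)
  p1 <- paste0(stem, "_features.csv")
  p2 <- paste0(stem, "_metadata.csv")
  readr::write_csv(trial_matrix[, fcols], p1)
  readr::write_csv(trial_matrix[, setdiff(names(trial_matrix), fcols)], p2)
  invisible(c(features = p1, metadata = p2))
}
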