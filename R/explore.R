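# Exploration vs. exploitation from per-trial cluster label sequences.
#
# A transition from trial n-1 to trial n is "exploitation" when both trials
# belong to the same movement cluster and "exploration" when the cluster
# changes.  The exploration-exploitation ratio (EER) is the total number of
# explorations divided by the number of exploitations; 1.0 marks a balance
# between the two modes.

#' Classify trial-to-trial transitions as exploration or exploitation
#'
#' @param labels Integer vector of per-trial cluster labels.
#' @return A tibble with one row per consecutive pair: `trial` (the later
#'   trial), `from`, `to`, and `explore` (`TRUE` iff the labels differ).
#'   Sequences shorter than 2 return an empty tibble with a warning.
#' @export
#' @examples
#' classify_transitions(c(2, 2, 2, 3))$explore  # FALSE FALSE TRUE
classify_transitions <- function(labels) {
  n <- length(labels)
  if (n < 2) {
    warn("fewer than 2 trials: no transitions to classify")
    return(tibble::tibble(trial = integer(), from = integer(),
                          to = integer(), explore = logical()))
  }
  from <- labels[-n]
  to <- labels[-1]
  tibble::tibble(trial = 2:n, from = from, to = to, explore = from != to)
}

#' Exploration-exploitation ratio of a label sequence
#'
#' Counts exploration and exploitation transitions and reports their ratio.
#' With `scope = "session"` every consecutive pair counts, including pairs
#' spanning block boundaries; with `scope = "block"` only within-block
#' transitions are evaluated, one result row per block.  When a scope
#' contains no exploitation at all the ratio is reported as `Inf` (a
#' strictly alternating sequence is representable); aggregation code should
#' drop these sentinels and report how many were dropped.
#'
#' @param labels Integer vector of per-trial cluster labels.
#' @param blocks Optional per-trial block ids (required for
#'   `scope = "block"`).
#' @param scope `"session"` (default) or `"block"`.
#' @return A tibble with columns `scope`, `block` (`NA` for session scope),
#'   `n_explore`, `n_exploit`, `eer`.
#' @export
#' @examples
#' eer(c(1, 2, 3, 2, 1, 3, 2, 3, 1, 2, 3))  # exploration-heavy: eer > 1
eer <- function(labels, blocks = NULL, scope = c("session", "block")) {
  scope <- match.arg(scope)
  one <- function(lab, block_id) {
    tr <- if (length(lab) < 2) {
      tibble::tibble(explore = logical())
    } else {
      suppressWarnings(classify_transitions(lab))
    }
    n_explore <- sum(tr$explore)
    n_exploit <- sum(!tr$explore)
    tibble::tibble(
      scope = scope, block = block_id,
      n_explore = n_explore, n_exploit = n_exploit,
      eer = if (n_exploit > 0) n_explore / n_exploit else Inf
    )
  }
  if (scope == "session") {
    if (length(labels) < 2) abort("at least 2 trials are required")
    return(one(labels, NA_integer_))
  }
  if (is.null(blocks)) abort("`blocks` is required for per-block scope")
  if (length(blocks) != length(labels)) {
    abort("`labels` and `blocks` must have the same length")
  }
  purrr::map_dfr(split(seq_along(labels), blocks), function(idx) {
    one(labels[idx], blocks[idx[1]])
  })
}

#' Cumulative exploration and exploitation counts over trials
#'
#' Running totals of the two transition types, as plotted per participant to
#' show how one behavioral mode overtakes the other during learning.
#'
#' @param labels Integer vector of per-trial cluster labels.
#' @return A tibble with `trial`, `n_explore_cum`, `n_exploit_cum`; the last
#'   row reproduces the session EER counts.
#' @export
cumulative_curves <- function(labels) {
  tr <- classify_transitions(labels)
  tibble::tibble(
    trial = tr$trial,
    n_explore_cum = cumsum(tr$explore),
    n_exploit_cum = cumsum(!tr$explore)
  )
}

#' Cluster transition counts between consecutive trials
#'
#' `transition_matrix()` returns the K x K count matrix (rows = cluster at
#' trial n, columns = cluster at trial n + 1; the diagonal sum equals the
#' number of exploitations).  `transition_counts()` returns the same tallies
#' in long format.
#'
#' @param labels Integer vector of per-trial cluster labels.
#' @param K Number of clusters (default `max(labels)`).
#' @return A K x K integer matrix of class `transition_matrix`, or a tibble
#'   `from`, `to`, `count`.
#' @export
transition_matrix <- function(labels, K = max(labels)) {
  tr <- classify_transitions(labels)
  M <- matrix(0L, K, K, dimnames = list(from = 1:K, to = 1:K))
  for (i in seq_len(nrow(tr))) {
    M[tr$from[i], tr$to[i]] <- M[tr$from[i], tr$to[i]] + 1L
  }
  structure(M, class = c("transition_matrix", "matrix"))
}

#' @rdname transition_matrix
#' @export
transition_counts <- function(labels, K = max(labels)) {
  M <- transition_matrix(labels, K)
  tibble::as_tibble(as.data.frame.table(unclass(M), stringsAsFactors = FALSE),
                    .name_repair = "minimal") |>
    setNames(c("from", "to", "count")) |>
    dplyr::mutate(from = as.integer(.data$from), to = as.integer(.data$to))
}

#' Number of distinct clusters visited at least once
#'
#' @param labels Integer vector of per-trial cluster labels.
#' @return Integer count.
#' @export
visited_clusters <- function(labels) {
  length(unique(labels))
}

#' Reward-conditioned exploitation measures
#'
#' Partitions all transitions by the reward outcome of the *preceding* trial
#' and reports: the probability of exploiting given reward / given failure,
#' the probability that a rewarded movement is repeated and rewarded again
#' (the empirical exploitation measure), and the mean absolute cluster shift
#' (ordinal distance on left-to-right ordered labels) after reward and after
#' failure.  An empty conditioning set yields `NA` with `n = 0`.
#'
#' @param labels Integer per-trial cluster labels (ideally ordered left to
#'   right via [order_clusters()], so the shift magnitude is meaningful).
#' @param rewards Logical per-trial reward outcomes.
#' @return A tibble with columns `measure`, `value`, `n` (conditioning-set
#'   size).  Measures: `p_exploit_given_reward`, `p_exploit_given_fail`,
#'   `p_reward_given_reward`, `mean_shift_after_reward`,
#'   `mean_shift_after_fail`.
#' @export
reward_conditioned_measures <- function(labels, rewards) {
  if (length(labels) != length(rewards)) {
    abort("`labels` and `rewards` must have the same length")
  }
  if (length(labels) < 2) abort("at least 2 trials are required")
  n <- length(labels)
  prev_reward <- rewards[-n]
  exploit <- labels[-1] == labels[-n]
  shift <- abs(labels[-1] - labels[-n])
  next_reward <- rewards[-1]
  cond <- function(x, keep) {
    if (sum(keep) == 0) {
      tibble::tibble(value = NA_real_, n = 0L)
    } else {
      tibble::tibble(value = mean(x[keep]), n = sum(keep))
    }
  }
  dplyr::bind_rows(
    dplyr::mutate(cond(exploit, prev_reward), measure = "p_exploit_given_reward"),
    dplyr::mutate(cond(exploit, !prev_reward), measure = "p_exploit_given_fail"),
    dplyr::mutate(cond(next_reward, prev_reward), measure = "p_reward_given_reward"),
    dplyr::mutate(cond(shift, prev_reward), measure = "mean_shift_after_reward"),
    dplyr::mutate(cond(shift, !prev_reward), measure = "mean_shift_after_fail")
  )[, c("measure", "value", "n")]
}

#' Trial-to-trial change in movement direction conditioned on prior outcome
#'
#' Computes the per-transition differences of the endpoint and mid-flight
#' perpendicular deviations together with the reward outcome of the
#' preceding trial; `summarize_delta_m()` aggregates the mean absolute
#' change per partition, the conventional measure in which exploration shows
#' up as larger direction changes after failure.
#'
#' @param trials Tibble with per-trial columns `pd_end`, `pd_mid`, `reward`
#'   in trial order (e.g. from [simulate_session()]).
#' @return `delta_m()`: a tibble with `trial`, `d_pd_end`, `d_pd_mid`,
#'   `prev_reward`.  `summarize_delta_m()`: one row per `prev_reward` value
#'   with `mean_abs_d_pd_end`, `mean_abs_d_pd_mid`, `n`.
#' @export
delta_m <- function(trials) {
  for (col in c("pd_end", "pd_mid", "reward")) {
    if (!col %in% names(trials)) abort(sprintf("`trials` must contain `%s`", col))
  }
  n <- nrow(trials)
  if (n < 2) abort("at least 2 trials are required")
  tibble::tibble(
    trial = 2:n,
    d_pd_end = diff(trials$pd_end),
    d_pd_mid = diff(trials$pd_mid),
    prev_reward = trials$reward[-n]
  )
}

#' @rdname delta_m
#' @param dm Output of `delta_m()`.
#' @export
summarize_delta_m <- function(dm) {
  dm |>
    dplyr::group_by(.data$prev_reward) |>
    dplyr::summarise(
      mean_abs_d_pd_end = mean(abs(.data$d_pd_end)),
      mean_abs_d_pd_mid = mean(abs(.data$d_pd_mid)),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Sensitivity of the exploration metrics to the number of clusters
#'
#' Refits the mixture at each K in `K_range` (cold starts), orders clusters
#' left to right, assigns labels, and recomputes per-session summaries:
#' clusters visited, session EER, and (when rewards are present) the
#' correlation across sessions between early-learning EER and late-learning
#' reward count.
#'
#' @param trial_matrix Tibble from [build_trial_matrix()] with metadata
#'   columns `participant`, `condition`, `block` (and optionally `reward`).
#' @param K_range Integer vector of cluster counts to evaluate.
#' @param early_blocks,late_blocks Blocks defining "early" EER and "late"
#'   reward (defaults `1:2` and `3:4`).
#' @param ... Passed to [fit_gmm()].
#' @return A tibble keyed by `K`, `participant`, `condition` with
#'   `visited`, `eer`, `n_explore`, `n_exploit`, plus per-K columns
#'   `cor_early_eer_late_reward` (NA without rewards).
#' @export
sensitivity_analysis <- function(trial_matrix, K_range,
                                 early_blocks = 1:2, late_blocks = 3:4, ...) {
  X <- trial_features(trial_matrix)
  purrr::map_dfr(K_range, function(K) {
    fit <- order_clusters(fit_gmm(X, K, ...))
    tm <- assign_clusters(trial_matrix, fit)
    per_session <- tm |>
      dplyr::group_by(.data$participant, .data$condition) |>
      dplyr::reframe(
        visited = visited_clusters(.data$cluster),
        eer(.data$cluster)[, c("n_explore", "n_exploit", "eer")]
      )
    if ("reward" %in% names(tm)) {
      early <- tm |>
        dplyr::filter(.data$block %in% early_blocks) |>
        dplyr::group_by(.data$participant) |>
        dplyr::reframe(early_eer = eer(.data$cluster)$eer)
      late <- tm |>
        dplyr::filter(.data$block %in% late_blocks) |>
        dplyr::group_by(.data$participant) |>
        dplyr::summarise(late_reward = sum(.data$reward), .groups = "drop")
      j <- dplyr::inner_join(early, late, by = "participant")
      j <- j[is.finite(j$early_eer), ]
      r <- if (nrow(j) >= 3 && sd(j$early_eer) > 0 && sd(j$late_reward) > 0) {
        cor(j$early_eer, j$late_reward)
      } else {
        NA_real_
      }
    } else {
      r <- NA_real_
    }
    dplyr::mutate(per_session, K = K, cor_early_eer_late_reward = r)
  })
}
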