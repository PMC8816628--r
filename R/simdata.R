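#' Default group parameter specification for the simulated functional dataset
#'
#' Returns the four-group specification used throughout the validation study.
#' Each observation from group \eqn{k} is a 120-point curve: a logistic
#' segment \eqn{a_k / (1 + \exp(-(t - b_k)/c_k))} over time indices 1..60
#' concatenated with a linear segment \eqn{m_k t} over 61..120.  The four
#' parameters of every observation are drawn from group-specific Gaussian
#' distributions whose means and standard deviations this table holds.
#'
#' The upper (positive-amplitude) and lower (negative-amplitude) groups
#' overlap deliberately in the linear segment, so that cluster recovery is a
#' non-trivial test of the mixture model.
#'
#' @return A tibble with one row per group and columns `group`, `a_mean`,
#'   `a_sd`, `b_mean`, `b_sd`, `c_mean`, `c_sd`, `m_mean`, `m_sd`.
#' @export
#' @examples
#' curve_groups()
curve_groups <- function() {
  tibble::tibble(
    group  = 1:4,
    a_mean = c(-10, 10, -10, 10),
    a_sd   = c(2, 0.1, 0.1, 0.1),
    b_mean = c(30, 30, 35, 35),
    b_sd   = c(3, 2, 2, 2),
    c_mean = c(8, 8, 6, 6),
    c_sd   = c(1, 2, 1, 1),
    m_mean = c(-0.1, 0.2, 0.1, -0.2),
    m_sd   = c(0.05, 0.03, 0.05, 0.03)
  )
}

validate_group_spec <- function(groups) {
  req <- c(
    "group", "a_mean", "a_sd", "b_mean", "b_sd", "c_mean", "c_sd",
    "m_mean", "m_sd"
  )
  missing <- setdiff(req, names(groups))
  if (length(missing) > 0) {
    abort(paste0("group spec is missing columns: ", paste(missing, collapse = ", ")))
  }
  sds <- as.matrix(groups[, c("a_sd", "b_sd", "c_sd", "m_sd")])
  if (any(sds < 0)) abort("all parameter standard deviations must be >= 0")
  if (any(groups$c_mean <= 0)) abort("`c_mean` must be > 0")
  invisible(groups)
}

#' Draw curve parameters from a group specification
#'
#' Each of the four curve parameters (`a`, `b`, `c`, `m`) is drawn
#' independently from its group's Gaussian distribution.
#'
#' @param groups Group specification tibble, as from [curve_groups()];
#'   may contain any subset of groups.
#' @param n Number of draws per group.
#' @return A tibble with columns `group`, `a`, `b`, `c`, `m`, ordered by
#'   group, `n` rows per group.
#' @export
#' @examples
#' sample_curve_params(curve_groups(), n = 2)
sample_curve_params <- function(groups, n = 1) {
  validate_group_spec(groups)
  purrr::pmap_dfr(groups, function(group, a_mean, a_sd, b_mean, b_sd,
                                    c_mean, c_sd, m_mean, m_sd, ...) {
    tibble::tibble(
      group = group,
      a = rnorm(n, a_mean, a_sd),
      b = rnorm(n, b_mean, b_sd),
      c = rnorm(n, c_mean, c_sd),
      m = rnorm(n, m_mean, m_sd)
    )
  })
}

#' Evaluate one piecewise logistic + linear curve
#'
#' Computes the noiseless curve value at integer time indices `1..t_total`:
#' the logistic segment \eqn{a / (1 + \exp(-(t - b)/c))} for
#' \eqn{t \le t_{split}} and the linear segment \eqn{m t} afterwards.  The two
#' segments are concatenated as-is; a value discontinuity at the split is
#' allowed (and typical).
#'
#' @param a,b,c,m Curve parameters: logistic amplitude, midpoint, slope scale,
#'   and linear slope.
#' @param t_total Total number of time points (default 120).
#' @param t_split Last time index of the logistic segment (default 60).
#' @return Numeric vector of length `t_total`.
#' @export
#' @examples
#' generate_curve(a = 10, b = 30, c = 8, m = 0.2)[30]  # a/2 = 5 at the midpoint
generate_curve <- function(a, b, c, m, t_total = 120, t_split = 60) {
  if (c == 0) abort("`c` must be non-zero (division by zero in the logistic segment)")
  if (t_split >= t_total) abort("`t_split` must be < `t_total`")
  t1 <- seq_len(t_split)
  t2 <- seq.int(t_split + 1L, t_total)
  c(a / (1 + exp(-(t1 - b) / c)), m * t2)
}

#' Generate a labelled simulated functional dataset
#'
#' Draws `n_per_group` observations from each group: parameters are sampled
#' from the group's Gaussians and the noiseless piecewise curve is evaluated
#' at `t_total` integer time points.  All within-group variation therefore
#' comes from parameter sampling.
#'
#' @param groups Group specification tibble (default [curve_groups()]).
#' @param n_per_group Observations per group (default 1500).
#' @param t_total,t_split Curve length and segment split (defaults 120 / 60).
#' @param seed Optional integer seed; when supplied the dataset is
#'   reproducible bit-for-bit.
#' @return A tibble with columns `obs_id`, `true_label` and `v1..v<t_total>`,
#'   one row per observation, grouped rows in group order.
#' @seealso [curve_matrix()] to extract the numeric observation matrix.
#' @export
#' @examples
#' d <- simulate_curves(n_per_group = 5, seed = 1)
#' dim(curve_matrix(d))
simulate_curves <- function(groups = curve_groups(), n_per_group = 1500,
                            t_total = 120, t_split = 60, seed = NULL) {
  validate_group_spec(groups)
  if (n_per_group < 1) abort("`n_per_group` must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  params <- sample_curve_params(groups, n = n_per_group)
  X <- t(mapply(generate_curve, params$a, params$b, params$c, params$m,
                MoreArgs = list(t_total = t_total, t_split = t_split)))
  colnames(X) <- paste0("v", seq_len(t_total))
  dplyr::bind_cols(
    tibble::tibble(obs_id = seq_len(nrow(X)), true_label = params$group),
    tibble::as_tibble(X)
  )
}

#' Extract the observation matrix from a simulated curve dataset
#'
#' @param dataset Tibble from [simulate_curves()].
#' @return Numeric matrix, observations in rows.
#' @export
curve_matrix <- function(dataset) {
  as.matrix(dataset[, grep("^v[0-9]+$", names(dataset)), drop = FALSE])
}

#' Sampling rules of the four hypothetical-participant validation cases
#'
#' Each case draws a 200-trial label sequence i.i.d. from a categorical
#' distribution over a subset of the simulated groups:
#' \describe{
#'   \item{case 1}{uniform over all four groups - high exploration}
#'   \item{case 2}{one group favoured at 70%, 10% each for the rest -
#'     moderate exploration}
#'   \item{case 3}{two groups at 80%/20% - low exploration}
#'   \item{case 4}{two groups at 50%/50% - balanced}
#' }
#' Which specific groups participate in the 2-cluster cases is not uniquely
#' determined by the study design; the default uses groups 2 and 3 (a pair
#' overlapping in the linear segment), and the favoured cluster of each
#' non-uniform case is the first of its cluster set.
#'
#' @param length Sequence length per case (default 200).
#' @param two_cluster_groups Groups used by cases 3-4 (default `c(2, 3)`).
#' @return A tibble with columns `case`, `clusters` (list), `probs` (list),
#'   `K`, `length`.
#' @export
#' @examples
#' sampling_rules()
sampling_rules <- function(length = 200, two_cluster_groups = c(2, 3)) {
  stopifnot(base::length(two_cluster_groups) == 2)
  tibble::tibble(
    case = 1:4,
    clusters = list(1:4, 1:4, two_cluster_groups, two_cluster_groups),
    probs = list(
      rep(0.25, 4),
      c(0.7, 0.1, 0.1, 0.1),
      c(0.8, 0.2),
      c(0.5, 0.5)
    ),
    K = c(4L, 4L, 2L, 2L),
    length = as.integer(length)
  )
}

#' Sample a hypothetical-participant label sequence from a dataset
#'
#' Draws an i.i.d. categorical label sequence and, per trial, a member
#' observation of that group sampled uniformly with replacement, so that a
#' 200-trial functional dataset with known ground-truth labels can be
#' assembled.
#'
#' @param dataset Simulated curve dataset from [simulate_curves()].
#' @param probs Sampling probabilities (must sum to 1).
#' @param clusters Group labels the probabilities refer to (default
#'   `seq_along(probs)`).
#' @param length Sequence length (default 200).
#' @return A tibble with columns `trial`, `label`, `obs_id`.
#' @export
#' @examples
#' d <- simulate_curves(n_per_group = 20, seed = 1)
#' sample_behavior_sequence(d, probs = rep(0.25, 4), length = 10)
sample_behavior_sequence <- function(dataset, probs,
                                     clusters = seq_along(probs),
                                     length = 200) {
  assert_prob_vector(probs)
  if (base::length(clusters) != base::length(probs)) {
    abort("`clusters` and `probs` must have the same length")
  }
  labels <- clusters[sample.int(base::length(clusters), length,
                                replace = TRUE, prob = probs)]
  idx_by_group <- split(dataset$obs_id, dataset$true_label)
  missing <- setdiff(as.character(clusters), names(idx_by_group))
  if (base::length(missing) > 0) {
    abort(paste0("dataset has no observations for group(s): ",
                 paste(missing, collapse = ", ")))
  }
  obs <- vapply(labels, function(l) {
    pool <- idx_by_group[[as.character(l)]]
    pool[sample.int(base::length(pool), 1L)]
  }, integer(1))
  tibble::tibble(trial = seq_len(length), label = labels, obs_id = obs)
}

#' Write / read a simulated curve dataset as TSV
#'
#' One row per observation with columns `obs_id`, `true_label`, `v1..vT`.
#'
#' @param dataset Tibble from [simulate_curves()].
#' @param path File path.
#' @return `write_curve_dataset()` returns `dataset` invisibly;
#'   `read_curve_dataset()` returns the tibble.
#' @export
write_curve_dataset <- function(dataset, path) {
  readr::write_tsv(dataset, path)
  invisible(dataset)
}

#' @rdname write_curve_dataset
#' @export
read_curve_dataset <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
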