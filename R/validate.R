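# Cluster-validation machinery: agreement indices and the four-case
# bootstrap study that rebuilds the Table-2-style report.

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie form): all pairs
#' of observations are examined and agreements/disagreements between the two
#' partitions tallied.  1.0 means identical partitions (up to label names);
#' values near 0 are expected for independent labelings.
#'
#' @param labels_a,labels_b Label vectors of equal length (>= 2); any atomic
#'   label type.
#' @return A number in \[-1, 1\]; permutation-invariant in both arguments.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("`labels_a` and `labels_b` must have the same length")
  }
  n <- length(labels_a)
  if (n < 2) abort("at least 2 observations are required")
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Percentage agreement under the best one-to-one label mapping
#'
#' Finds the one-to-one mapping between the two label sets that maximizes
#' the number of matching observations and reports the matched percentage -
#' the percentage-scaled counterpart of the agreement index (e.g. 8
#' mismatches out of 200 observations = 96%).  The assignment is solved
#' exactly by exhaustive permutation for up to `exact_max` labels and
#' greedily above that.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @param exact_max Largest label-set size solved exactly (default 8).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' raw_agreement(rep(1:2, each = 100), c(rep(2, 99), 1, rep(1, 100)))  # 99.5
raw_agreement <- function(labels_a, labels_b, exact_max = 8) {
  if (length(labels_a) != length(labels_b)) {
    abort("`labels_a` and `labels_b` must have the same length")
  }
  tab <- unclass(table(labels_a, labels_b))
  K <- max(nrow(tab), ncol(tab))
  M <- matrix(0, K, K)
  M[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  if (K <= exact_max) {
    best <- 0
    for (p in all_permutations(seq_len(K))) {
      best <- max(best, sum(M[cbind(seq_len(K), p)]))
    }
  } else {
    # greedy: repeatedly take the largest remaining cell
    best <- 0
    rows <- cols <- rep(TRUE, K)
    for (i in seq_len(K)) {
      sub <- M
      sub[!rows, ] <- -1
      sub[, !cols] <- -1
      ij <- arrayInd(which.max(sub), dim(sub))
      best <- best + M[ij[1], ij[2]]
      rows[ij[1]] <- cols[ij[2]] <- FALSE
    }
  }
  100 * best / length(labels_a)
}

#' Bootstrap validation of one hypothetical-participant case
#'
#' For each of `B` bootstrap replicates: draw a label sequence of the given
#' length by the case's sampling rule, assemble the matching observation
#' matrix (members resampled with replacement from the labelled dataset),
#' fit the mixture model, assign emergent labels, and score (i) agreement
#' with the ground truth (Adjusted Rand Index and matched-assignment
#' percentage), (ii) the ground-truth EER from the generating labels,
#' (iii) the estimated EER from the emergent labels, and (iv) their
#' difference.  Summaries are means with 2.5/97.5 percentile intervals over
#' replicates.
#'
#' By default the mixture is fitted with K fixed at the case's ground-truth
#' cluster count - each hypothetical case is defined with a known K.
#' Supplying `K_grid` instead selects K per replicate by the BIC
#' first-plateau rule; note that at 200 observations of these strongly
#' non-Gaussian within-group shapes the plateau rule tends to over-select K
#' (see the methods vignette), which is why it is not the default here.
#'
#' A replicate whose fit does not converge is retried once and recorded as
#' failed (and excluded) if the retry also fails.  Replicates with no
#' exploitation transitions carry an infinite EER and are excluded from the
#' EER means, with the exclusion count reported.
#'
#' @param dataset Labelled dataset from [simulate_curves()].
#' @param probs Sampling probabilities of the case.
#' @param clusters Group labels the probabilities refer to.
#' @param B Number of bootstrap replicates (default 500).
#' @param length Sequence length per replicate (default 200).
#' @param K Fixed component count (default `length(clusters)`).
#' @param K_grid Optional K grid for per-replicate BIC-plateau selection
#'   (overrides `K`).
#' @param plateau_frac Plateau threshold for `K_grid` selection.
#' @param case_id Identifier copied into the output (default `NA`).
#' @param family Covariance family for the per-replicate fits.  The default
#'   `"shared_diagonal"` pools one diagonal variance vector across clusters:
#'   with as few as ~20 members per cluster in 120 dimensions, per-cluster
#'   variance estimates are poorly determined and the unpooled likelihood
#'   can prefer splitting a broad cluster over separating a small distinct
#'   one; pooling removes that failure mode (see the methods vignette).
#' @param seed Optional integer seed.
#' @param ... Passed to [fit_gmm()] / [fit_gmm_grid()] (e.g. `n_restarts`).
#' @return An object of class `validation_case`: a list with `replicates`
#'   (per-replicate tibble: `case`, `replicate`, `K_used`, `ari`,
#'   `agreement_pct`, `true_eer`, `est_eer`, `diff`), `summary` (one-row
#'   tibble of means and percentile CIs), `case_id`, `B`, `n_failed`,
#'   `n_inf_eer`.
#' @export
run_case_validation <- function(dataset, probs, clusters = seq_along(probs),
                                B = 500, length = 200,
                                K = base::length(clusters), K_grid = NULL,
                                plateau_frac = 0.05, case_id = NA_integer_,
                                family = "shared_diagonal", seed = NULL, ...) {
  if (B < 1) abort("`B` must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  Xall <- curve_matrix(dataset)
  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    res <- NULL
    for (attempt in 1:2) {
      seq_tbl <- sample_behavior_sequence(dataset, probs, clusters, length)
      X <- Xall[seq_tbl$obs_id, , drop = FALSE]
      if (is.null(K_grid)) {
        fit <- fit_gmm(X, K, family = family, ...)
        K_used <- K
      } else {
        grid <- fit_gmm_grid(X, K_grid = K_grid, family = family, ...)
        K_used <- as.integer(select_K(grid, plateau_frac))
        fit <- grid$fits[[paste0("K", K_used)]]
      }
      if (!fit$converged) next
      est_labels <- fit$labels
      true_eer <- eer(seq_tbl$label)$eer
      est_eer <- eer(est_labels)$eer
      res <- tibble::tibble(
        case = case_id, replicate = b, K_used = K_used,
        ari = adjusted_rand_index(seq_tbl$label, est_labels),
        agreement_pct = raw_agreement(seq_tbl$label, est_labels),
        true_eer = true_eer, est_eer = est_eer,
        diff = est_eer - true_eer
      )
      break
    }
    if (is.null(res)) n_failed <- n_failed + 1L else reps[[b]] <- res
  }
  replicates <- dplyr::bind_rows(reps)
  if (nrow(replicates) == 0) abort("all replicates failed to converge")
  n_inf <- sum(!is.finite(replicates$true_eer) | !is.finite(replicates$est_eer))
  fin <- replicates[is.finite(replicates$true_eer) & is.finite(replicates$est_eer), ]
  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  summary <- tibble::tibble(
    case = case_id,
    K = if (is.null(K_grid)) K else NA_integer_,
    B = B,
    mean_ari = mean(replicates$ari),
    mean_agreement_pct = mean(replicates$agreement_pct),
    agreement_lo = ci(replicates$agreement_pct)[1],
    agreement_hi = ci(replicates$agreement_pct)[2],
    mean_true_eer = mean(fin$true_eer),
    true_eer_lo = ci(fin$true_eer)[1],
    true_eer_hi = ci(fin$true_eer)[2],
    mean_est_eer = mean(fin$est_eer),
    est_eer_lo = ci(fin$est_eer)[1],
    est_eer_hi = ci(fin$est_eer)[2],
    mean_diff = mean(fin$diff),
    diff_lo = ci(fin$diff)[1],
    diff_hi = ci(fin$diff)[2]
  )
  structure(
    list(replicates = replicates, summary = summary, case_id = case_id,
         B = B, n_failed = n_failed, n_inf_eer = n_inf),
    class = "validation_case"
  )
}

#' @export
print.validation_case <- function(x, ...) {
  cat(sprintf(
    "Bootstrap cluster validation (case %s, B = %d, %d failed, %d infinite-EER)\n",
    x$case_id, x$B, x$n_failed, x$n_inf_eer
  ))
  print(x$summary)
  invisible(x)
}

#' Aggregate case validations into a Table-2-style report
#'
#' @param cases A list of `validation_case` objects (e.g. one per sampling
#'   rule).
#' @return A tibble with one row per case: ground-truth K, mean agreement
#'   (%), mean ARI, and the ground-truth / estimated / difference EER means
#'   with 95% percentile confidence intervals.
#' @export
summarize_validation <- function(cases) {
  purrr::map_dfr(cases, function(cs) {
    stopifnot(inherits(cs, "validation_case"))
    cs$summary
  })
}

#' Replicate-level log of a validation study
#'
#' @param cases A list of `validation_case` objects.
#' @return A tibble binding all per-replicate rows.
#' @export
validation_replicates <- function(cases) {
  purrr::map_dfr(cases, function(cs) cs$replicates)
}
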