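# internal helpers shared across modules

# row-wise log(sum(exp(M))) without overflow
row_logsumexp <- function(M) {
  mx <- do.call(pmax, as.data.frame(M))
  mx + log(rowSums(exp(M - mx)))
}

# k-means++ seeding: D^2-weighted choice of K initial centers
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  ctr <- X[sample.int(n, 1L), , drop = FALSE]
  if (K == 1L) return(ctr)
  d2 <- rowSums(sweep(X, 2L, ctr[1L, ])^2)
  for (k in seq_len(K - 1L)) {
    i <- sample.int(n, 1L, prob = pmax(d2, 1e-300))
    ctr <- rbind(ctr, X[i, ])
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[i, ])^2))
  }
  ctr
}

# all permutations of a vector (used for exact label alignment, small K only)
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

assert_prob_vector <- function(p, arg = "probs", tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort(sprintf("`%s` must be finite and non-negative.", arg))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.15g).", arg, sum(p)))
  }
  invisible(p)
}

# extract a plain numeric matrix from either a matrix or a data frame of
# feature columns (non-numeric metadata columns are dropped)
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    meta <- c(
      "obs_id", "true_label", "trial", "block", "reward", "label", "cluster",
      "posterior_max"
    )
    keep <- num & !(names(x) %in% meta)
    return(as.matrix(x[, keep, drop = FALSE]))
  }
  abort("expected a matrix or data frame of feature columns")
}
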