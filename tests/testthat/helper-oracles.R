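# Independent oracles used across the suite.  Each is deliberately written
# in a different form than the package implementation it checks.

# ARI by exhaustive pair enumeration: count pairs together/apart in both
# labelings and apply the pair-count identity
ari_bruteforce <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# matched-assignment % by exhaustive search over label permutations
agreement_bruteforce <- function(a, b) {
  la <- sort(unique(a))
  lb <- sort(unique(b))
  K <- max(length(la), length(lb))
  la <- c(la, rep(max(la) + seq_len(K - length(la)), length.out = K - length(la)))
  lb <- c(lb, rep(max(lb) + seq_len(K - length(lb)), length.out = K - length(lb)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(K))) {
    map <- setNames(lb[p], la)
    best <- max(best, sum(map[as.character(a)] == b))
  }
  100 * best / length(a)
}

# minimum-jerk position fraction (closed form, restated independently)
mj <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# expected EER of an i.i.d. categorical sequence (infinite-length limit)
eer_closed_form <- function(p) (1 - sum(p^2)) / sum(p^2)

# small labelled Gaussian-blob dataset for clustering tests
make_blobs <- function(n_per = 30, d = 3, sep = 8, K = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(K), function(k) {
      matrix(rnorm(n_per * d, mean = sep * k), n_per, d)
    }))
    list(X = X, labels = rep(seq_len(K), each = n_per))
  })
}
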