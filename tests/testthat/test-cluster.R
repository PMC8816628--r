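test_that("K=1 fit reproduces the sample moments in closed form", {
  withr::local_seed(2)
  X <- matrix(rnorm(200), 50, 4)
  f <- fit_gmm(X, K = 1)
  expect_equal(drop(f$means), colMeans(X), ignore_attr = TRUE)
  mle_var <- apply(X, 2, function(x) mean((x - mean(x))^2))
  expect_equal(drop(f$variances), mle_var, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(f$weights, 1)
})

test_that("well-separated blobs are recovered exactly in every family", {
  blobs <- make_blobs(n_per = 40, d = 4, sep = 10, K = 2, seed = 3)
  for (fam in c("diagonal", "shared_diagonal", "full")) {
    f <- fit_gmm(blobs$X, K = 2, family = fam, seed = 5)
    expect_equal(adjusted_rand_index(blobs$labels, f$labels), 1)
    expect_true(f$converged)
  }
})

test_that("EM log-likelihood is monotone non-decreasing on random instances", {
  withr::local_seed(17)
  for (i in 1:8) {
    n <- sample(30:80, 1)
    d <- sample(2:5, 1)
    K <- sample(2:3, 1)
    centers <- matrix(rnorm(K * d, sd = 3), K, d)
    X <- matrix(rnorm(n * d), n, d) + centers[sample(K, n, TRUE), ]
    fam <- sample(c("diagonal", "shared_diagonal", "full"), 1)
    f <- fit_gmm(X, K, family = fam, n_restarts = 2)
    expect_true(all(diff(f$loglik_trace) > -1e-6 * abs(f$loglik)))
  }
})

test_that("restarts never decrease the reported log-likelihood", {
  blobs <- make_blobs(n_per = 25, d = 3, sep = 3, K = 3, seed = 7)
  f1 <- fit_gmm(blobs$X, K = 3, n_restarts = 1, seed = 11)
  f10 <- fit_gmm(blobs$X, K = 3, n_restarts = 10, seed = 11)
  expect_gte(f10$loglik + 1e-9 * abs(f10$loglik), f1$loglik)
})

test_that("information criteria match the hand-computed 1-D Gaussian", {
  x <- c(2.1, -0.3, 1.7, 0.4, 2.9, -1.2, 0.8, 1.5, 0.2, 1.1)
  f <- fit_gmm(matrix(x, ncol = 1), K = 1)
  # closed-form MLE log-likelihood of a single Gaussian
  v <- mean((x - mean(x))^2)
  ll <- sum(dnorm(x, mean(x), sqrt(v), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  np <- 2  # mean + variance
  ic <- information_criteria(f)
  expect_equal(ic$bic, 2 * ll - np * log(10), tolerance = 1e-6)
  expect_equal(ic$aic, 2 * ll - 2 * np, tolerance = 1e-6)
  # the penalty is monotone: same loglik, more params => lower bic
  expect_lt(information_criteria(ll, 5, 10)$bic, information_criteria(ll, 2, 10)$bic)
  expect_equal(information_criteria(ll, 0, 10)$bic, 2 * ll)
})

test_that("the first-plateau rule selects K as specified", {
  grid <- data.frame(K = 1:5, bic = c(0, 80, 98, 100, 100.5))
  expect_equal(as.integer(select_K(grid, plateau_frac = 0.05)), 3)
  # flat BIC: every gain is below threshold => grid minimum
  flat <- data.frame(K = 2:6, bic = rep(10, 5))
  expect_equal(as.integer(select_K(flat)), 2)
  # steep gains throughout: grid maximum with a warning
  steep <- data.frame(K = 2:5, bic = c(0, 100, 200, 300))
  expect_warning(ks <- select_K(steep), "steep")
  expect_equal(as.integer(ks), 5)
  expect_error(select_K(data.frame(K = 1:2, bic = c(1, 2))), "3 grid points")
})

test_that("posteriors are proper and consistent with MAP labels", {
  blobs <- make_blobs(n_per = 30, d = 3, sep = 4, K = 3, seed = 9)
  f <- fit_gmm(blobs$X, K = 3, seed = 1)
  pr <- predict(f)
  P <- as.matrix(pr[, paste0("p", 1:3)])
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_equal(pr$cluster, f$labels)
  expect_equal(pr$posterior_max, apply(P, 1, max))
  # predict on new data reproduces the training assignment
  pr2 <- predict(f, newdata = blobs$X)
  expect_equal(pr2$cluster, f$labels)
})

test_that("the fit is invariant to row shuffling up to label permutation", {
  blobs <- make_blobs(n_per = 30, d = 4, sep = 8, K = 2, seed = 13)
  f1 <- fit_gmm(blobs$X, K = 2, seed = 5)
  perm <- withr::with_seed(1, sample(nrow(blobs$X)))
  f2 <- fit_gmm(blobs$X[perm, ], K = 2, seed = 6)
  expect_equal(adjusted_rand_index(f1$labels[perm], f2$labels), 1)
})

test_that("order_clusters renumbers left to right and is stable", {
  blobs <- make_blobs(n_per = 20, d = 4, sep = 6, K = 3, seed = 15)
  f <- fit_gmm(blobs$X, K = 3, seed = 2)
  # order by an explicit per-cluster statistic: mean endpoint PD -2 / 0 / +2
  stat <- c(2, -2, 0)
  fo <- order_clusters(f, endpoint = stat)
  expect_equal(attr(fo, "perm"), rank(stat))  # left-most mean becomes label 1
  expect_equal(fo$labels, attr(fo, "perm")[f$labels])
  # posterior columns were permuted consistently
  expect_equal(max.col(fo$posterior), fo$labels)
  # ordering is invariant to which permutation the fit converged to
  fo2 <- order_clusters(order_clusters(f, endpoint = stat), endpoint = sort(stat))
  expect_equal(fo2$labels, fo$labels)
  # trial-feature fits order by the endpoint PD of the mean trajectory
  pol <- reach_policy(mode_angles_deg = c(5, -5), motor_noise_sd_deg = 0.2,
                      curvature_sd_deg = 0,
                      p_switch_given_reward = 0.5, p_switch_given_fail = 0.5)
  s <- simulate_session(pol, make_schedule("Fixed"), seed = 21)
  tm <- build_trial_matrix(s)
  ftr <- order_clusters(suppressWarnings(fit_gmm(trial_features(tm), K = 2, seed = 3)))
  pd_by_cluster <- tapply(s$pd_end, ftr$labels, mean)
  expect_lt(pd_by_cluster["1"], pd_by_cluster["2"])
})

test_that("cluster variance summaries match a direct scatter computation", {
  blobs <- make_blobs(n_per = 40, d = 3, sep = 10, K = 2, seed = 19)
  f <- fit_gmm(blobs$X, K = 2, seed = 4)
  cv <- cluster_variances(f)
  for (k in 1:2) {
    Xk <- blobs$X[f$labels == k, ]
    scatter <- mean(apply(Xk, 2, function(x) mean((x - mean(x))^2)))
    expect_equal(cv$variance[k], scatter, tolerance = 0.05)
  }
  expect_equal(nrow(cv), 2)
})

test_that("achieved log-likelihood matches an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  blobs <- make_blobs(n_per = 50, d = 2, sep = 5, K = 2, seed = 23)
  f <- fit_gmm(blobs$X, K = 2, family = "diagonal", seed = 8, tol = 1e-10)
  m <- Mclust(blobs$X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(f$loglik, m$loglik, tolerance = 1e-4)
  expect_equal(adjusted_rand_index(f$labels, m$classification), 1)
})

test_that("the Fisher-subspace option produces an orthonormal subspace", {
  blobs <- make_blobs(n_per = 40, d = 6, sep = 8, K = 3, seed = 27)
  f <- fit_gmm(blobs$X, K = 3, subspace = TRUE, n_restarts = 3, seed = 2)
  U <- f$subspace$loadings
  expect_equal(dim(U), c(6, 2))  # rank K-1 < K
  expect_equal(crossprod(U), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(adjusted_rand_index(blobs$labels, f$labels), 1)
  # posterior rows still sum to one
  expect_true(all(abs(rowSums(f$posterior) - 1) < 1e-9))
})

test_that("broom methods summarize fits and grids", {
  blobs <- make_blobs(n_per = 25, d = 3, sep = 8, K = 2, seed = 29)
  f <- fit_gmm(blobs$X, K = 2, seed = 1)
  td <- tidy(f)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$weight), 1)
  g <- glance(f)
  expect_equal(g$K, 2L)
  expect_equal(g$bic, f$bic)
  grid <- fit_gmm_grid(blobs$X, K_grid = 1:3, n_restarts = 3, seed = 2)
  expect_equal(tidy(grid)$K, 1:3)
})
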