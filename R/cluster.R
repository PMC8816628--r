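# Model-based clustering: Gaussian mixtures fitted by multi-restart EM,
# information-criterion model selection, and the left-to-right cluster
# ordering convention.

# per-observation log joint densities log(w_k) + log N(x | mu_k, Sigma_k),
# one column per component
log_component_densities <- function(X, w, mu, vars, family) {
  n <- nrow(X); d <- ncol(X); K <- length(w)
  LP <- matrix(0, n, K)
  if (family %in% c("diagonal", "shared_diagonal")) {
    X2 <- X^2
    for (k in seq_len(K)) {
      iv <- 1 / vars[k, ]
      LP[, k] <- log(w[k]) - 0.5 * (
        d * log(2 * pi) + sum(log(vars[k, ])) +
          drop(X2 %*% iv) - 2 * drop(X %*% (mu[k, ] * iv)) + sum(mu[k, ]^2 * iv)
      )
    }
  } else {
    for (k in seq_len(K)) {
      ch <- chol(vars[[k]])
      Z <- forwardsolve(t(ch), t(sweep(X, 2L, mu[k, ])))
      LP[, k] <- log(w[k]) - 0.5 * (
        d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(Z^2)
      )
    }
  }
  LP
}

regularize_cov <- function(S, ridge_abs) {
  S + diag(ridge_abs, nrow(S))
}

# deterministic agglomerative (Ward) initialization for criterion scans;
# large inputs are subsampled (using the caller's RNG stream) before the
# quadratic-cost linkage, and the resulting group means seed the EM
ward_init_means <- function(X, K, max_n = 2000) {
  n <- nrow(X)
  idx <- if (n > max_n) sample.int(n, max_n) else seq_len(n)
  cl <- stats::cutree(stats::hclust(stats::dist(X[idx, , drop = FALSE]),
                                    method = "ward.D2"), K)
  do.call(rbind, lapply(seq_len(K), function(g) {
    colMeans(X[idx[cl == g], , drop = FALSE])
  }))
}

em_once <- function(X, K, family, max_iter, tol, ridge, init_means) {
  n <- nrow(X); d <- ncol(X)
  vtot <- apply(X, 2L, var)
  ridge_abs <- ridge * mean(vtot)
  mu <- init_means
  w <- rep(1 / K, K)
  regularized <- FALSE
  if (family %in% c("diagonal", "shared_diagonal")) {
    vars <- matrix(pmax(vtot, ridge_abs), K, d, byrow = TRUE)
  } else {
    S0 <- regularize_cov(var(X) * (n - 1) / n, ridge_abs)
    vars <- replicate(K, S0, simplify = FALSE)
  }
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    LP <- log_component_densities(X, w, mu, vars, family)
    lse <- row_logsumexp(LP)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    R <- exp(LP - lse)
    nk <- colSums(R) + 1e-300
    w <- nk / n
    mu <- (t(R) %*% X) / nk
    if (family == "diagonal") {
      vars <- (t(R) %*% X^2) / nk - mu^2
      if (any(vars < ridge_abs)) regularized <- TRUE
      vars <- pmax(vars, ridge_abs)
    } else if (family == "shared_diagonal") {
      v <- colSums((t(R) %*% X^2) - nk * mu^2) / n
      if (any(v < ridge_abs)) regularized <- TRUE
      vars <- matrix(pmax(v, ridge_abs), K, d, byrow = TRUE)
    } else {
      for (k in seq_len(K)) {
        Xc <- sweep(X, 2L, mu[k, ]) * sqrt(R[, k])
        Sk <- crossprod(Xc) / nk[k]
        ok <- tryCatch({ chol(Sk); TRUE }, error = function(e) FALSE)
        if (!ok || min(diag(Sk)) < ridge_abs) {
          Sk <- regularize_cov(Sk, ridge_abs)
          regularized <- TRUE
        }
        vars[[k]] <- Sk
      }
    }
  }
  LP <- log_component_densities(X, w, mu, vars, family)
  lse <- row_logsumexp(LP)
  list(
    loglik = sum(lse), w = w, mu = mu, vars = vars,
    posterior = exp(LP - lse), trace = trace, n_iter = length(trace),
    converged = converged, regularized = regularized
  )
}

# free-parameter count of a K-component mixture in d dimensions
gmm_n_params <- function(K, d, family) {
  cov_params <- switch(family,
    diagonal = K * d,
    shared_diagonal = d,
    full = K * d * (d + 1) / 2
  )
  (K - 1) + K * d + cov_params
}

#' Fit a K-component Gaussian mixture by EM
#'
#' With `init = "kmeanspp"` (the default) the EM is run `n_restarts` times
#' from independent k-means++ seedings and the fit with the highest
#' log-likelihood is kept.  With `init = "ward"` a single EM run starts from
#' the group means of an agglomerative Ward partition (subsampled above 2000
#' rows), the conventional deterministic initialization for information-
#' criterion scans over K.  The log-likelihood is non-decreasing over EM
#' iterations (the trace is stored in `$loglik_trace`).  Near-singular
#' covariances are handled by a ridge floor of `ridge` times the mean total
#' variance, with a warning when it engages.
#'
#' Information criteria are oriented so that **higher is better**:
#' `bic = 2*loglik - n_params*log(n)` and `aic = 2*loglik - 2*n_params`.
#'
#' With `subspace = TRUE` the EM alternates with re-estimation of an
#' orthonormal discriminative subspace (rank `K - 1` by default) maximizing
#' the Fisher between/within criterion, and the mixture is fitted to the
#' projected coordinates; see [fisher_em()].
#'
#' @param data Numeric matrix (observations x features) or a data frame with
#'   numeric feature columns (e.g. from [build_trial_matrix()] or
#'   [simulate_curves()]; recognized metadata columns are dropped).
#' @param K Number of mixture components (`2 <= K <= n` rows).
#' @param family Covariance family: `"diagonal"` (default; per-cluster
#'   diagonal), `"shared_diagonal"` (one diagonal variance vector pooled
#'   across clusters - the robust choice when cluster sizes are small
#'   relative to the dimension), or `"full"` (per-cluster unrestricted).
#' @param init Initialization: `"kmeanspp"` (multi-restart) or `"ward"`
#'   (single deterministic agglomerative start).
#' @param n_restarts Number of independent EM runs for `"kmeanspp"`
#'   (default 10; ignored for `"ward"`).
#' @param max_iter Maximum EM iterations per run (default 300).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param ridge Covariance ridge fraction (default 1e-6).
#' @param subspace Fit in a Fisher discriminative subspace (default FALSE).
#' @param subspace_rank Rank of the subspace (default `K - 1`).
#' @param seed Optional integer seed.
#' @return An object of class `gmm_fit` with elements `K`, `weights`,
#'   `means` (K x d), `variances` (K x d matrix for `"diagonal"`, list of
#'   d x d matrices for `"full"`), `posterior`, `labels` (MAP), `loglik`,
#'   `loglik_trace`, `n_params`, `bic`, `aic`, `converged`, `n_iter`,
#'   `family`, `n`, `d`, and (subspace fits only) `subspace` (d x r
#'   orthonormal loadings).
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, 5), 50))
#' f <- fit_gmm(X, K = 2, seed = 1)
#' glance(f)
fit_gmm <- function(data, K, family = c("diagonal", "shared_diagonal", "full"),
                    init = c("kmeanspp", "ward"), n_restarts = 10,
                    max_iter = 300, tol = 1e-6, ridge = 1e-6,
                    subspace = FALSE, subspace_rank = NULL, seed = NULL) {
  family <- match.arg(family)
  init <- match.arg(init)
  X <- as_feature_matrix(data)
  n <- nrow(X); d <- ncol(X)
  if (K > n) abort(sprintf("K = %d exceeds the number of observations (%d)", K, n))
  if (K < 1) abort("K must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  if (subspace) {
    return(fisher_em(X, K, family = family, n_restarts = n_restarts,
                     max_iter = max_iter, tol = tol, ridge = ridge,
                     subspace_rank = subspace_rank))
  }
  n_runs <- if (init == "ward" || K == 1L) 1L else n_restarts
  best <- NULL
  for (rs in seq_len(n_runs)) {
    mu0 <- if (K == 1L) {
      matrix(colMeans(X), 1L)
    } else if (init == "ward") {
      ward_init_means(X, K)
    } else {
      kmeanspp_centers(X, K)
    }
    run <- em_once(X, K, family, max_iter, tol, ridge, mu0)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (best$regularized) {
    warn("near-singular covariance: ridge regularization applied")
  }
  np <- gmm_n_params(K, d, family)
  structure(
    list(
      K = as.integer(K), weights = best$w, means = best$mu,
      variances = best$vars, posterior = best$posterior,
      labels = max.col(best$posterior), loglik = best$loglik,
      loglik_trace = best$trace, n_params = np,
      bic = 2 * best$loglik - np * log(n),
      aic = 2 * best$loglik - 2 * np,
      converged = best$converged, n_iter = best$n_iter,
      family = family, n = n, d = d, subspace = NULL
    ),
    class = "gmm_fit"
  )
}

#' Information criteria of a fitted mixture (higher is better)
#'
#' `bic = 2*loglik - n_params*log(n)`, `aic = 2*loglik - 2*n_params`.  With
#' this orientation a higher value represents a better fit, and the
#' incremental gain over a K grid flattens into a plateau.
#'
#' @param loglik Maximized log-likelihood (or a `gmm_fit`, from which
#'   everything is taken).
#' @param n_params Free-parameter count.
#' @param n Number of observations.
#' @return A one-row tibble with `bic` and `aic`.
#' @export
information_criteria <- function(loglik, n_params = NULL, n = NULL) {
  if (inherits(loglik, "gmm_fit")) {
    fit <- loglik
    loglik <- fit$loglik; n_params <- fit$n_params; n <- fit$n
  }
  tibble::tibble(
    bic = 2 * loglik - n_params * log(n),
    aic = 2 * loglik - 2 * n_params
  )
}

#' Fit Gaussian mixtures over a grid of K values
#'
#' Cold-starts an independent EM fit at every K.  The default
#' initialization for grid scans is the deterministic agglomerative
#' (`"ward"`) start: comparing information criteria across K is more stable
#' when every fit descends from the same hierarchical partition than when
#' each K independently chases its best restart.
#'
#' @inheritParams fit_gmm
#' @param K_grid Integer vector of component counts (default `2:6`).
#' @return An object of class `gmm_grid`: a list with `fits` (one `gmm_fit`
#'   per K) and `criteria` (tibble of K, loglik, n_params, bic, aic,
#'   converged).
#' @export
fit_gmm_grid <- function(data, K_grid = 2:6,
                         family = c("diagonal", "shared_diagonal", "full"),
                         init = c("ward", "kmeanspp"), n_restarts = 10,
                         max_iter = 300, tol = 1e-6, ridge = 1e-6,
                         seed = NULL) {
  family <- match.arg(family)
  init <- match.arg(init)
  if (!is.null(seed)) withr::local_seed(seed)
  X <- as_feature_matrix(data)
  fits <- purrr::map(K_grid, function(K) {
    fit_gmm(X, K, family = family, init = init, n_restarts = n_restarts,
            max_iter = max_iter, tol = tol, ridge = ridge)
  })
  names(fits) <- paste0("K", K_grid)
  criteria <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      K = f$K, loglik = f$loglik, n_params = f$n_params,
      bic = f$bic, aic = f$aic, converged = f$converged
    )
  })
  structure(list(fits = fits, criteria = criteria), class = "gmm_grid")
}

#' Select the number of clusters at the first BIC plateau
#'
#' The optimum K is the first K whose marginal BIC gain to the next grid
#' point falls below `plateau_frac` times the BIC range over the whole grid.
#' If the gains stay steep throughout, the grid maximum is returned with a
#' warning.
#'
#' @param grid A `gmm_grid` from [fit_gmm_grid()], or a tibble/data frame
#'   with columns `K` and `bic`.
#' @param plateau_frac Plateau threshold as a fraction of the BIC range
#'   (default 0.05).
#' @return The selected K (integer), with the criteria table and threshold
#'   attached as attributes `criteria` and `threshold`.
#' @export
#' @examples
#' select_K(data.frame(K = 1:5, bic = c(0, 80, 98, 100, 100.5)))  # 3
select_K <- function(grid, plateau_frac = 0.05) {
  criteria <- if (inherits(grid, "gmm_grid")) grid$criteria else tibble::as_tibble(grid)
  if (nrow(criteria) < 3) abort("at least 3 grid points are required")
  criteria <- dplyr::arrange(criteria, .data$K)
  bic <- criteria$bic
  gains <- diff(bic)
  threshold <- plateau_frac * diff(range(bic))
  # non-strict so that a perfectly flat grid plateaus at its first point
  hit <- which(gains <= threshold)
  if (length(hit) == 0) {
    warn("BIC gains stay steep over the whole grid; returning the grid maximum")
    K_star <- criteria$K[nrow(criteria)]
  } else {
    K_star <- criteria$K[hit[1]]
  }
  structure(as.integer(K_star), criteria = criteria, threshold = threshold)
}

#' Posterior cluster membership for observations
#'
#' @param object A `gmm_fit`.
#' @param newdata Optional new observations (matrix or data frame); defaults
#'   to the training posteriors.
#' @param ... Unused.
#' @return A tibble with `cluster` (MAP label), `posterior_max`, and one
#'   `p<k>` column per component; posterior rows sum to 1.
#' @export
predict.gmm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    P <- object$posterior
  } else {
    X <- as_feature_matrix(newdata)
    if (!is.null(object$subspace)) {
      X <- sweep(X, 2L, object$subspace$center) %*% object$subspace$loadings
      LP <- log_component_densities(X, object$weights, object$subspace$means,
                                    object$subspace$variances, object$family)
    } else {
      LP <- log_component_densities(X, object$weights, object$means,
                                    object$variances, object$family)
    }
    P <- exp(LP - row_logsumexp(LP))
  }
  colnames(P) <- paste0("p", seq_len(object$K))
  dplyr::bind_cols(
    tibble::tibble(cluster = max.col(P), posterior_max = apply(P, 1L, max)),
    tibble::as_tibble(P)
  )
}

#' Append cluster assignments to a trial metadata table
#'
#' @param data The tibble the observations came from (row-aligned with the
#'   fitted matrix).
#' @param fit A `gmm_fit`.
#' @return `data` with `cluster` and `posterior_max` columns appended.
#' @export
assign_clusters <- function(data, fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (nrow(data) != fit$n) abort("`data` rows do not match the fitted observations")
  pr <- predict(fit)
  dplyr::mutate(data, cluster = pr$cluster, posterior_max = pr$posterior_max)
}

#' Renumber clusters from left to right by endpoint position
#'
#' Relabels the mixture components in ascending order of the signed lateral
#' endpoint coordinate of each cluster's mean trajectory, so that cluster 1
#' is the left-most and cluster K the right-most.  Ties are broken by the
#' orthogonal (along-reach) endpoint coordinate of the mean, then by the
#' original component index.
#'
#' @param fit A `gmm_fit`.
#' @param endpoint Per-cluster ordering statistic: a numeric vector of
#'   length K, a function applied to the K x d mean matrix returning one, or
#'   `NULL` (default) to use the built-in convention - for 60-feature trial
#'   vectors (`x01..y30`) the perpendicular deviation of the mean endpoint,
#'   otherwise the last column of the means.
#' @return The relabeled `gmm_fit`; the permutation applied is stored in
#'   attribute `perm` (`perm[old_label] = new_label`).
#' @export
order_clusters <- function(fit, endpoint = NULL) {
  stopifnot(inherits(fit, "gmm_fit"))
  M <- fit$means
  if (is.null(endpoint)) {
    stat <- default_endpoint_stat(fit)
  } else if (is.function(endpoint)) {
    stat <- endpoint(M)
  } else {
    stat <- endpoint
  }
  if (length(stat) != fit$K) abort("`endpoint` must yield one value per cluster")
  tie1 <- orthogonal_endpoint_stat(fit)
  ord <- order(stat, tie1, seq_len(fit$K))
  perm <- integer(fit$K)
  perm[ord] <- seq_len(fit$K)  # perm[old] = new
  fit$weights <- fit$weights[ord]
  fit$means <- fit$means[ord, , drop = FALSE]
  fit$variances <- if (is.list(fit$variances)) fit$variances[ord] else
    fit$variances[ord, , drop = FALSE]
  fit$posterior <- fit$posterior[, ord, drop = FALSE]
  fit$labels <- perm[fit$labels]
  if (!is.null(fit$subspace)) {
    fit$subspace$means <- fit$subspace$means[ord, , drop = FALSE]
    fit$subspace$variances <- if (is.list(fit$subspace$variances)) {
      fit$subspace$variances[ord]
    } else {
      fit$subspace$variances[ord, , drop = FALSE]
    }
  }
  attr(fit, "perm") <- perm
  fit
}

# lateral endpoint PD of each cluster mean: trial-feature fits use the
# (x, y) endpoint columns, generic fits the last feature column
default_endpoint_stat <- function(fit) {
  d <- fit$d
  if (d %% 2 == 0 && !is.null(colnames(fit$means)) &&
      all(grepl("^[xy][0-9]+$", colnames(fit$means)))) {
    np <- d / 2
    return(lateral_coordinate(fit$means[, np], fit$means[, 2 * np]))
  }
  fit$means[, d]
}

orthogonal_endpoint_stat <- function(fit) {
  d <- fit$d
  if (d %% 2 == 0 && !is.null(colnames(fit$means)) &&
      all(grepl("^[xy][0-9]+$", colnames(fit$means)))) {
    np <- d / 2
    ang <- TARGET_ANGLE_DEG * pi / 180
    return(fit$means[, np] * cos(ang) + fit$means[, 2 * np] * sin(ang))
  }
  rep(0, fit$K)
}

#' Scalar variance summary per cluster
#'
#' One value per cluster: the trace of the cluster covariance divided by the
#' dimension (the mean per-feature variance).  Multiply by 100 to mirror the
#' conventional "x 10^-2" table formatting.
#'
#' @param fit A `gmm_fit`.
#' @return A tibble with `cluster` and `variance`.
#' @export
cluster_variances <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  v <- if (is.list(fit$variances)) {
    vapply(fit$variances, function(S) mean(diag(S)), numeric(1))
  } else {
    rowMeans(fit$variances)
  }
  tibble::tibble(cluster = seq_len(fit$K), variance = unname(v))
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian mixture fit: K = %d, %s covariance%s, n = %d, d = %d\n",
    x$K, x$family, if (!is.null(x$subspace)) " (Fisher subspace)" else "", x$n, x$d
  ))
  cat(sprintf(
    "  loglik = %.2f  BIC = %.2f  AIC = %.2f  (%s in %d iterations)\n",
    x$loglik, x$bic, x$aic,
    if (x$converged) "converged" else "not converged", x$n_iter
  ))
  invisible(x)
}

#' @export
print.gmm_grid <- function(x, ...) {
  cat("Gaussian mixture fits over a K grid\n")
  print(x$criteria)
  invisible(x)
}

#' Tidy a fitted Gaussian mixture: one row per component
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @return Tibble with `cluster`, `weight`, `size` (expected membership
#'   count) and `variance` (mean per-feature variance).
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$K),
    weight = x$weights,
    size = x$weights * x$n,
    variance = cluster_variances(x)$variance
  )
}

#' One-row model summary of a fitted Gaussian mixture
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, loglik = x$loglik, n_params = x$n_params, bic = x$bic,
    aic = x$aic, converged = x$converged, n_iter = x$n_iter, n = x$n, d = x$d
  )
}

#' @rdname tidy.gmm_fit
#' @export
tidy.gmm_grid <- function(x, ...) x$criteria

#' Serialize a fitted mixture to JSON
#'
#' Writes weights, means, per-cluster variance summaries, subspace loadings
#' (if any) and the information criteria in a documented layout.
#'
#' @param fit A `gmm_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmm_json <- function(fit, path) {
  obj <- list(
    K = fit$K, family = fit$family, n = fit$n, d = fit$d,
    weights = fit$weights,
    means = fit$means,
    cluster_variances = cluster_variances(fit)$variance,
    subspace = fit$subspace,
    loglik = fit$loglik, n_params = fit$n_params,
    bic = fit$bic, aic = fit$aic,
    converged = fit$converged, n_iter = fit$n_iter
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
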