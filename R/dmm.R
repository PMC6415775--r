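# Dirichlet-multinomial mixture (DMM) community typing.
#
# Samples are binned by community structure with a finite mixture of
# Dirichlet-multinomial components fitted by EM; the number of community
# types K is chosen by the lowest Laplace-approximation score (negative
# approximate log model evidence). Fitting works in log-gamma space
# throughout, so depths of 1e5 reads pose no overflow problem.

#' Log pmf of the Dirichlet-multinomial distribution
#'
#' Includes the multinomial coefficient, so the pmf is proper:
#' `log n!/(prod x_j!) + lgamma(A) - lgamma(n+A) +
#'  sum_j [lgamma(x_j + a_j) - lgamma(a_j)]` with `A = sum(a)`.
#'
#' @param x Non-negative integer count vector.
#' @param alpha Positive Dirichlet parameter vector, same length as `x`.
#' @return The log probability (a scalar).
#' @export
dm_log_pmf <- function(x, alpha) {
  if (length(x) != length(alpha)) abort("x and alpha must have equal length")
  if (any(alpha <= 0)) abort("alpha must be strictly positive")
  if (any(x < 0 | x != round(x))) abort("x must be non-negative integers")
  n <- sum(x)
  A <- sum(alpha)
  lgamma(n + 1) - sum(lgamma(x + 1)) +
    lgamma(A) - lgamma(n + A) +
    sum(lgamma(x + alpha) - lgamma(alpha))
}

# Sparse representation of the positive cells of a count matrix, plus the
# per-sample log multinomial coefficient. All DM likelihood terms involving
# cells with x = 0 vanish, so only positive cells are ever touched.
dmm_prepare <- function(X) {
  n <- rowSums(X)
  pos <- which(X > 0, arr.ind = TRUE)
  ord <- order(pos[, 1])
  ri <- pos[ord, 1]
  ci <- pos[ord, 2]
  xv <- X[cbind(ri, ci)]
  lfact <- lgamma(n + 1) - as.vector(rowsum(lgamma(xv + 1), ri))
  list(X = X, n = n, ri = ri, ci = ci, xv = xv, lfact = lfact,
       N = nrow(X), S = ncol(X))
}

# Column-wise aggregate of sparse cell values into a length-S vector.
agg_cols <- function(v, ci, S) {
  out <- numeric(S)
  a <- rowsum(v, ci)
  out[as.integer(rownames(a))] <- a
  out
}

# Log-likelihood of every sample under one DM component (vector length N).
dmm_comp_loglik <- function(prep, alpha) {
  A <- sum(alpha)
  v <- lgamma(prep$xv + alpha[prep$ci]) - lgamma(alpha)[prep$ci]
  prep$lfact + lgamma(A) - lgamma(prep$n + A) + as.vector(rowsum(v, prep$ri))
}

# Weighted Dirichlet-multinomial fixed-point update (Minka-style) for one
# component; `w` are responsibilities. `iters` inner iterations.
dmm_alpha_update <- function(prep, alpha, w, iters = 3, floor = 1e-8) {
  wcells <- w[prep$ri]
  for (it in seq_len(iters)) {
    A <- sum(alpha)
    den <- sum(w * (digamma(prep$n + A) - digamma(A)))
    v <- (digamma(prep$xv + alpha[prep$ci]) - digamma(alpha)[prep$ci]) * wcells
    num <- agg_cols(v, prep$ci, prep$S)
    if (den <= 0) break
    alpha <- pmax(alpha * num / den, floor)
  }
  alpha
}

# Moment-style initial alpha for a (soft) cluster of samples.
dmm_alpha_init <- function(X, w, conc = 30, floor = 1e-8) {
  p <- colSums(X * w) / sum(X * w)
  pmax(p * conc, 0.05)
}

row_logsumexp <- function(M) {
  mx <- do.call(pmax, as.data.frame(M))
  mx + log(rowSums(exp(M - mx)))
}

dmm_em_once <- function(prep, k, seed, max_iter, tol, inner_iter, verbose) {
  X <- prep$X
  N <- prep$N
  rel <- X / prep$n
  init <- withr::with_seed(seed, {
    if (k == 1) rep(1L, N) else {
      # k-means on sqrt proportions (variance stabilised) for initial bins
      km <- suppressWarnings(stats::kmeans(sqrt(rel), centers = k,
                                           nstart = 5, iter.max = 50))
      km$cluster
    }
  })
  alpha <- matrix(0, k, prep$S)
  for (j in seq_len(k)) alpha[j, ] <- dmm_alpha_init(X, as.numeric(init == j))
  pi_k <- as.numeric(tabulate(init, k)) / N
  pi_k <- pmax(pi_k, 1e-8); pi_k <- pi_k / sum(pi_k)
  dmm_em_core(prep, alpha, pi_k, max_iter, tol, inner_iter, verbose)
}

# EM from given starting parameters.
dmm_em_core <- function(prep, alpha, pi_k, max_iter, tol, inner_iter,
                        verbose = FALSE, polish = TRUE) {
  X <- prep$X
  N <- prep$N
  k <- length(pi_k)
  nll_trace <- numeric(0)
  nll_prev <- Inf
  r <- matrix(1 / k, N, k)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    LL <- vapply(seq_len(k), function(j) dmm_comp_loglik(prep, alpha[j, ]),
                 numeric(N))
    M <- sweep(matrix(LL, N, k), 2, log(pi_k), "+")
    lse <- row_logsumexp(M)
    r <- exp(M - lse)
    nll <- -sum(lse)

    # empty-component rescue: reseed from the worst-fit sample (the trace
    # records only genuine EM steps, which are monotone)
    col_max <- apply(r, 2, max)
    if (any(col_max < 1e-6)) {
      worst <- which.min(lse)
      for (j in which(col_max < 1e-6)) {
        alpha[j, ] <- dmm_alpha_init(X, as.numeric(seq_len(N) == worst))
        pi_k[j] <- 1 / N
      }
      pi_k <- pi_k / sum(pi_k)
      nll_prev <- Inf
      next
    }
    nll_trace <- c(nll_trace, nll)

    if (is.finite(nll_prev) && abs(nll_prev - nll) < tol * (1 + abs(nll))) {
      converged <- TRUE
      break
    }
    nll_prev <- nll

    pi_k <- pmax(colMeans(r), 1e-10)
    pi_k <- pi_k / sum(pi_k)
    for (j in seq_len(k)) {
      alpha[j, ] <- dmm_alpha_update(prep, alpha[j, ], r[, j], iters = inner_iter)
    }
    if (verbose && iter %% 10 == 0) inform(sprintf("  iter %d nll %.2f", iter, nll))
  }
  # polish: run each component's fixed point to stationarity at the final
  # responsibilities (a generalised M-step, so the likelihood cannot
  # decrease), then refresh responsibilities once
  if (!polish) {
    return(list(alpha = alpha, pi = pi_k, r = r,
                nll = nll_trace[length(nll_trace)],
                nll_trace = nll_trace, converged = converged))
  }
  for (j in seq_len(k)) {
    a_old <- alpha[j, ]
    for (pp in 1:100) {
      a_new <- dmm_alpha_update(prep, a_old, r[, j], iters = 1)
      if (max(abs(a_new - a_old) / pmax(a_old, 1e-8)) < 1e-10) {
        a_old <- a_new
        break
      }
      a_old <- a_new
    }
    alpha[j, ] <- a_old
  }
  LL <- vapply(seq_len(k), function(j) dmm_comp_loglik(prep, alpha[j, ]),
               numeric(N))
  M <- sweep(matrix(LL, N, k), 2, log(pi_k), "+")
  lse <- row_logsumexp(M)
  r <- exp(M - lse)
  nll_trace <- c(nll_trace, -sum(lse))
  list(alpha = alpha, pi = pi_k, r = r, nll = nll_trace[length(nll_trace)],
       nll_trace = nll_trace, converged = converged)
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' E-step responsibilities are computed through log-sum-exp; the M-step
#' re-estimates mixture weights and updates each component's Dirichlet
#' parameters by the weighted fixed-point iteration
#' `a_j <- a_j * sum_i r_i (psi(x_ij + a_j) - psi(a_j)) /
#'               sum_i r_i (psi(n_i + A)   - psi(A))`.
#' Components are initialised from a k-means partition of relative
#' abundances; the best of `n_restarts` runs (by final negative
#' log-likelihood) is kept, and clusters are relabelled 1..K by decreasing
#' mixture weight.
#'
#' @param counts Wide count tibble (rarefied or raw; all totals > 0).
#' @param k Number of mixture components (1 <= k <= number of samples).
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param n_restarts Number of EM restarts (default 3).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative NLL convergence tolerance (default 1e-6).
#' @param inner_iter Fixed-point iterations per M-step (default 3).
#' @param prior_var Variance of the Gaussian prior on log-alpha used by the
#'   Laplace score (default 10).
#' @param verbose Print progress.
#' @return An object of class `gd_dmm`: mixture weights `pi`, parameter
#'   matrix `alpha` (K x features), `responsibilities` (samples x K),
#'   `nll_trace`, `laplace` score, `converged`, `seed`, and the feature and
#'   sample ids.
#' @export
fit_dmm <- function(counts, k, seed = 1, n_restarts = 3, max_iter = 500,
                    tol = 1e-6, inner_iter = 3, prior_var = 10,
                    verbose = FALSE) {
  X <- count_matrix(counts)
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(X)) abort("k exceeds the number of samples")
  if (any(rowSums(X) == 0)) abort("all-zero sample; remove before fitting")
  prep <- dmm_prepare(X)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    fit <- dmm_em_once(prep, k, seed + rs - 1L, max_iter, tol, inner_iter, verbose)
    if (is.null(best) || fit$nll < best$nll) best <- fit
  }
  dmm_finalize(best, counts, X, seed, prior_var)
}

# Package an EM result as a gd_dmm model (clusters ordered by weight) and
# attach its Laplace score.
dmm_finalize <- function(best, counts, X, seed, prior_var) {
  k <- length(best$pi)
  ord <- order(best$pi, decreasing = TRUE)
  model <- structure(
    list(
      k = as.integer(k),
      pi = best$pi[ord],
      alpha = best$alpha[ord, , drop = FALSE],
      responsibilities = best$r[, ord, drop = FALSE],
      nll = best$nll,
      nll_trace = best$nll_trace,
      converged = best$converged,
      seed = seed,
      prior_var = prior_var,
      feature_ids = colnames(X),
      sample_ids = rownames(X)
    ),
    class = "gd_dmm"
  )
  dimnames(model$alpha) <- list(paste0("cluster", seq_len(k)), colnames(X))
  model$laplace <- laplace_score(model, counts)
  model
}

# Warm-start initialisation for K components from a fitted (K-1)-component
# model: split one component in two along its internal 2-means partition.
dmm_split_init <- function(prep, fit, j, seed) {
  lab <- apply(fit$r, 1, which.max)
  members <- which(lab == j & fit$r[cbind(seq_len(nrow(fit$r)), lab)] > 0.5)
  if (length(members) < 4) return(NULL)
  rel <- sqrt(prep$X[members, , drop = FALSE] / prep$n[members])
  km <- withr::with_seed(seed, suppressWarnings(
    stats::kmeans(rel, centers = 2, nstart = 3, iter.max = 30)))
  if (min(tabulate(km$cluster, 2)) < 2) return(NULL)
  w1 <- w2 <- numeric(prep$N)
  w1[members[km$cluster == 1]] <- 1
  w2[members[km$cluster == 2]] <- 1
  alpha <- rbind(fit$alpha[-j, , drop = FALSE],
                 dmm_alpha_init(prep$X, w1),
                 dmm_alpha_init(prep$X, w2))
  frac <- mean(km$cluster == 1)
  pi_k <- c(fit$pi[-j], fit$pi[j] * frac, fit$pi[j] * (1 - frac))
  list(alpha = alpha, pi = pi_k / sum(pi_k))
}

#' Laplace-approximation model score of a fitted DMM
#'
#' The negative approximate log evidence, evaluated in the
#' log-parameterisation `lambda = log(alpha)`:
#' `-(logL + log p(lambda) + d/2 log 2pi - 1/2 log det H)`, where `d = K*S`,
#' `p` is an independent Gaussian prior on each `lambda` (mean 0, variance
#' `prior_var`), and `H` is the Hessian of the negative log posterior at the
#' mode, taken block-diagonal per component with expected responsibilities.
#' Each block has diagonal-plus-rank-one structure, so its log determinant is
#' evaluated by the matrix determinant lemma; non-positive blocks fall back
#' to an eigendecomposition regularised by `eps * trace/d` on the diagonal.
#' Lower scores indicate better evidence; K is selected by the minimum.
#'
#' @param model A fitted `gd_dmm` object.
#' @param counts The count tibble the model was fitted to.
#' @return The Laplace score (scalar; lower is better).
#' @export
laplace_score <- function(model, counts) {
  X <- count_matrix(counts)[model$sample_ids, model$feature_ids, drop = FALSE]
  prep <- dmm_prepare(X)
  v <- model$prior_var
  k <- model$k
  S <- prep$S
  d <- k * S

  LL <- vapply(seq_len(k), function(j) dmm_comp_loglik(prep, model$alpha[j, ]),
               numeric(prep$N))
  M <- sweep(matrix(LL, prep$N, k), 2, log(model$pi), "+")
  loglik <- sum(row_logsumexp(M))
  lambda <- log(model$alpha)
  logprior <- sum(-lambda^2 / (2 * v) - 0.5 * log(2 * pi * v))

  logdet <- 0
  for (j in seq_len(k)) {
    a <- model$alpha[j, ]
    w <- model$responsibilities[, j]
    sw <- sum(w)
    A <- sum(a)
    wc <- w[prep$ri]
    # gradient and curvature pieces of the weighted component log-likelihood
    c1 <- sum(w * (digamma(A) - digamma(prep$n + A)))
    c2 <- sum(w * (trigamma(A) - trigamma(prep$n + A)))
    s_j <- agg_cols((digamma(prep$xv + a[prep$ci]) - digamma(a)[prep$ci]) * wc,
                    prep$ci, S)
    t_j <- agg_cols((trigamma(prep$xv + a[prep$ci]) - trigamma(a)[prep$ci]) * wc,
                    prep$ci, S)
    g <- c1 + s_j                        # d loglik / d alpha
    gpost <- g - lambda[j, ] / (v * a)   # posterior gradient in alpha
    # neg log-posterior Hessian in lambda = diag(Dg) - c2 * a a^T
    Dg <- 1 / v - (a^2 * t_j + a * gpost)
    if (all(Dg > 0)) {
      corr <- 1 - c2 * sum(a^2 / Dg)
      if (corr > 1e-12) {
        logdet <- logdet + sum(log(Dg)) + log(corr)
        next
      }
    }
    # fall back to the dense block with ridge regularisation
    B <- diag(Dg, S) - c2 * tcrossprod(a)
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      eps <- 1e-6 * sum(diag(B)) / S
      warn("non-positive-definite Laplace Hessian block; regularising")
      ev <- ev + (abs(min(ev)) + eps)
    }
    logdet <- logdet + sum(log(ev))
  }
  -(loglik + logprior + d / 2 * log(2 * pi) - 0.5 * logdet)
}

#' Choose the number of community types by Laplace score
#'
#' Fits a DMM at each K in `k_range` and returns the K with the lowest
#' Laplace score (ties broken toward the smaller K), together with the full
#' score table for audit. In addition to `n_restarts` k-means-initialised EM
#' runs per K, each K is warm-started from the previous K's solution by
#' splitting candidate components in two (worst-fitting and largest first),
#' which substantially reduces the local-optimum noise that otherwise makes
#' neighbouring K scores incomparable.
#'
#' @param counts Wide count tibble.
#' @param k_range Integer vector of candidate K (default 1:10).
#' @param seed Integer seed shared across K.
#' @param n_restarts k-means-initialised restarts per K (default 2).
#' @param max_iter,tol,inner_iter,prior_var As [fit_dmm()].
#' @param n_split_candidates Components tried for the warm-start split.
#' @return A list of class `gd_dmm_selection`: `best_k`, `scores` tibble
#'   (`k`, `laplace`, `nll`, `converged`, `error`), and `model`, the fitted
#'   model at `best_k`.
#' @export
select_k <- function(counts, k_range = 1:10, seed = 1, n_restarts = 2,
                     max_iter = 300, tol = 1e-6, inner_iter = 3,
                     prior_var = 10, n_split_candidates = 3) {
  if (length(k_range) == 0) abort("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  X <- count_matrix(counts)
  prep <- dmm_prepare(X)
  fits <- vector("list", length(k_range))
  rows <- vector("list", length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    res <- tryCatch({
      best <- NULL
      for (rs in seq_len(n_restarts)) {
        f <- dmm_em_once(prep, k, seed + rs - 1L, max_iter, tol, inner_iter, FALSE)
        if (is.null(best) || f$nll < best$nll) best <- f
      }
      # warm start by splitting components of the previous model
      if (!is.null(prev) && length(prev$pi) == k - 1L) {
        cand <- dmm_split_candidates(prep, prev, n_split_candidates)
        short <- purrr::compact(purrr::map(cand, function(j) {
          ini <- dmm_split_init(prep, prev, j, seed + 31L * j)
          if (is.null(ini)) return(NULL)
          dmm_em_core(prep, ini$alpha, ini$pi, 40L, tol * 10, inner_iter,
                      polish = FALSE)
        }))
        if (length(short)) {
          top <- short[[which.min(purrr::map_dbl(short, "nll"))]]
          f <- dmm_em_core(prep, top$alpha, top$pi, max_iter, tol, inner_iter)
          if (f$nll < best$nll) best <- f
        }
      }
      dmm_finalize(best, counts, X, seed, prior_var)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- tibble(k = k, laplace = NA_real_, nll = NA_real_,
                          converged = NA, error = conditionMessage(res))
    } else {
      fits[[i]] <- res
      prev <- list(r = res$responsibilities, alpha = res$alpha, pi = res$pi)
      rows[[i]] <- tibble(k = k, laplace = res$laplace, nll = res$nll,
                          converged = res$converged, error = NA_character_)
    }
  }
  scores <- bind_rows(rows)
  if (all(is.na(scores$laplace))) abort("all DMM fits failed")
  best_i <- which(scores$laplace == min(scores$laplace, na.rm = TRUE))[1]
  structure(
    list(best_k = scores$k[best_i], scores = scores, model = fits[[best_i]]),
    class = "gd_dmm_selection"
  )
}

# Ranked component indices to try splitting: worst weighted per-sample fit
# first, then largest weight.
dmm_split_candidates <- function(prep, fit, n_cand) {
  k <- length(fit$pi)
  LL <- vapply(seq_len(k), function(j) dmm_comp_loglik(prep, fit$alpha[j, ]),
               numeric(prep$N))
  avg <- vapply(seq_len(k), function(j) {
    w <- fit$r[, j]
    if (sum(w) < 2) return(Inf)
    -sum(w * LL[, j]) / sum(w)
  }, numeric(1))
  utils::head(unique(c(order(avg, decreasing = TRUE),
                       order(fit$pi, decreasing = TRUE))), n_cand)
}

#' @export
print.gd_dmm_selection <- function(x, ...) {
  cat(sprintf("DMM model selection: best K = %d (lowest Laplace score)\n", x$best_k))
  print(x$scores, n = nrow(x$scores))
  invisible(x)
}

#' Assign samples to community types
#'
#' Maximum a posteriori cluster per sample under a fitted DMM; ties resolve
#' to the lowest cluster index. Cluster labels follow the model's
#' decreasing-weight order.
#'
#' @param model A fitted `gd_dmm`.
#' @param counts Wide count tibble; features must match the model's.
#' @return Tibble with `sample_id`, `cluster` (integer), `responsibility`
#'   (posterior probability of the assigned cluster).
#' @export
assign_clusters <- function(model, counts) {
  X <- count_matrix(counts)
  if (!identical(colnames(X), model$feature_ids)) {
    abort("feature ids do not match the fitted model")
  }
  prep <- dmm_prepare(X)
  LL <- vapply(seq_len(model$k), function(j) dmm_comp_loglik(prep, model$alpha[j, ]),
               numeric(prep$N))
  M <- sweep(matrix(LL, prep$N, model$k), 2, log(model$pi), "+")
  lse <- row_logsumexp(M)
  r <- exp(M - lse)
  lab <- apply(r, 1, which.max)   # which.max takes the first (lowest) on ties
  tibble(
    sample_id = rownames(X),
    cluster = as.integer(lab),
    responsibility = r[cbind(seq_len(nrow(X)), lab)]
  )
}

#' @export
print.gd_dmm <- function(x, ...) {
  cat(sprintf("Dirichlet-multinomial mixture: K = %d, %d samples, %d features\n",
              x$k, length(x$sample_ids), length(x$feature_ids)))
  cat(sprintf("  NLL %.2f | Laplace score %.2f | %s\n", x$nll, x$laplace,
              if (x$converged) "converged" else "not converged"))
  cat("  weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}
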