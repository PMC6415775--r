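test_that("dm_log_pmf matches enumeration on two-category problems", {
  expect_equal(dm_log_pmf(c(1, 0), c(1, 1)), log(1 / 2), tolerance = 1e-9)
  expect_equal(dm_log_pmf(c(1, 1), c(1, 1)), log(1 / 3), tolerance = 1e-9)
  expect_equal(dm_log_pmf(7, 2.5), 0)     # single category: probability 1
  expect_error(dm_log_pmf(c(1, 0), c(1, -1)), "positive")
  expect_error(dm_log_pmf(c(1.5, 0), c(1, 1)), "integers")
})

test_that("dm pmf sums to one over all compositions (S = 2, n <= 5)", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      alpha <- runif(2, 0.1, 5)
      for (n in 1:5) {
        tot <- sum(vapply(0:n, function(x) {
          exp(dm_log_pmf(c(x, n - x), alpha))
        }, numeric(1)))
        expect_lt(abs(tot - 1), 1e-10)
      }
    }
  })
})

test_that("dm_log_pmf is stable at large depth", {
  x <- c(95000, 4000, 1000)
  expect_true(is.finite(dm_log_pmf(x, c(5, 1, 0.5))))
})

test_that("K = 1 EM equals the direct single-component fit", {
  fx <- random_dm_counts(40, 6, 300, seed = 21)
  fit <- fit_dmm(fx$counts, k = 1, seed = 1, n_restarts = 1)
  expect_true(all(fit$responsibilities == 1))
  direct <- oracle_dm_fit(count_matrix(fx$counts))
  expect_lt(max(abs(fit$alpha[1, ] - direct) / direct), 1e-4)
})

test_that("EM decreases the negative log-likelihood monotonically", {
  for (s in 1:5) {
    fx <- random_dm_counts(30, 5, 200, k = 2, seed = s)
    fit <- fit_dmm(fx$counts, k = 2, seed = s, n_restarts = 1)
    expect_true(all(diff(fit$nll_trace) <= 1e-8))
  }
})

test_that("model invariants hold after fitting", {
  fx <- random_dm_counts(60, 8, 500, k = 3, seed = 2)
  fit <- fit_dmm(fx$counts, k = 3, seed = 1, n_restarts = 2)
  expect_lt(abs(sum(fit$pi) - 1), 1e-10)
  expect_true(all(fit$alpha > 0))
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-10))
  # cluster labels ordered by decreasing weight
  expect_true(all(diff(fit$pi) <= 1e-12))
})

test_that("planted two-component structure is recovered", {
  for (s in 1:5) {
    fx <- random_dm_counts(200, 10, 1000, k = 2, seed = s, sep = 12)
    fit <- fit_dmm(fx$counts, k = 2, seed = s, n_restarts = 2)
    lab <- assign_clusters(fit, fx$counts)$cluster
    expect_gte(ari(lab, fx$z), 0.95)
  }
})

test_that("planted dominant-taxon ordering is recovered exactly", {
  fx <- random_dm_counts(200, 10, 1000, k = 2, seed = 4, sep = 12)
  fit <- fit_dmm(fx$counts, k = 2, seed = 1, n_restarts = 2)
  # map each fitted component to the planted one sharing its dominant set
  for (j in 1:2) {
    dom_fit <- order(fit$alpha[j, ], decreasing = TRUE)[1:5]
    truth_j <- which.max(vapply(1:2, function(t) {
      sum(dom_fit %in% order(fx$alpha[t, ], decreasing = TRUE)[1:5])
    }, numeric(1)))
    expect_setequal(dom_fit, order(fx$alpha[truth_j, ], decreasing = TRUE)[1:5])
  }
})

test_that("Laplace score prefers the true K on separated data", {
  agree <- 0
  for (s in 1:10) {
    fx <- random_dm_counts(120, 9, 800, k = 3, seed = s, sep = 12)
    f3 <- fit_dmm(fx$counts, 3, seed = s, n_restarts = 2)
    f1 <- fit_dmm(fx$counts, 1, seed = s, n_restarts = 1)
    if (f3$laplace < f1$laplace) agree <- agree + 1
  }
  expect_gte(agree, 9)
})

test_that("select_k returns K = 1 for single-component data", {
  agree <- 0
  for (s in 1:10) {
    fx <- random_dm_counts(80, 6, 400, k = 1, seed = s)
    sel <- suppressWarnings(select_k(fx$counts, 1:4, seed = s, n_restarts = 1))
    if (sel$best_k == 1) agree <- agree + 1
  }
  expect_gte(agree, 9)
})

test_that("a duplicated empty component never lowers the Laplace score", {
  fx <- random_dm_counts(60, 6, 400, k = 2, seed = 3, sep = 12)
  fit <- fit_dmm(fx$counts, 2, seed = 1, n_restarts = 2)
  aug <- fit
  aug$k <- 3L
  aug$pi <- c(fit$pi, 1e-12)
  aug$pi <- aug$pi / sum(aug$pi)
  aug$alpha <- rbind(fit$alpha, fit$alpha[2, ])
  rownames(aug$alpha) <- paste0("cluster", 1:3)
  aug$responsibilities <- cbind(fit$responsibilities, 0)
  s_aug <- suppressWarnings(laplace_score(aug, fx$counts))
  expect_gte(s_aug, fit$laplace)
})

test_that("d equals K * S free parameters in the Laplace score", {
  # verified through the score's dependence on the parameter count: the
  # (d/2) log 2pi and prior constants shift by exactly S per added component
  fx <- random_dm_counts(30, 5, 200, seed = 8)
  fit <- fit_dmm(fx$counts, 1, seed = 1, n_restarts = 1)
  expect_equal(length(fit$alpha), fit$k * 5)
})

test_that("assignment breaks ties toward the lower cluster index", {
  fx <- random_dm_counts(30, 5, 200, k = 2, seed = 5)
  fit <- fit_dmm(fx$counts, 2, seed = 1, n_restarts = 1)
  # duplicate components: responsibilities are exactly 0.5/0.5
  fit$alpha[2, ] <- fit$alpha[1, ]
  fit$pi <- c(0.5, 0.5)
  lab <- assign_clusters(fit, fx$counts)
  expect_true(all(lab$cluster == 1L))
})

test_that("feature mismatch and degenerate inputs error", {
  fx <- random_dm_counts(10, 4, 100, seed = 6)
  fit <- fit_dmm(fx$counts, 1, seed = 1, n_restarts = 1)
  other <- fx$counts
  names(other)[2] <- "renamed"
  expect_error(assign_clusters(fit, other), "feature ids")
  expect_error(fit_dmm(fx$counts, 11), "exceeds")
  zero <- fx$counts
  zero[1, -1] <- 0L
  expect_error(fit_dmm(zero, 1), "all-zero")
})
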